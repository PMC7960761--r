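test_that("preprocess sorts, merges duplicate osmolalities and enforces the size floor", {
  o <- c(seq(100, 190, by = 5), 100, 150)   # 19 distinct + 2 duplicates
  e <- c(seq(0.2, 0.2, length.out = 19), 0.4, 0.3)
  expect_error(preprocess(osmoscan_curve(o[1:19], e[1:19])),
               class = "osmoscan_too_few_points")
  o2 <- c(seq(100, 195, by = 5), 100)       # 20 distinct, one duplicate of 100
  e2 <- c(0.2, seq(0.21, 0.4, length.out = 19), 0.4)
  pc <- preprocess(osmoscan_curve(o2, e2), smooth_window = 1)
  expect_equal(length(pc$osmolality), 20)
  expect_true("DUPLICATE_OSM" %in% attr(pc, "preprocessed")$flags)
  expect_equal(pc$ei[pc$osmolality == 100], mean(c(0.2, 0.4)))
  # window 1 leaves an already clean curve untouched
  cv <- synth_curve(curve_params())$curve
  pc2 <- preprocess(cv, smooth_window = 1)
  expect_equal(pc2$ei, cv$ei)
  expect_equal(pc2$osmolality, cv$osmolality)
})

test_that("find_peak resolves unique maxima and exact plateaus", {
  o <- seq(100, 500, by = 1)
  tri <- 0.6 - 0.003 * abs(o - 300)             # symmetric triangle at (300, 0.6)
  pk <- find_peak(prep_curve(o, pmax(tri, 0)))
  expect_equal(pk$ei_max, 0.6)
  expect_equal(pk$o_eimax, 300, tolerance = 1e-9)
  plat <- pmin(pmax(0.6 - 0.003 * (abs(o - 300) - 10), 0), 0.6)  # flat on [290, 310]
  pk2 <- find_peak(prep_curve(o, plat))
  expect_equal(pk2$o_eimax, 300)
  # low signal flagged but indices still returned
  pk3 <- find_peak(prep_curve(o, rep(0.02, length(o))))
  expect_true("LOW_SIGNAL" %in% pk3$flags)
  expect_equal(pk3$ei_max, 0.02)
})

test_that("find_valley requires an interior minimum", {
  o <- seq(50, 500, by = 1)
  v <- pmax(0.2, 0.2 + 0.004 * abs(o - 150))    # V-shape, vertex (150, 0.2)
  v[o > 300] <- v[o == 300]
  vl <- find_valley(prep_curve(o, pmin(v, 0.9)), o_eimax = 300)
  expect_equal(vl$o_min, 150, tolerance = 1e-9)
  expect_equal(vl$ei_min, 0.2)
  expect_length(vl$flags, 0)
  # monotone rise across the window: minimum on the edge, no valley
  mono <- find_valley(prep_curve(o, 0.1 + 0.001 * (o - 50)), o_eimax = 300)
  expect_true("NO_VALLEY" %in% mono$flags)
  expect_true(is.na(mono$o_min))
})

test_that("find_hyper interpolates the first downward half-max crossing", {
  o <- seq(100, 500, by = 1)
  lin <- approx(c(100, 300, 500), c(0, 0.6, 0), xout = o)$y
  hy <- find_hyper(prep_curve(o, lin), ei_max = 0.6, o_eimax = 300)
  expect_equal(hy$o_hyper, 400, tolerance = 1e-9)
  # logistic descending arm: frozen closed-form crossing 420 + 25 log(2/sigma(300) - 1)
  sig <- function(x) 1 / (1 + exp((x - 420) / 25))
  e <- ifelse(o <= 300, 0.6 * (o - 100) / 200, 0.6 * sig(o) / sig(300))
  hy2 <- find_hyper(prep_curve(o, e), ei_max = 0.6, o_eimax = 300)
  expect_equal(hy2$o_hyper, 420.4082, tolerance = 0.05)
  # never dropping below half-max: flagged
  hy3 <- find_hyper(prep_curve(o, pmax(lin, 0.35)), ei_max = 0.6, o_eimax = 300)
  expect_true("HYPER_NOT_REACHED" %in% hy3$flags)
  expect_true(is.na(hy3$o_hyper))
})

test_that("compute_area integrates between interpolated bounds", {
  o <- seq(50, 450, by = 1)
  expect_equal(compute_area(prep_curve(o, rep(0.5, length(o))), 100, 400), 150)
  ramp <- approx(c(50, 100, 400, 450), c(0, 0, 0.6, 0.7), xout = o)$y
  expect_equal(compute_area(prep_curve(o, ramp), 100, 400), 90, tolerance = 1e-9)
  expect_true(is.na(compute_area(prep_curve(o, ramp), NA, 400)))
  expect_error(compute_area(prep_curve(o, ramp), 400, 100),
               class = "osmoscan_param_error")
})

test_that("extraction recovers generator ground truth on noiseless presets", {
  for (lab in c("WB", "L", "M", "H")) {
    s <- synth_curve(fraction_presets()[[lab]])
    ix <- extract_indices(s$curve, cfg_nosmooth)
    expect_indices_close(ix, s$truth)
    expect_length(ix$qc_flags, 0)
    expect_identical(ix$ei_hyper, ix$ei_max / 2)
  }
  # extracted Area preserves the H < M phenotype
  sH <- extract_indices(synth_curve(fraction_presets()$H)$curve, cfg_nosmooth)
  sM <- extract_indices(synth_curve(fraction_presets()$M)$curve, cfg_nosmooth)
  expect_lt(sH$area, sM$area)
})

test_that("degenerate flat curves are flagged, not fatal", {
  o <- seq(50, 500, by = 5)
  ix <- extract_indices(osmoscan_curve(o, rep(0.02, length(o))))
  expect_true(all(c("LOW_SIGNAL", "NO_VALLEY", "HYPER_NOT_REACHED")
                  %in% ix$qc_flags))
  expect_true(is.na(ix$o_min) && is.na(ix$o_hyper) && is.na(ix$area))
})

test_that("extraction is idempotent under preprocessing with the same config", {
  p <- curve_params(noise_sd = 0.004, seed = 21)
  cv <- synth_curve(p)$curve
  cfg <- extract_config()
  a <- extract_indices(cv, cfg)
  b <- extract_indices(preprocess(cv, cfg$smooth_window), cfg)
  expect_identical(indices_to_df(list(a)), indices_to_df(list(b)))
})

test_that("EI rescaling scales the EI indices and leaves osmolality indices fixed", {
  s <- synth_curve(fraction_presets()$WB)
  base <- extract_indices(s$curve, cfg_nosmooth)
  for (k in c(0.5, 1.5)) {
    cv <- s$curve
    cv$ei <- cv$ei * k
    ix <- extract_indices(cv, cfg_nosmooth)
    expect_equal(ix$ei_max, k * base$ei_max, tolerance = 1e-9)
    expect_equal(ix$ei_min, k * base$ei_min, tolerance = 1e-9)
    expect_equal(ix$ei_hyper, k * base$ei_hyper, tolerance = 1e-9)
    expect_equal(ix$area, k * base$area, tolerance = 1e-6)
    expect_equal(ix$o_min, base$o_min, tolerance = 0.5)
    expect_equal(ix$o_eimax, base$o_eimax, tolerance = 0.5)
    expect_equal(ix$o_hyper, base$o_hyper, tolerance = 0.5)
  }
})

test_that("noiseless round trip holds across random parameter draws", {
  ps <- random_curve_params(30, seed = 314)
  for (p in ps) {
    s <- synth_curve(p)
    expect_indices_close(extract_indices(s$curve, cfg_nosmooth), s$truth)
  }
})
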