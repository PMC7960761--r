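# rasterize a disk/ellipse directly as the measurement oracle
raster_ellipse <- function(nr, nc, cy, cx, a, b, theta = 0, label = 1L) {
  m <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    dx <- cc - cx; dy <- r - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    if (u^2 + v^2 <= 1) m[r, cc] <- label
  }
  m
}

test_that("disk and ellipse measurements match geometry", {
  disk <- raster_ellipse(64, 64, 32, 32, 20, 20)
  sh <- measure_cells(labeled_mask(disk))
  expect_equal(nrow(sh), 1)
  expect_lt(abs(sh$area / (pi * 400) - 1), 0.02)
  expect_gte(sh$sphericity, 0.98)
  ell <- raster_ellipse(64, 96, 32, 48, 20, 10)
  she <- measure_cells(labeled_mask(ell))
  expect_lt(abs(she$area / (pi * 200) - 1), 0.02)
  expect_lt(abs(she$sphericity - 0.5), 0.03)
  expect_lt(abs(she$major_axis - 40), 1.5)
})

test_that("sphericity is rotation invariant and area follows the pixel-size scale law", {
  base <- measure_cells(labeled_mask(raster_ellipse(96, 96, 48, 48, 24, 12)))
  for (th in c(pi / 6, pi / 4, 1.2)) {
    rot <- measure_cells(labeled_mask(raster_ellipse(96, 96, 48, 48, 24, 12, th)))
    expect_lt(abs(rot$sphericity - base$sphericity), 0.04)
  }
  m <- raster_ellipse(64, 64, 32, 32, 15, 12)
  s1 <- measure_cells(labeled_mask(m, pixel_size = 1))
  s2 <- measure_cells(labeled_mask(m, pixel_size = 2))
  expect_equal(s2$area, 4 * s1$area)
  expect_equal(s2$sphericity, s1$sphericity)
})

test_that("small components are dropped, border cells flagged, empty masks allowed", {
  m <- matrix(0L, 40, 40)
  m[2:4, 2:4] <- 1L                 # 9 px, below min_area
  m[10:25, 10:25] <- 2L             # interior square
  m[30:40, 30:40] <- 3L             # touches the border
  sh <- measure_cells(labeled_mask(m), min_area_px = 50)
  expect_equal(attr(sh, "n_dropped"), 1L)
  expect_setequal(sh$label, c(2L, 3L))
  expect_false(sh$border[sh$label == 2])
  expect_true(sh$border[sh$label == 3])
  # pixel conservation
  expect_equal(sum(m > 0) + sum(m == 0), length(m))
  empty <- measure_cells(labeled_mask(matrix(0L, 10, 10)))
  expect_equal(nrow(empty), 0)
  expect_error(labeled_mask(matrix(0.5, 5, 5)), class = "osmoscan_format_error")
})

test_that("area histograms use half-open width-binwidth bins and conserve counts", {
  sh <- data.frame(area = c(100, 600, 1100))
  h <- area_histogram(sh, binwidth = 500)
  expect_equal(h$count, c(1, 1, 1))
  expect_equal(h$bin_lo, c(0, 500, 1000))
  expect_equal(h$bin_hi, c(500, 1000, 1500))
  one <- area_histogram(data.frame(area = 750))
  expect_equal(sum(one$count), 1)
  set.seed(40)
  many <- data.frame(area = runif(500, 0, 4000))
  expect_equal(sum(area_histogram(many)$count), 500)
  # boundary value falls in the right-open bin above it
  expect_equal(area_histogram(data.frame(area = 500))$count, c(0, 1))
  expect_error(area_histogram(sh, binwidth = 0), class = "osmoscan_param_error")
})

test_that("synthetic masks are an exact oracle for measure_cells", {
  sm <- synth_mask(10, seed = 17)
  sh <- measure_cells(sm$mask)
  expect_equal(nrow(sh), 10)
  m <- merge(sh, sm$truth, by = "label")
  expect_true(all(abs(m$area.x / m$area.y - 1) < 0.03))
  expect_true(all(abs(m$sphericity.x - m$sphericity.y) < 0.04))
  # determinism and the empty case
  sm2 <- synth_mask(10, seed = 17)
  expect_identical(sm$mask$pixels, sm2$mask$pixels)
  expect_equal(nrow(synth_mask(0)$truth), 0)
  expect_error(synth_mask(50, image_shape = c(64, 64), seed = 1),
               class = "osmoscan_packing_error")
})

test_that("axis measurements agree with an independent moment implementation", {
  skip_if_not_installed("EBImage")
  sm <- synth_mask(8, seed = 23)
  sh <- measure_cells(sm$mask)
  ft <- EBImage::computeFeatures.moment(sm$mask$pixels)
  expect_equal(sh$major_axis, unname(ft[, "m.majoraxis"]), tolerance = 0.03)
  ecc <- unname(ft[, "m.eccentricity"])
  expect_equal(sh$sphericity, sqrt(1 - ecc^2), tolerance = 0.03)
})

test_that("fraction morphology comparison recovers generated orderings", {
  set.seed(55)
  donors <- sprintf("d%02d", 1:8)
  mk <- function(fr, mu_area, mu_sph) {
    do.call(rbind, lapply(donors, function(d)
      data.frame(donor_id = d, fraction = fr,
                 area = rnorm(40, mu_area, 60),
                 sphericity = pmin(rnorm(40, mu_sph, 0.03), 1))))
  }
  cells <- rbind(mk("L", 1400, 0.82), mk("M", 1250, 0.90), mk("H", 1150, 0.80))
  res <- compare_fraction_morphology(cells)
  am <- attr(res, "donor_means")
  mean_of <- function(fr, metric) mean(am[[metric]][am$fraction == fr])
  expect_true(mean_of("L", "area") > mean_of("M", "area"))
  expect_true(mean_of("M", "area") > mean_of("H", "area"))
  expect_true(mean_of("M", "sphericity") > mean_of("L", "sphericity"))
  expect_true(mean_of("M", "sphericity") > mean_of("H", "sphericity"))
  expect_lt(res$p_value[res$pair == "L:H" & res$metric == "area"], 0.05)
  # identical cell sets in two fractions: zero estimate, p = 1
  one <- mk("L", 1300, 0.85)
  ident <- compare_fraction_morphology(
    rbind(one, transform(one, fraction = "M")), fractions = c("L", "M"))
  expect_true(all(ident$estimate == 0))
  expect_true(all(ident$p_value == 1))
  # missing fraction pairing is an error
  expect_error(compare_fraction_morphology(cells[cells$fraction != "H", ],
                                           fractions = c("L", "M", "H")),
               class = "osmoscan_param_error")
})

test_that("masks survive a 16-bit TIFF and PNG round trip", {
  sm <- synth_mask(5, seed = 3, image_shape = c(128, 128))
  for (ext in c("tif", "png")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mask(sm$mask, f)
    back <- read_mask(f)
    expect_identical(back$pixels, sm$mask$pixels)
    unlink(f)
  }
})
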