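test_that("replica cohorts reproduce the reference composition exactly", {
  for (seed in c(1, 77, 2024)) {
    rc <- replica_cohort(seed = seed)
    expect_equal(nrow(rc), 45)
    expect_equal(sum(rc$gender == "F"), 28)
    expect_equal(sum(rc$gender == "M"), 17)
    expect_true(all(rc$age[rc$gender == "F"] >= 18 & rc$age[rc$gender == "F"] <= 61))
    expect_true(all(rc$age[rc$gender == "M"] >= 23 & rc$age[rc$gender == "M"] <= 51))
    expect_lt(max(rc$hypochromic_pct), 5)
    expect_true(all(rc$water_fraction > 0.55 & rc$water_fraction < 0.75))
  }
})

test_that("replica calibration recovers the reference hematology means", {
  reps <- lapply(1:150, replica_cohort)
  pool <- do.call(rbind, reps)
  check <- function(x, target) {
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target), 3 * se + 1e-12)
  }
  check(pool$hb[pool$gender == "F"], 136.6)
  check(pool$hb[pool$gender == "M"], 151.5)
  check(pool$hct[pool$gender == "F"], 41.4)
  check(pool$hct[pool$gender == "M"], 46.2)
  check(pool$mcv, 89.6)
  check(pool$mchc, 334)
  check(pool$rdw, 13.2)
})

test_that("the generator is seeded-deterministic", {
  cfg <- cohort_config(seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  d <- simulate_cohort(cfg)[1, ]
  expect_identical(simulate_fractions(d, seed = 9), simulate_fractions(d, seed = 9))
})

test_that("null and non-null age effects behave as generated", {
  null_cfg <- cohort_config(n_female = 5000, n_male = 5000, beta_age = 0,
                            rho_rdw = 0, seed = 8)
  co <- simulate_cohort(null_cfg)
  expect_lt(abs(cor(co$age, co$o_hyper)), 0.05)
  eff <- simulate_cohort(cohort_config(n_female = 500, n_male = 500,
                                       beta_age = 0.5, seed = 9))
  slope <- coef(lm(o_hyper ~ age + gender, eff))["age"]
  expect_lt(abs(slope - 0.5), 0.1)
})

test_that("generated couplings have the reported signs", {
  co <- simulate_cohort(cohort_config(n_female = 2000, n_male = 2000, seed = 10))
  expect_gt(cor(co$rdw, co$o_hyper), 0.2)            # O_hyper rises with RDW
  expect_gt(cor(co$water_fraction, co$o_hyper), 0.2) # hydration marker
  expect_lt(cor(co$water_fraction, co$mchc), -0.2)   # denser cells, less water
})

test_that("fraction samples carry the Percoll shift and expected marker structure", {
  donor <- simulate_cohort(cohort_config(seed = 3))[1, ]
  fr <- simulate_fractions(donor, seed = 5)
  expect_setequal(fr$fraction, c("WB", "WBP", "L", "M", "H"))
  wb <- fr[fr$fraction == "WB", ]
  wbp <- fr[fr$fraction == "WBP", ]
  expect_equal(wbp$o_min - wb$o_min, 10)
  expect_equal(wbp$o_hyper - wb$o_hyper, 10)
  expect_equal(wbp$ei_max, wb$ei_max)
  expect_true(all(is.na(wb$ratio_41ab)))
  lmh <- fr[fr$fraction %in% c("L", "M", "H"), ]
  expect_true(all(lmh$retic_pct > 0 & lmh$retic_pct < 100))
  expect_true(all(lmh[, rownames(osmoscan:::.marker_gm())] > 0))
  # expected orderings hold on fraction-level means across donors
  many <- do.call(rbind, lapply(seq_len(40), function(i)
    simulate_fractions(donor, seed = 100 + i)))
  gm <- aggregate(many[many$fraction %in% c("L", "M", "H"),
                       c("ratio_41ab", "daf_gmean")],
                  by = list(fraction = many$fraction[many$fraction %in% c("L", "M", "H")]),
                  mean)
  r <- setNames(gm$ratio_41ab, gm$fraction)
  expect_true(r["L"] < r["M"] && r["M"] < r["H"])
  d <- setNames(gm$daf_gmean, gm$fraction)
  expect_true(d["L"] > d["H"] && d["H"] > d["M"])
})

test_that("donor curve parameters mirror the donor's whole-blood indices", {
  donor <- simulate_cohort(cohort_config(seed = 12))[3, ]
  ps <- donor_fraction_params(donor, noise_sd = 0, seed = 1)
  expect_equal(ps$WB$o_hyper_true, donor$o_hyper)
  expect_equal(ps$WB$o_min_true, donor$o_min)
  expect_equal(ps$WB$ei_max_true, donor$ei_max)
  # WBP shifted right on O_min/O_hyper (up to the small per-scan jitter)
  expect_gt(ps$WBP$o_min_true, ps$WB$o_min_true + 5)
  expect_gt(ps$WBP$o_hyper_true, ps$WB$o_hyper_true + 5)
  # H-fraction markedly left of WB on O_hyper
  expect_lt(ps$H$o_hyper_true, ps$WB$o_hyper_true - 25)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulate_cohort(cohort_config(n_female = 0, n_male = 0)),
               class = "osmoscan_param_error")
  expect_error(cohort_config(n_female = -1), class = "osmoscan_param_error")
  expect_error(cohort_config(rho_rdw = 1.5), class = "osmoscan_param_error")
  expect_error(simulate_fractions(data.frame(x = 1)),
               class = "osmoscan_param_error")
})
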