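test_that("qc_filter removes donors at or above 5% hypochromic cells", {
  co <- data.frame(donor_id = c("a", "b", "c"),
                   hypochromic_pct = c(2.0, 4.9, 5.1))
  out <- qc_filter(co)
  expect_equal(nrow(out$cohort), 2)
  expect_equal(out$flags$donor_id, "c")
  clean <- data.frame(donor_id = "a", hypochromic_pct = 1)
  expect_identical(qc_filter(clean)$cohort, clean)
  empty <- data.frame(donor_id = character(0), hypochromic_pct = numeric(0))
  expect_equal(nrow(qc_filter(empty)$cohort), 0)
  expect_equal(nrow(qc_filter(empty)$flags), 0)
  expect_error(qc_filter(data.frame(x = 1)), class = "osmoscan_format_error")
})

test_that("the Shapiro-Wilk gate picks the test an independent check would", {
  set.seed(11)
  d_norm <- rnorm(20)
  x <- rnorm(20) ; y <- x - d_norm
  expect_identical(choose_paired_test(x, y), "paired_t")
  expect_gte(shapiro.test(x - y)$p.value, 0.05)  # independent gate check
  set.seed(11)
  d_cauchy <- rcauchy(50)
  x2 <- rnorm(50) ; y2 <- x2 - d_cauchy
  expect_identical(choose_paired_test(x2, y2), "wilcoxon_signed_rank")
  expect_lt(shapiro.test(x2 - y2)$p.value, 0.05)
  expect_warning(res <- choose_paired_test(rep(1, 10), rep(0, 10)),
                 "constant")
  expect_identical(res, "wilcoxon_signed_rank")
  expect_error(choose_paired_test(1:3, 2:4), class = "osmoscan_param_error")
})

test_that("paired_compare honors identity, exact shifts and orientation", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  same <- paired_compare(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate, 0)
  shift <- paired_compare(1:5, 1:5 + 2, force = "paired_t")
  expect_equal(shift$estimate, -2)   # oriented as x - y
  expect_lt(shift$p_value, 0.01)
  set.seed(2)
  r <- paired_compare(rnorm(30, 1), rnorm(30))
  expect_true(r$ci_lo <= r$estimate && r$estimate <= r$ci_hi)
})

test_that("the gated comparison detects the L vs H O_hyper offset at study scale", {
  cfg <- cohort_config()
  rejections <- vapply(1:200, function(k) {
    co <- simulate_cohort(cohort_config(n_female = 7, n_male = 6,
                                        seed = 5000 + k))
    fr <- do.call(rbind, lapply(seq_len(nrow(co)), function(i)
      simulate_fractions(co[i, ], cfg, seed = 7000 + 20 * k + i)))
    l <- fr$o_hyper[fr$fraction == "L"]
    h <- fr$o_hyper[fr$fraction == "H"]
    suppressWarnings(paired_compare(l, h)$p_value) < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("the gated procedure approximately holds its type-I error", {
  set.seed(606)
  rej <- vapply(1:400, function(k) {
    d <- rnorm(20)
    suppressWarnings(paired_compare(d, rep(0, 20))$p_value) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.085)
})

test_that("index models recover exact and generated effects", {
  co <- data.frame(age = seq(20, 60, length.out = 30))
  co$o_hyper <- 2 * co$age
  fm <- suppressWarnings(fit_index_model(co, "o_hyper", covariates = "age"))
  expect_equal(fm$coefficients$estimate, 2, tolerance = 1e-9)
  expect_lt(fm$coefficients$p_value, 1e-12)
  expect_identical(fm$coefficients$test_name, "ols_t")
  expect_identical(fm$model_f$test_name, "anova_F")
  # collinear covariates are named in the error
  co$age2 <- co$age
  expect_error(fit_index_model(co, "o_hyper", covariates = c("age", "age2")),
               "age2", class = "osmoscan_param_error")
  expect_error(fit_index_model(co, "nope"), class = "osmoscan_format_error")
})

test_that("reference intervals follow the pinned quantile rule and flag small strata", {
  ri <- reference_interval(1:100, rep("all", 100))
  expect_equal(ri$lo, 3.475)
  expect_equal(ri$hi, 97.525)
  small <- reference_interval(1:5, rep("s", 5))
  expect_true(is.na(small$lo) && small$flag == "LOW_N")
  # equivariance under increasing affine maps
  set.seed(31)
  v <- rnorm(200)
  base <- reference_interval(v, rep("a", 200))
  tr <- reference_interval(3 + 2 * v, rep("a", 200))
  expect_equal(tr$lo, 3 + 2 * base$lo)
  expect_equal(tr$hi, 3 + 2 * base$hi)
  # stratum midpoints track the generating means
  set.seed(32)
  vals <- c(rnorm(100, 440, 5), rnorm(100, 470, 5))
  strata <- rep(c("young", "old"), each = 100)
  ri2 <- reference_interval(vals, strata)
  mid <- (ri2$lo + ri2$hi) / 2
  expect_lt(mid[ri2$stratum == "young"], mid[ri2$stratum == "old"])
})
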