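# Synthetic osmoscan curve model.
#
# An osmoscan records the elongation index (EI) of sheared red blood cells
# while extracellular osmolality is swept from the hypoosmotic to the
# hyperosmotic range (0-500 mOsm/kg at 30 Pa). The curve rises over a small
# sub-lysis bump, falls into the hypoosmotic valley (O_min, EI_min), climbs
# to the deformability maximum (O_EI_max, EI_max) and then descends through
# the half-maximum point (O_hyper) toward 500 mOsm/kg.
#
# The generator builds that shape from monotone cubic Hermite segments
# through named control features, so every ground-truth index is an explicit
# input and extraction can be validated against an exact oracle.

#' Osmoscan curve container
#'
#' Bundles an ordered (osmolality, EI) trace with acquisition metadata.
#'
#' @param osmolality Numeric vector of osmolalities (mOsm/kg), within
#'   \[0, 500\].
#' @param ei Numeric vector of elongation-index values (dimensionless), same
#'   length as `osmolality`. Small negatives (\eqn{\ge -0.05}) are tolerated
#'   as instrument noise ahead of QC.
#' @param sample_id Sample identifier.
#' @param fraction One of `"WB"`, `"WBP"`, `"L"`, `"M"`, `"H"`, or `NA`
#'   (whole blood, mock-Percoll-treated whole blood, low/medium/high density
#'   fraction).
#' @param shear_stress_Pa Shear stress of the sweep (Pa); the assay operates
#'   at 30 Pa.
#' @param temperature_C Measurement temperature (degrees C).
#' @return An object of class `osmoscan_curve`.
#' @export
osmoscan_curve <- function(osmolality, ei, sample_id = "sample",
                           fraction = NA_character_,
                           shear_stress_Pa = 30, temperature_C = 37) {
  osmolality <- as.numeric(osmolality)
  ei <- as.numeric(ei)
  if (length(osmolality) != length(ei))
    stop_param("osmolality and ei must have equal length")
  if (any(!is.finite(osmolality)) || any(!is.finite(ei)))
    stop_param("non-finite values in curve data")
  if (any(osmolality < 0 | osmolality > 500))
    stop_param("osmolality outside [0, 500] mOsm/kg")
  if (any(ei < -0.05 | ei > 1))
    stop_param("EI outside [-0.05, 1]")
  if (!is.na(fraction) && !fraction %in% c("WB", "WBP", "L", "M", "H"))
    stop_param("fraction must be one of WB, WBP, L, M, H or NA")
  structure(
    list(osmolality = osmolality, ei = ei, sample_id = sample_id,
         fraction = fraction, shear_stress_Pa = shear_stress_Pa,
         temperature_C = temperature_C),
    class = "osmoscan_curve")
}

#' @export
print.osmoscan_curve <- function(x, ...) {
  cat(sprintf("<osmoscan_curve> %s (fraction %s): %d points, %.0f-%.0f mOsm/kg, EI %.3f-%.3f\n",
              x$sample_id, x$fraction, length(x$osmolality),
              min(x$osmolality), max(x$osmolality), min(x$ei), max(x$ei)))
  invisible(x)
}

#' Ground-truth parameters of a synthetic osmoscan curve
#'
#' The five target indices (`o_min_true`, `ei_min_true`, `o_eimax_true`,
#' `ei_max_true`, `o_hyper_true`) are generator inputs; the noiseless curve
#' is constructed so that it attains exactly those features, including
#' `EI(o_hyper_true) = ei_max_true / 2`.
#'
#' @param o_min_true,ei_min_true Hypoosmotic valley position and depth.
#' @param o_eimax_true,ei_max_true Deformability peak position and height.
#' @param o_hyper_true Osmolality of the half-maximum point on the
#'   descending arm (mOsm/kg).
#' @param bump_osm,bump_ei Position and height of the sub-lysis bump.
#' @param start_osm First emitted osmolality (mOsm/kg); the informative
#'   shape begins after lysis, so no samples are emitted below it.
#' @param end_ei EI at 500 mOsm/kg; must stay below `ei_max_true / 2`.
#' @param noise_sd Standard deviation of additive Gaussian EI noise.
#' @param grid_step Sampling step (mOsm/kg).
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `curve_params`.
#' @export
curve_params <- function(o_min_true = 140, ei_min_true = 0.18,
                         o_eimax_true = 300, ei_max_true = 0.60,
                         o_hyper_true = 460,
                         bump_osm = 75, bump_ei = 0.25,
                         start_osm = 50, end_ei = 0.10,
                         noise_sd = 0, grid_step = 1, seed = NULL) {
  p <- list(o_min_true = o_min_true, ei_min_true = ei_min_true,
            o_eimax_true = o_eimax_true, ei_max_true = ei_max_true,
            o_hyper_true = o_hyper_true, bump_osm = bump_osm,
            bump_ei = bump_ei, start_osm = start_osm, end_ei = end_ei,
            noise_sd = noise_sd, grid_step = grid_step, seed = seed)
  validate_curve_params(p)
  structure(p, class = "curve_params")
}

validate_curve_params <- function(p) {
  ok <- function(cond, msg) if (!cond) stop_param("invalid curve_params: ", msg)
  ok(p$start_osm < p$bump_osm && p$bump_osm < p$o_min_true &&
       p$o_min_true < p$o_eimax_true && p$o_eimax_true < p$o_hyper_true &&
       p$o_hyper_true <= 500,
     "need start_osm < bump_osm < o_min_true < o_eimax_true < o_hyper_true <= 500")
  ok(p$start_osm >= 0, "start_osm must be >= 0")
  ok(p$ei_min_true >= 0 && p$ei_min_true < p$ei_max_true && p$ei_max_true < 1,
     "need 0 <= ei_min_true < ei_max_true < 1")
  ok(p$bump_ei > p$ei_min_true, "bump_ei must exceed ei_min_true")
  ok(p$bump_ei < 1, "bump_ei must be < 1")
  ok(p$end_ei >= 0 && p$end_ei < p$ei_max_true / 2,
     "end_ei must lie in [0, ei_max_true / 2)")
  ok(p$noise_sd >= 0, "noise_sd must be >= 0")
  ok(p$grid_step > 0, "grid_step must be > 0")
  invisible(p)
}

# ---- monotone cubic Hermite machinery ------------------------------------

# Slopes for a monotone piecewise-cubic interpolant. `fixed` pins slopes at
# chosen knots (NA = free). Free interior slopes use the Fritsch-Butland
# harmonic mean and free slopes are limited to three times the adjacent
# secant; fixed slopes that would break monotonicity raise a construction
# error naming the segment.
monotone_slopes <- function(x, y, fixed) {
  n <- length(x)
  d <- diff(y) / diff(x)
  m <- numeric(n)
  for (k in seq_len(n)) {
    if (!is.na(fixed[k])) { m[k] <- fixed[k]; next }
    if (k == 1) m[k] <- d[1]
    else if (k == n) m[k] <- d[n - 1]
    else if (d[k - 1] * d[k] <= 0) m[k] <- 0
    else m[k] <- 2 * d[k - 1] * d[k] / (d[k - 1] + d[k])
  }
  # limit / verify segment by segment
  for (k in seq_len(n - 1)) {
    if (d[k] == 0) {
      bad <- c(m[k] != 0 && is.na(fixed[k]), m[k + 1] != 0 && is.na(fixed[k + 1]))
      if (bad[1]) m[k] <- 0
      if (bad[2]) m[k + 1] <- 0
      if (m[k] != 0 || m[k + 1] != 0)
        stop(errorCondition(
          sprintf("monotone construction impossible on flat segment %d (knots %.6g-%.6g)",
                  k, x[k], x[k + 1]),
          class = c("osmoscan_construction_error", "error")))
      next
    }
    for (j in c(k, k + 1)) {
      a <- m[j] / d[k]
      if (a < 0 || a > 3) {
        if (is.na(fixed[j])) {
          m[j] <- if (a < 0) 0 else 3 * d[k]
        } else {
          stop(errorCondition(
            sprintf("monotone construction impossible on segment %d (knots %.6g-%.6g): fixed slope %.6g vs secant %.6g",
                    k, x[k], x[k + 1], m[j], d[k]),
            class = c("osmoscan_construction_error", "error")))
        }
      }
    }
  }
  m
}

hermite_eval <- function(x, y, m, xout) {
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i >= length(x)] <- length(x) - 1L
  h <- x[i + 1] - x[i]
  t <- (xout - x[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
}

# Noiseless EI as a function of osmolality for given curve parameters.
# Knots: (start, 0) -> bump (slope 0) -> valley (slope 0) -> peak (slope 0),
# then a monotone descending arm through (o_hyper, ei_max/2) and (500, end_ei).
curve_shape_fun <- function(params) {
  p <- params
  x <- c(p$start_osm, p$bump_osm, p$o_min_true, p$o_eimax_true,
         p$o_hyper_true, 500)
  y <- c(0, p$bump_ei, p$ei_min_true, p$ei_max_true,
         p$ei_max_true / 2, p$end_ei)
  fixed <- c(0, 0, 0, 0, NA, NA)
  m <- monotone_slopes(x, y, fixed)
  function(o) hermite_eval(x, y, m, o)
}

#' Generate a synthetic osmoscan curve with known ground truth
#'
#' Samples the noiseless monotone piecewise-cubic shape defined by `params`
#' on a regular osmolality grid from `start_osm` to 500 mOsm/kg, adds
#' Gaussian EI noise (`noise_sd`), and returns the exact ground-truth Lorrca
#' indices alongside the curve. The ground-truth Area is a fine-grid
#' trapezoidal quadrature of the noiseless shape between `o_min_true` and
#' `o_hyper_true`.
#'
#' @param params A [curve_params()] object.
#' @param sample_id,fraction Metadata stored on the curve.
#' @return A list with elements `curve` (an [osmoscan_curve()]) and `truth`
#'   (a [lorrca_indices()] holding the generator's exact indices).
#' @examples
#' cv <- synth_curve(curve_params(noise_sd = 0))
#' cv$truth$o_hyper
#' @export
synth_curve <- function(params, sample_id = "synthetic", fraction = NA_character_) {
  validate_curve_params(params)
  f <- curve_shape_fun(params)
  grid <- seq(params$start_osm, 500, by = params$grid_step)
  if (grid[length(grid)] < 500) grid <- c(grid, 500)
  ei <- f(grid)
  if (params$noise_sd > 0) {
    ei <- ei + with_seed(params$seed, stats::rnorm(length(grid), 0, params$noise_sd))
    ei <- pmin(pmax(ei, -0.05), 1)
  }
  fine <- seq(params$o_min_true, params$o_hyper_true, length.out = 8192L)
  area <- pracma::trapz(fine, f(fine))
  truth <- lorrca_indices(
    o_min = params$o_min_true, ei_min = params$ei_min_true,
    o_eimax = params$o_eimax_true, ei_max = params$ei_max_true,
    o_hyper = params$o_hyper_true, area = area)
  list(curve = osmoscan_curve(grid, ei, sample_id = sample_id,
                              fraction = fraction),
       truth = truth)
}

# ---- fraction presets ----------------------------------------------------

# Index levels for the phenotype presets. The study prints no absolute index
# values; these are plausible-range constants constrained by the reported
# orderings between whole blood (WB), mock-Percoll-treated whole blood (WBP)
# and the low/medium/high density fractions. Tests compare extraction
# against generator truth, never against these numbers.
.preset_table <- list(
  WB  = list(o_min_true = 140, ei_min_true = 0.18, o_eimax_true = 300,
             ei_max_true = 0.60, o_hyper_true = 460, bump_ei = 0.25),
  WBP = list(o_min_true = 150, ei_min_true = 0.18, o_eimax_true = 300,
             ei_max_true = 0.60, o_hyper_true = 470, bump_ei = 0.25),
  L   = list(o_min_true = 140, ei_min_true = 0.16, o_eimax_true = 290,
             ei_max_true = 0.58, o_hyper_true = 455, bump_ei = 0.22),
  M   = list(o_min_true = 140, ei_min_true = 0.17, o_eimax_true = 300,
             ei_max_true = 0.61, o_hyper_true = 445, bump_ei = 0.23),
  H   = list(o_min_true = 140, ei_min_true = 0.20, o_eimax_true = 285,
             ei_max_true = 0.54, o_hyper_true = 425, bump_ei = 0.26))

#' Phenotype presets for whole blood, Percoll-treated blood and density fractions
#'
#' Returns named [curve_params()] (noiseless) for the five sample types.
#' The presets jointly encode the reported phenotype orderings: O_hyper
#' decreases L > M > H while O_min is identical across density fractions;
#' the high-density (senescent) fraction has the smallest Area and EI_max
#' but the highest EI_min; both L and H reach maximal deformability below
#' the M-fraction's optimum; mock Percoll treatment (WBP) right-shifts
#' O_min and O_hyper relative to WB without changing EI_max.
#'
#' @param noise_sd,grid_step,seed Sampling settings applied to every preset.
#' @return Named list of `curve_params` with names WB, WBP, L, M, H.
#' @export
fraction_presets <- function(noise_sd = 0, grid_step = 1, seed = NULL) {
  out <- lapply(names(.preset_table), function(lab) {
    p <- .preset_table[[lab]]
    curve_params(o_min_true = p$o_min_true, ei_min_true = p$ei_min_true,
                 o_eimax_true = p$o_eimax_true, ei_max_true = p$ei_max_true,
                 o_hyper_true = p$o_hyper_true, bump_ei = p$bump_ei,
                 noise_sd = noise_sd, grid_step = grid_step, seed = seed)
  })
  stats::setNames(out, names(.preset_table))
}

#' Random plausible curve parameters
#'
#' Draws curve parameters by jittering the phenotype presets, emulating
#' healthy-donor variation: each target feature receives an independent
#' Gaussian perturbation around its preset value, and draws violating the
#' parameter invariants are rejected and redrawn.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @param noise_sd,grid_step Passed through to each `curve_params`.
#' @return List of `curve_params`.
#' @export
random_curve_params <- function(n, seed = NULL, noise_sd = 0, grid_step = 1) {
  presets <- fraction_presets()
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        base <- presets[[sample.int(length(presets), 1)]]
        p <- try(curve_params(
          o_min_true = base$o_min_true + stats::rnorm(1, 0, 6),
          ei_min_true = base$ei_min_true + stats::rnorm(1, 0, 0.012),
          o_eimax_true = base$o_eimax_true + stats::rnorm(1, 0, 8),
          ei_max_true = base$ei_max_true + stats::rnorm(1, 0, 0.02),
          o_hyper_true = base$o_hyper_true + stats::rnorm(1, 0, 8),
          bump_ei = base$bump_ei + stats::rnorm(1, 0, 0.01),
          end_ei = stats::runif(1, 0.06, 0.14),
          noise_sd = noise_sd, grid_step = grid_step), silent = TRUE)
        if (!inherits(p, "try-error")) { out[[i]] <- p; break }
      }
    }
    out
  })
}
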