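# Lorrca index extraction from an osmoscan curve.
#
# Seven indices summarize the curve: the hypoosmotic valley (O_min, EI_min),
# the deformability maximum (O_EI_max, EI_max), the half-maximum point on
# the descending arm (O_hyper, EI_hyper = EI_max / 2), and the area under
# the curve between O_min and O_hyper. Degenerate shapes are reported
# through QC flags rather than errors; only an undersized input is fatal.

QC_FLAGS <- c("TOO_FEW_POINTS", "NO_VALLEY", "HYPER_NOT_REACHED",
              "LOW_SIGNAL", "DUPLICATE_OSM")

#' Lorrca index record
#'
#' @param o_min,ei_min Valley osmolality (mOsm/kg) and EI; `NA` when no
#'   interior valley exists (`NO_VALLEY`).
#' @param o_eimax,ei_max Peak osmolality and maximal EI.
#' @param o_hyper Half-maximum osmolality on the descending arm; `NA` when
#'   the curve never falls to EI_max / 2 (`HYPER_NOT_REACHED`).
#' @param area Area under the curve between `o_min` and `o_hyper`
#'   (mOsm/kg, since EI is dimensionless); `NA` when either bound is.
#' @param qc_flags Character vector of QC flags.
#' @return An object of class `lorrca_indices`. `ei_hyper` is always
#'   `ei_max / 2` by definition.
#' @export
lorrca_indices <- function(o_min = NA_real_, ei_min = NA_real_,
                           o_eimax = NA_real_, ei_max = NA_real_,
                           o_hyper = NA_real_, area = NA_real_,
                           qc_flags = character(0)) {
  bad <- setdiff(qc_flags, QC_FLAGS)
  if (length(bad)) stop_param("unknown qc flag: ", paste(bad, collapse = ", "))
  structure(
    list(o_min = o_min, ei_min = ei_min, o_eimax = o_eimax, ei_max = ei_max,
         o_hyper = o_hyper, ei_hyper = if (is.na(ei_max)) NA_real_ else ei_max / 2,
         area = area, qc_flags = qc_flags),
    class = "lorrca_indices")
}

#' @export
print.lorrca_indices <- function(x, ...) {
  cat(sprintf(
    "<lorrca_indices> O_min %.1f EI_min %.3f | O_EI_max %.1f EI_max %.3f | O_hyper %.1f EI_hyper %.3f | Area %.1f\n",
    x$o_min, x$ei_min, x$o_eimax, x$ei_max, x$o_hyper, x$ei_hyper, x$area))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Turn a list of index records into a data frame
#' @param indices List of [lorrca_indices()] objects.
#' @return data.frame with one row per record; flags collapsed to a
#'   semicolon-separated string.
#' @export
indices_to_df <- function(indices) {
  do.call(rbind, lapply(indices, function(ix) {
    data.frame(o_min = ix$o_min, ei_min = ix$ei_min, o_eimax = ix$o_eimax,
               ei_max = ix$ei_max, o_hyper = ix$o_hyper,
               ei_hyper = ix$ei_hyper, area = ix$area,
               qc_flags = paste(ix$qc_flags, collapse = ";"))
  }))
}

#' Extraction settings
#'
#' @param smooth_window Odd width of the centered moving average applied to
#'   EI (1 disables smoothing).
#' @param plateau_tol EI tolerance used to resolve peak/valley plateaus.
#' @param search_lo Lower osmolality bound of the valley search window
#'   (mOsm/kg); excludes the sub-lysis bump.
#' @param low_signal_threshold EI_max below this raises the `LOW_SIGNAL` flag.
#' @return A list of settings for [extract_indices()].
#' @export
extract_config <- function(smooth_window = 5, plateau_tol = 0.001,
                           search_lo = 100, low_signal_threshold = 0.05) {
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop_param("smooth_window must be a positive odd integer")
  if (plateau_tol < 0) stop_param("plateau_tol must be >= 0")
  list(smooth_window = smooth_window, plateau_tol = plateau_tol,
       search_lo = search_lo, low_signal_threshold = low_signal_threshold)
}

#' Preprocess a raw osmoscan curve
#'
#' Sorts points by osmolality, averages EI over duplicate osmolalities
#' (recording `DUPLICATE_OSM` for downstream), drops points outside
#' \[0, 500\] mOsm/kg, and smooths EI with a centered moving average that
#' shrinks symmetrically at the ends. The returned curve carries a
#' `preprocessed` attribute so that a second pass with the same window is a
#' no-op, making extraction idempotent.
#'
#' @param curve An [osmoscan_curve()] with at least 20 raw points.
#' @param smooth_window Odd moving-average width; 1 disables smoothing.
#' @return The preprocessed `osmoscan_curve`.
#' @export
preprocess <- function(curve, smooth_window = 5) {
  pre <- attr(curve, "preprocessed")
  if (!is.null(pre) && identical(pre$smooth_window, smooth_window)) return(curve)
  if (length(curve$osmolality) < 20)
    stop(errorCondition("TOO_FEW_POINTS: fewer than 20 raw points",
                        class = c("osmoscan_too_few_points", "error")))
  keep <- curve$osmolality >= 0 & curve$osmolality <= 500
  o <- curve$osmolality[keep]
  e <- curve$ei[keep]
  ord <- order(o)
  o <- o[ord]; e <- e[ord]
  flags <- character(0)
  if (anyDuplicated(o)) {
    flags <- "DUPLICATE_OSM"
    e <- as.numeric(tapply(e, factor(o, levels = unique(o)), mean))
    o <- unique(o)
  }
  if (length(o) < 20)
    stop(errorCondition("TOO_FEW_POINTS: fewer than 20 points survive preprocessing",
                        class = c("osmoscan_too_few_points", "error")))
  # robust noise-scale estimate from second differences of the raw trace;
  # for a smooth noiseless curve this is O(grid_step^2) and effectively zero
  sigma_hat <- if (length(e) >= 5) {
    stats::median(abs(diff(e, differences = 2))) / (0.6745 * sqrt(6))
  } else 0
  e <- moving_average(e, smooth_window)
  out <- osmoscan_curve(o, pmin(pmax(e, -0.05), 1),
                        sample_id = curve$sample_id, fraction = curve$fraction,
                        shear_stress_Pa = curve$shear_stress_Pa,
                        temperature_C = curve$temperature_C)
  attr(out, "preprocessed") <- list(smooth_window = smooth_window, flags = flags,
                                    sigma_smooth = sigma_hat / sqrt(smooth_window))
  out
}

# Sub-grid refinement of a peak/valley location. An exact plateau (tied EI
# values) resolves to the run's mean osmolality. A clean (noise-free) curved
# extremum is located by the zero crossing of the centered finite-difference
# derivative, interpolated linearly between the bracketing samples — unlike
# a band midpoint this is insensitive to curvature asymmetry between the
# two arms. When the trace carries measurable noise (`noisy`), the location
# is instead the vertex of a quadratic fitted to all points within `tol` of
# the extremum, which averages over the noise. Any degenerate case falls
# back to the run mean. `sign` is +1 for a peak, -1 for a valley.
refine_extremum <- function(o, e, idx, run, tol, sign, noisy = FALSE) {
  fallback <- mean(o[run])
  if (length(run) > 1 && all(e[run] == e[idx])) return(fallback)
  n <- length(o)
  if (!noisy) {
    if (idx <= 1 || idx >= n) return(fallback)
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    d <- sign * (e[up] - e[dn]) / (o[up] - o[dn])
    if (d[idx] == 0) return(o[idx])
    j <- if (d[idx] > 0) idx else idx - 1L
    if (j < 1 || j + 1 > n || !(d[j] > 0 && d[j + 1] <= 0)) return(fallback)
    return(o[j] + d[j] * (o[j + 1] - o[j]) / (d[j] - d[j + 1]))
  }
  sel <- if (sign > 0) which(e >= e[idx] - tol) else which(e <= e[idx] + tol)
  if (length(sel) < 5) return(fallback)
  x <- o[sel] - o[idx]
  y <- e[sel]
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  a <- fit$coefficients[3]
  if (!is.finite(a) || sign * a >= 0) return(fallback)
  vertex <- o[idx] - fit$coefficients[2] / (2 * a)
  if (vertex < min(o[sel]) || vertex > max(o[sel])) return(fallback)
  vertex
}

# Contiguous run of indices around `at` satisfying cond (logical vector).
plateau_run <- function(cond, at) {
  lo <- at
  while (lo > 1 && cond[lo - 1]) lo <- lo - 1
  hi <- at
  while (hi < length(cond) && cond[hi + 1]) hi <- hi + 1
  lo:hi
}

#' Locate the deformability peak (O_EI_max, EI_max)
#'
#' `ei_max` is the global maximum of the smoothed EI. `o_eimax` is located
#' from the plateau of points within `plateau_tol` of the maximum: an exact
#' plateau resolves to its mean osmolality, a curved peak to the vertex of
#' a quadratic fitted through the near-maximum band. When the trace carries
#' measurable noise the band widens automatically (to eight times the
#' estimated noise scale of the smoothed trace) so the localization
#' averages over the noise instead of chasing the noisy argmax.
#'
#' @param curve Preprocessed [osmoscan_curve()].
#' @param plateau_tol EI tolerance defining the peak plateau.
#' @param low_signal_threshold EI_max below this adds a `LOW_SIGNAL` flag.
#' @return List with `o_eimax`, `ei_max`, `flags`.
#' @export
find_peak <- function(curve, plateau_tol = 0.001, low_signal_threshold = 0.05) {
  e <- curve$ei
  i <- which.max(e)
  ei_max <- e[i]
  tol <- max(plateau_tol, 8 * (attr(curve, "preprocessed")$sigma_smooth %||% 0))
  run <- plateau_run(e >= ei_max - tol, i)
  flags <- if (ei_max < low_signal_threshold) "LOW_SIGNAL" else character(0)
  list(o_eimax = refine_extremum(curve$osmolality, e, i, run, tol, +1,
                                 noisy = tol > plateau_tol),
       ei_max = ei_max, flags = flags)
}

#' Locate the hypoosmotic valley (O_min, EI_min)
#'
#' Global minimum of smoothed EI restricted to osmolalities in
#' \[`search_lo`, `o_eimax`\]; exact plateaus resolve to the run's mean
#' osmolality and curved valleys to a quadratic-vertex refinement, as for
#' [find_peak()]. The minimum must be interior to the window — a minimum on
#' either window edge (e.g. a monotone rise) yields the `NO_VALLEY` flag.
#'
#' @param curve Preprocessed [osmoscan_curve()].
#' @param o_eimax Peak osmolality from [find_peak()].
#' @param search_lo Lower bound of the search window (mOsm/kg).
#' @param plateau_tol Plateau tolerance in EI units.
#' @return List with `o_min`, `ei_min` (NA when flagged) and `flags`.
#' @export
find_valley <- function(curve, o_eimax, search_lo = 100, plateau_tol = 0.001) {
  win <- which(curve$osmolality >= search_lo & curve$osmolality <= o_eimax)
  no_valley <- list(o_min = NA_real_, ei_min = NA_real_, flags = "NO_VALLEY")
  if (length(win) < 3) return(no_valley)
  e <- curve$ei[win]
  o <- curve$osmolality[win]
  i <- which.min(e)
  tol <- max(plateau_tol, 8 * (attr(curve, "preprocessed")$sigma_smooth %||% 0))
  run <- plateau_run(e <= e[i] + tol, i)
  if (1L %in% run || length(e) %in% run) return(no_valley)
  list(o_min = refine_extremum(o, e, i, run, tol, -1, noisy = tol > plateau_tol),
       ei_min = e[i], flags = character(0))
}

#' Locate the hyperosmotic half-maximum point (O_hyper)
#'
#' First downward crossing of the level `ei_max / 2` by the smoothed curve
#' at osmolality above `o_eimax`, located by linear interpolation between
#' the bracketing samples.
#'
#' @param curve Preprocessed [osmoscan_curve()].
#' @param ei_max Maximal EI from [find_peak()].
#' @param o_eimax Peak osmolality.
#' @return List with `o_hyper` (NA when flagged) and `flags`.
#' @export
find_hyper <- function(curve, ei_max, o_eimax) {
  level <- ei_max / 2
  o <- curve$osmolality
  e <- curve$ei
  idx <- which(o > o_eimax)
  if (length(idx)) {
    start <- idx[1]
    below <- which(e[start:length(e)] < level)
    if (length(below)) {
      j <- start + below[1] - 1L
      if (j == 1L) return(list(o_hyper = o[1], flags = character(0)))
      # bracketing samples (j-1, j): e[j-1] >= level > e[j]
      o_hyper <- o[j - 1] + (level - e[j - 1]) * (o[j] - o[j - 1]) / (e[j] - e[j - 1])
      return(list(o_hyper = o_hyper, flags = character(0)))
    }
  }
  list(o_hyper = NA_real_, flags = "HYPER_NOT_REACHED")
}

#' Area under the curve between O_min and O_hyper
#'
#' Trapezoidal integral of smoothed EI over \[`o_min`, `o_hyper`\], with EI
#' at the two bounds obtained by linear interpolation.
#'
#' @param curve Preprocessed [osmoscan_curve()].
#' @param o_min,o_hyper Integration bounds (mOsm/kg).
#' @return Area (mOsm/kg) or `NA` when either bound is undefined.
#' @export
compute_area <- function(curve, o_min, o_hyper) {
  if (is.na(o_min) || is.na(o_hyper)) return(NA_real_)
  if (o_min >= o_hyper) stop_param("o_min must be below o_hyper")
  o <- curve$osmolality
  e <- curve$ei
  inside <- o > o_min & o < o_hyper
  xs <- c(o_min, o[inside], o_hyper)
  ys <- c(interp_at(o, e, o_min), e[inside], interp_at(o, e, o_hyper))
  pracma::trapz(xs, ys)
}

#' Extract the seven Lorrca indices from a raw osmoscan curve
#'
#' Orchestrates [preprocess()], [find_peak()], [find_valley()],
#' [find_hyper()] and [compute_area()]. Degenerate shapes never raise:
#' missing features are reported as `NA` with the corresponding QC flag.
#' The only hard error is an input with fewer than 20 points.
#'
#' @param curve Raw [osmoscan_curve()].
#' @param config Settings from [extract_config()].
#' @return A [lorrca_indices()] object.
#' @examples
#' cv <- synth_curve(curve_params(noise_sd = 0))
#' extract_indices(cv$curve)
#' @export
extract_indices <- function(curve, config = extract_config()) {
  pc <- preprocess(curve, config$smooth_window)
  flags <- attr(pc, "preprocessed")$flags
  pk <- find_peak(pc, config$plateau_tol, config$low_signal_threshold)
  vl <- find_valley(pc, pk$o_eimax, config$search_lo, config$plateau_tol)
  hy <- find_hyper(pc, pk$ei_max, pk$o_eimax)
  area <- compute_area(pc, vl$o_min, hy$o_hyper)
  lorrca_indices(o_min = vl$o_min, ei_min = vl$ei_min,
                 o_eimax = pk$o_eimax, ei_max = pk$ei_max,
                 o_hyper = hy$o_hyper, area = area,
                 qc_flags = unique(c(flags, pk$flags, vl$flags, hy$flags)))
}
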