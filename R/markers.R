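# Small bespoke marker computations: gravimetric water fraction,
# SDS-PAGE band 4.1a:b densitometric ratio, geometric-mean fluorescence,
# and the fraction-ordering report for the marker panel.

#' Red-cell water fraction from wet and dry pellet weights
#'
#' Water content is `1 - dry/wet`; also returned as percent.
#'
#' @param wet_mg,dry_mg Wet and dry pellet masses (same units).
#' @return List with `fraction` and `percent`.
#' @export
water_fraction <- function(wet_mg, dry_mg) {
  if (any(dry_mg <= 0) || any(wet_mg <= 0) || any(dry_mg >= wet_mg))
    stop(errorCondition("measurement error: need 0 < dry_mg < wet_mg",
                        class = c("osmoscan_measurement_error", "error")))
  f <- 1 - dry_mg / wet_mg
  list(fraction = f, percent = 100 * f)
}

#' Densitometry lane profile
#'
#' @param position Increasing migration coordinate (arbitrary units).
#' @param intensity Non-negative intensities, same length.
#' @param window_a,window_b `c(lo, hi)` position intervals of bands 4.1a
#'   and 4.1b; disjoint, with `window_a` preceding `window_b` in migration
#'   order.
#' @return Object of class `lane_profile`.
#' @export
lane_profile <- function(position, intensity, window_a, window_b) {
  if (length(position) != length(intensity))
    stop_param("position and intensity must have equal length")
  if (is.unsorted(position, strictly = TRUE))
    stop_param("position must be strictly increasing")
  if (any(intensity < 0)) stop_param("intensity must be >= 0")
  if (window_a[2] >= window_b[1])
    stop_param("window_a must precede window_b and be disjoint from it")
  structure(list(position = position, intensity = intensity,
                 window_a = window_a, window_b = window_b),
            class = "lane_profile")
}

# baseline-subtracted trapezoidal band integral; baseline is the straight
# line through the minimum intensities just outside the window (between
# the window and the neighboring window or profile end); negative
# post-subtraction values are clipped to zero
band_integral <- function(pos, int, window, flank_lo, flank_hi) {
  inw <- which(pos >= window[1] & pos <= window[2])
  if (length(inw) < 3) stop_param("band window must contain >= 3 samples")
  left <- which(pos >= flank_lo & pos < window[1])
  right <- which(pos > window[2] & pos <= flank_hi)
  if (!length(left)) left <- inw[1]
  if (!length(right)) right <- inw[length(inw)]
  li <- left[which.min(int[left])]
  ri <- right[which.min(int[right])]
  base <- int[li] + (int[ri] - int[li]) *
    (pos[inw] - pos[li]) / (pos[ri] - pos[li])
  pracma::trapz(pos[inw], pmax(int[inw] - base, 0))
}

#' Band 4.1a:b ratio from a densitometry lane profile
#'
#' Each band is integrated trapezoidally after subtracting a local linear
#' baseline anchored at the minimum intensities just outside the band
#' window; the ratio of the 4.1a to the 4.1b integral rises with mean
#' red-cell age (the 4.1a form accumulates by deamidation).
#'
#' @param profile A [lane_profile()].
#' @return The 4.1a:b ratio (dimensionless).
#' @export
band41_ratio <- function(profile) {
  p <- profile
  lo <- p$position[1]
  hi <- p$position[length(p$position)]
  ia <- band_integral(p$position, p$intensity, p$window_a, lo, p$window_b[1])
  ib <- band_integral(p$position, p$intensity, p$window_b, p$window_a[2], hi)
  if (ib <= 0)
    stop(errorCondition("undefined ratio: band 4.1b integral is zero",
                        class = c("osmoscan_measurement_error", "error")))
  ia / ib
}

#' Geometric mean of fluorescence values
#'
#' @param values Positive numeric vector.
#' @return `exp(mean(log(values)))`.
#' @export
geo_mean_fluor <- function(values) {
  if (any(values <= 0) || any(!is.finite(values)))
    stop_param("geometric mean requires positive finite values")
  exp(mean(log(values)))
}

# the ten expected fraction orderings of the marker panel, as predicates
# on a named vector per fraction
.marker_orderings <- list(
  ratio_41ab_increases_with_age = function(L, M, H)
    L["ratio_41ab"] < M["ratio_41ab"] && M["ratio_41ab"] < H["ratio_41ab"],
  reticulocytes_maximal_in_L = function(L, M, H)
    L["retic_pct"] > M["retic_pct"] && L["retic_pct"] > H["retic_pct"],
  cd71_maximal_in_L = function(L, M, H)
    L["cd71_pct"] > M["cd71_pct"] && L["cd71_pct"] > H["cd71_pct"],
  ema_decreases_L_to_H = function(L, M, H)
    L["ema_gmean"] > M["ema_gmean"] && M["ema_gmean"] > H["ema_gmean"],
  fs_decreases_L_to_H = function(L, M, H)
    L["fs_gmean"] > M["fs_gmean"] && M["fs_gmean"] > H["fs_gmean"],
  ss_maximal_in_H = function(L, M, H)
    H["ss_gmean"] > L["ss_gmean"] && H["ss_gmean"] > M["ss_gmean"],
  mbbr_decreases_L_to_H = function(L, M, H)
    L["mbbr_gmean"] > M["mbbr_gmean"] && M["mbbr_gmean"] > H["mbbr_gmean"],
  thiol_decreases_L_to_H = function(L, M, H)
    L["thiol_gmean"] > M["thiol_gmean"] && M["thiol_gmean"] > H["thiol_gmean"],
  dhr_maximal_in_L = function(L, M, H)
    L["dhr_gmean"] > M["dhr_gmean"] && L["dhr_gmean"] > H["dhr_gmean"],
  daf_L_above_H_above_M = function(L, M, H)
    L["daf_gmean"] > H["daf_gmean"] && H["daf_gmean"] > M["daf_gmean"])

#' Check the expected marker orderings across density fractions
#'
#' Evaluates the ten expected L/M/H orderings of the marker panel on each
#' donor's fraction samples and reports the fraction of donors satisfying
#' each.
#'
#' @param samples data.frame of fraction samples (rows per donor and
#'   fraction, as from [simulate_fractions()]); must contain L, M and H
#'   for every donor.
#' @return data.frame with `ordering` and `pass_rate`, plus attribute
#'   `n_donors`.
#' @export
marker_ordering_check <- function(samples) {
  markers <- rownames(.marker_gm())
  donors <- unique(samples$donor_id)
  per_donor <- sapply(donors, function(d) {
    sub <- samples[samples$donor_id == d, , drop = FALSE]
    rows <- lapply(c("L", "M", "H"), function(f) {
      r <- sub[sub$fraction == f, markers, drop = FALSE]
      if (nrow(r) != 1)
        stop_param("pairing error: donor ", d, " lacks fraction ", f)
      unlist(r[1, ])
    })
    names(rows) <- c("L", "M", "H")
    vapply(.marker_orderings,
           function(fun) isTRUE(unname(fun(rows$L, rows$M, rows$H))),
           logical(1))
  })
  out <- data.frame(ordering = names(.marker_orderings),
                    pass_rate = rowMeans(matrix(per_donor,
                                                nrow = length(.marker_orderings))))
  rownames(out) <- NULL
  attr(out, "n_donors") <- length(donors)
  out
}
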