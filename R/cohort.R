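# Synthetic donor cohorts and per-donor density-fraction samples.
#
# The generator reproduces the statistical structure of a healthy-donor
# osmoscan study: gender-specific hematology (hemoglobin, hematocrit) and
# shared red-cell indices (MCV, MCHC, RDW) drawn from calibrated normals, a
# latent red-cell water fraction coupled negatively to MCHC, and an O_hyper
# that rises with donor age and water content while sharing a residual
# correlation with RDW. Density fractions (L/M/H) and the mock-Percoll
# treatment (WBP) shift the whole-blood indices by phenotype offsets, and a
# flow/densitometry marker panel is drawn log-normally around
# fraction-specific geometric means.

#' Calibration table for the healthy reference cohort
#'
#' Gender-specific counts, age ranges and hemoglobin/hematocrit moments,
#' plus shared MCV/MCHC/RDW moments (mean, sd), of the 45-donor reference
#' cohort (28 women aged 18-61, 17 men aged 23-51).
#' @return Nested list with `female`, `male` and `shared` components.
#' @export
table1_calibration <- function() {
  list(
    female = list(n = 28L, age_range = c(18, 61),
                  hb = c(mean = 136.6, sd = 7.67),
                  hct = c(mean = 41.4, sd = 2.69)),
    male = list(n = 17L, age_range = c(23, 51),
                hb = c(mean = 151.5, sd = 8.92),
                hct = c(mean = 46.2, sd = 3.07)),
    shared = list(mcv = c(mean = 89.6, sd = 2.58),
                  mchc = c(mean = 334, sd = 11.9),
                  rdw = c(mean = 13.2, sd = 0.51)))
}

# marker geometric means by fraction (L, M, H); orderings encode the
# fraction phenotypes: band 4.1a:b rises with cell age, reticulocyte and
# CD71 positivity mark the young L-fraction, EMA (band 3 / membrane
# surface) and forward scatter fall with density, side scatter is maximal
# in the echinocytic H-fraction, reduced thiols (mBBr, ThiolTracker)
# decline with density, oxidant production (DHR) peaks in L, and NO (DAF)
# is highest in L with H above M.
.marker_gm <- function() {
  m <- rbind(
    ratio_41ab  = c(0.6, 0.9, 1.3),
    retic_pct   = c(4.0, 0.8, 0.4),
    cd71_pct    = c(2.0, 0.3, 0.15),
    ema_gmean   = c(110, 100, 85),
    fs_gmean    = c(520, 480, 430),
    ss_gmean    = c(95, 90, 120),
    mbbr_gmean  = c(150, 120, 95),
    thiol_gmean = c(200, 160, 130),
    dhr_gmean   = c(80, 50, 45),
    daf_gmean   = c(70, 40, 55))
  colnames(m) <- c("L", "M", "H")
  m
}

.index_cols <- c("o_min", "ei_min", "o_eimax", "ei_max", "o_hyper", "area")

# per-fraction additive index offsets relative to WB, derived from the
# phenotype presets so they automatically satisfy the preset orderings
default_fraction_offsets <- function() {
  presets <- fraction_presets()
  truth <- lapply(presets, function(p) synth_curve(p)$truth)
  wb <- truth$WB
  out <- do.call(rbind, lapply(c("L", "M", "H"), function(lab) {
    tr <- truth[[lab]]
    data.frame(fraction = lab,
               o_min = tr$o_min - wb$o_min, ei_min = tr$ei_min - wb$ei_min,
               o_eimax = tr$o_eimax - wb$o_eimax, ei_max = tr$ei_max - wb$ei_max,
               o_hyper = tr$o_hyper - wb$o_hyper, area = tr$area - wb$area)
  }))
  rownames(out) <- out$fraction
  out
}

#' Cohort generator configuration
#'
#' @param n_female,n_male Donor counts per gender.
#' @param age_range_female,age_range_male Uniform age ranges (years).
#' @param calibration Hematology calibration, see [table1_calibration()].
#' @param beta_age O_hyper slope on donor age (mOsm/kg per year). The
#'   direction is positive, inferred from the reported upward trend of
#'   O_hyper with age and its positive association with RDW.
#' @param beta_water O_hyper slope on red-cell water fraction (mOsm/kg per
#'   unit fraction).
#' @param rho_rdw Correlation between RDW and the O_hyper-generating
#'   residual (positive, so O_hyper and RDW associate positively).
#' @param sigma_ohyper Residual sd of O_hyper (mOsm/kg).
#' @param ohyper_intercept Intercept of the O_hyper model (mOsm/kg); the
#'   default centers O_hyper near the whole-blood preset at the mean age of
#'   the reference cohort.
#' @param water_mean,water_sd Mean and residual sd of the latent water
#'   fraction.
#' @param water_mchc_slope Water-fraction change per g/L of MCHC (negative:
#'   denser cells carry less water).
#' @param wb_index_sd Named numeric: donor-level sd of the remaining
#'   whole-blood indices around the WB preset.
#' @param fraction_offsets Data frame of additive index offsets for L/M/H
#'   relative to WB (defaults derived from [fraction_presets()]).
#' @param fraction_index_sd Named numeric: per-fraction measurement sd
#'   added on top of the offsets.
#' @param percoll_shift Right shift (mOsm/kg) of O_min and O_hyper caused
#'   by Percoll contact and centrifugation (applied to WBP only).
#' @param marker_gm Matrix of marker geometric means (markers x L/M/H).
#' @param marker_sigma_donor Log-scale sd of the donor-level marker effect
#'   (shared across fractions within a donor, cancels in paired contrasts).
#' @param marker_sigma_within Log-scale sd of the within-donor,
#'   per-fraction marker noise.
#' @param hypochromic_range Uniform range of the hypochromic-RBC
#'   percentage; the default keeps every donor below the 5% iron-deficiency
#'   QC threshold.
#' @param seed Optional integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_female = 28L, n_male = 17L,
                          age_range_female = c(18, 61),
                          age_range_male = c(23, 51),
                          calibration = table1_calibration(),
                          beta_age = 0.3, beta_water = 300,
                          rho_rdw = 0.5, sigma_ohyper = 8,
                          ohyper_intercept = NULL,
                          water_mean = 0.65, water_sd = 0.008,
                          water_mchc_slope = -8e-4,
                          wb_index_sd = c(o_min = 2, ei_min = 0.008,
                                          o_eimax = 3, ei_max = 0.01,
                                          area = 4),
                          fraction_offsets = default_fraction_offsets(),
                          fraction_index_sd = c(o_min = 0.5, ei_min = 0.004,
                                                o_eimax = 1.5, ei_max = 0.004,
                                                o_hyper = 1.5, area = 3),
                          percoll_shift = 10,
                          marker_gm = .marker_gm(),
                          marker_sigma_donor = 0.15,
                          marker_sigma_within = 0.02,
                          hypochromic_range = c(0, 4.9),
                          seed = NULL) {
  if (n_female < 0 || n_male < 0) stop_param("donor counts must be >= 0")
  if (sigma_ohyper <= 0 || water_sd <= 0) stop_param("sds must be > 0")
  if (abs(rho_rdw) > 1) stop_param("rho_rdw must lie in [-1, 1]")
  if (any(wb_index_sd <= 0) || any(fraction_index_sd <= 0))
    stop_param("index sds must be > 0")
  if (is.null(ohyper_intercept)) {
    mean_age <- mean(c(mean(age_range_female), mean(age_range_male)))
    ohyper_intercept <- 460 - beta_age * mean_age
  }
  cfg <- list(n_female = as.integer(n_female), n_male = as.integer(n_male),
              age_range_female = age_range_female,
              age_range_male = age_range_male,
              calibration = calibration, beta_age = beta_age,
              beta_water = beta_water, rho_rdw = rho_rdw,
              sigma_ohyper = sigma_ohyper,
              ohyper_intercept = ohyper_intercept,
              water_mean = water_mean, water_sd = water_sd,
              water_mchc_slope = water_mchc_slope,
              wb_index_sd = wb_index_sd,
              fraction_offsets = fraction_offsets,
              fraction_index_sd = fraction_index_sd,
              percoll_shift = percoll_shift, marker_gm = marker_gm,
              marker_sigma_donor = marker_sigma_donor,
              marker_sigma_within = marker_sigma_within,
              hypochromic_range = hypochromic_range, seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a donor cohort with whole-blood Lorrca indices
#'
#' Ages are uniform within gender-specific ranges; hemoglobin and
#' hematocrit are gender-specific normals and MCV/MCHC/RDW shared normals
#' per the calibration; the latent water fraction couples negatively to
#' MCHC; and O_hyper follows
#' `intercept + beta_age * age + beta_water * (water - water_mean) + eps`
#' with `eps ~ N(0, sigma_ohyper^2)` and RDW correlated `rho_rdw` with the
#' standardized residual. The remaining whole-blood indices are drawn
#' around the WB preset.
#'
#' @param config A [cohort_config()].
#' @return data.frame with one row per donor: demographics, hematology,
#'   `water_fraction`, and whole-blood index columns.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop_param("config must be a cohort_config")
  n <- config$n_female + config$n_male
  if (n == 0) stop_param("empty cohort: n_female + n_male must be > 0")
  cal <- config$calibration
  with_seed(config$seed, {
    gender <- c(rep("F", config$n_female), rep("M", config$n_male))
    age <- c(stats::runif(config$n_female, config$age_range_female[1],
                          config$age_range_female[2]),
             stats::runif(config$n_male, config$age_range_male[1],
                          config$age_range_male[2]))
    hb <- ifelse(gender == "F",
                 stats::rnorm(n, cal$female$hb["mean"], cal$female$hb["sd"]),
                 stats::rnorm(n, cal$male$hb["mean"], cal$male$hb["sd"]))
    hct <- ifelse(gender == "F",
                  stats::rnorm(n, cal$female$hct["mean"], cal$female$hct["sd"]),
                  stats::rnorm(n, cal$male$hct["mean"], cal$male$hct["sd"]))
    mcv <- stats::rnorm(n, cal$shared$mcv["mean"], cal$shared$mcv["sd"])
    mchc <- stats::rnorm(n, cal$shared$mchc["mean"], cal$shared$mchc["sd"])
    water <- config$water_mean +
      config$water_mchc_slope * (mchc - cal$shared$mchc["mean"]) +
      stats::rnorm(n, 0, config$water_sd)
    water <- pmin(pmax(water, 0.551), 0.749)
    z_e <- stats::rnorm(n)
    z_r <- stats::rnorm(n)
    rdw <- cal$shared$rdw["mean"] + cal$shared$rdw["sd"] *
      (config$rho_rdw * z_e + sqrt(1 - config$rho_rdw^2) * z_r)
    o_hyper <- config$ohyper_intercept + config$beta_age * age +
      config$beta_water * (water - config$water_mean) +
      config$sigma_ohyper * z_e
    wb <- synth_curve(fraction_presets()$WB)$truth
    sdv <- config$wb_index_sd
    ei_max <- stats::rnorm(n, wb$ei_max, sdv["ei_max"])
    out <- data.frame(
      donor_id = sprintf("D%03d", seq_len(n)),
      age = age, gender = gender, hb = hb, hct = hct, mcv = mcv,
      mchc = mchc, rdw = rdw,
      hypochromic_pct = stats::runif(n, config$hypochromic_range[1],
                                     config$hypochromic_range[2]),
      water_fraction = water,
      o_min = stats::rnorm(n, wb$o_min, sdv["o_min"]),
      ei_min = stats::rnorm(n, wb$ei_min, sdv["ei_min"]),
      o_eimax = stats::rnorm(n, wb$o_eimax, sdv["o_eimax"]),
      ei_max = ei_max,
      o_hyper = o_hyper,
      ei_hyper = ei_max / 2,
      area = stats::rnorm(n, wb$area, sdv["area"]))
    rownames(out) <- NULL
    out
  })
}

#' Replica of the reference study cohort
#'
#' Exactly the reference composition: 28 women with ages uniform on
#' \[18, 61\] and 17 men on \[23, 51\], hematology drawn from the
#' calibrated normals, and hypochromic-RBC percentages uniform on
#' \[0, 4.9\] so every donor passes the < 5% iron-deficiency screen.
#'
#' @param seed Integer seed.
#' @return data.frame of donor records (no index columns).
#' @export
replica_cohort <- function(seed = NULL) {
  cohort <- simulate_cohort(cohort_config(seed = seed))
  cohort[, c("donor_id", "age", "gender", "hb", "hct", "mcv", "mchc",
             "rdw", "hypochromic_pct", "water_fraction")]
}

#' Simulate density-fraction samples for one donor
#'
#' Emits WB, WBP, L, M and H samples. WBP carries the whole-blood indices
#' with `percoll_shift` added to O_min and O_hyper only (the
#' centrifugation/Percoll swelling artifact); L/M/H add the phenotype
#' offsets plus per-fraction measurement noise. The marker panel is drawn
#' log-normally around fraction-specific geometric means with a shared
#' donor-level effect, so the expected fraction orderings hold within each
#' donor; markers are only measured on the density fractions (NA for
#' WB/WBP).
#'
#' @param donor One-row data.frame from [simulate_cohort()] (or any row
#'   with a `donor_id`; missing index columns default to the WB preset).
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return data.frame with five rows (WB, WBP, L, M, H).
#' @export
simulate_fractions <- function(donor, config = cohort_config(), seed = NULL) {
  if (!is.data.frame(donor) || nrow(donor) != 1 || is.null(donor$donor_id))
    stop_param("donor must be a one-row data.frame with a donor_id")
  wbt <- synth_curve(fraction_presets()$WB)$truth
  wb <- sapply(.index_cols, function(cn)
    if (!is.null(donor[[cn]])) donor[[cn]] else wbt[[cn]])
  with_seed(seed, {
    rows <- list()
    rows$WB <- wb
    wbp <- wb
    wbp["o_min"] <- wbp["o_min"] + config$percoll_shift
    wbp["o_hyper"] <- wbp["o_hyper"] + config$percoll_shift
    rows$WBP <- wbp
    sdv <- config$fraction_index_sd
    for (lab in c("L", "M", "H")) {
      off <- config$fraction_offsets[lab, ]
      rows[[lab]] <- sapply(.index_cols, function(cn)
        wb[[cn]] + off[[cn]] + stats::rnorm(1, 0, sdv[[cn]]))
    }
    idx <- as.data.frame(do.call(rbind, rows))
    gm <- config$marker_gm
    markers <- matrix(NA_real_, nrow = 5, ncol = nrow(gm),
                      dimnames = list(names(rows), rownames(gm)))
    donor_eff <- stats::rnorm(nrow(gm), 0, config$marker_sigma_donor)
    for (lab in c("L", "M", "H")) {
      markers[lab, ] <- gm[, lab] *
        exp(donor_eff + stats::rnorm(nrow(gm), 0, config$marker_sigma_within))
    }
    out <- cbind(
      data.frame(donor_id = donor$donor_id, fraction = names(rows)),
      idx, ei_hyper = idx$ei_max / 2, as.data.frame(markers))
    rownames(out) <- NULL
    out
  })
}

#' Curve parameters for a donor's whole-blood and fraction scans
#'
#' Bridges the cohort simulator to the curve generator: the donor's
#' whole-blood index values become the WB curve's ground-truth features;
#' WBP adds the Percoll swelling shift to O_min and O_hyper; L/M/H add the
#' phenotype offsets. Every non-WB scan receives small per-scan feature
#' jitter (`fraction_index_sd`) representing measurement-to-measurement
#' variation; the O_min jitter is kept small because the density fractions
#' share the same osmotic lysis point.
#'
#' @param donor One-row data.frame with whole-blood index columns (as from
#'   [simulate_cohort()]).
#' @param config A [cohort_config()].
#' @param fractions Which scans to parameterize.
#' @param noise_sd,grid_step Sampling settings for the curves.
#' @param seed Optional integer seed (drives the feature jitter and the
#'   per-curve noise seeds).
#' @return Named list of [curve_params()].
#' @export
donor_fraction_params <- function(donor, config = cohort_config(),
                                  fractions = c("WB", "WBP", "L", "M", "H"),
                                  noise_sd = 0.005, grid_step = 1,
                                  seed = NULL) {
  presets <- fraction_presets()
  feat <- c("o_min", "ei_min", "o_eimax", "ei_max", "o_hyper")
  wbt <- synth_curve(presets$WB)$truth
  wb <- sapply(feat, function(cn)
    if (!is.null(donor[[cn]])) donor[[cn]] else wbt[[cn]])
  sdv <- config$fraction_index_sd
  with_seed(seed, {
    out <- lapply(fractions, function(lab) {
      f <- wb
      if (lab == "WBP") {
        f["o_min"] <- f["o_min"] + config$percoll_shift
        f["o_hyper"] <- f["o_hyper"] + config$percoll_shift
      } else if (lab %in% c("L", "M", "H")) {
        off <- config$fraction_offsets[lab, ]
        for (cn in feat) f[cn] <- f[cn] + off[[cn]]
      }
      if (lab != "WB")
        for (cn in feat) f[cn] <- f[cn] + stats::rnorm(1, 0, sdv[[cn]])
      curve_params(o_min_true = f[["o_min"]], ei_min_true = f[["ei_min"]],
                   o_eimax_true = f[["o_eimax"]], ei_max_true = f[["ei_max"]],
                   o_hyper_true = f[["o_hyper"]],
                   bump_ei = presets[[lab]]$bump_ei,
                   noise_sd = noise_sd, grid_step = grid_step,
                   seed = sample.int(.Machine$integer.max - 1L, 1))
    })
    stats::setNames(out, fractions)
  })
}
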