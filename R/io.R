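# File dialects, run configuration and the end-to-end pipeline.

#' Write / read an osmoscan curve as CSV
#'
#' Dialect: comment lines `# key=value` carrying the metadata
#' (`sample_id`, `fraction`, `shear_stress_Pa`, `temperature_C`), then the
#' header `osmolality_mOsm_kg,EI`, then one data row per sample. Values
#' are written with 17 significant digits so a write/read round trip is
#' bit-exact. The reader tolerates missing metadata lines (defaults are
#' applied with a warning).
#'
#' @param curve An [osmoscan_curve()].
#' @param path Target file.
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv`
#'   an `osmoscan_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id=%s", curve$sample_id),
    sprintf("# fraction=%s", curve$fraction),
    sprintf("# shear_stress_Pa=%s", formatC(curve$shear_stress_Pa, format = "g", digits = 17)),
    sprintf("# temperature_C=%s", formatC(curve$temperature_C, format = "g", digits = 17)),
    "osmolality_mOsm_kg,EI",
    sprintf("%s,%s",
            formatC(curve$osmolality, format = "g", digits = 17),
            formatC(curve$ei, format = "g", digits = 17))), con)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    i <- i + 1L
  }
  if (i > length(lines) || trimws(lines[i]) != "osmolality_mOsm_kg,EI")
    stop_format("malformed curve CSV header at line ", i,
                ": expected 'osmolality_mOsm_kg,EI'")
  body <- lines[(i + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop_format("malformed data row at line ",
                i + which(lengths(parts) != 2)[1])
  o <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(o) || anyNA(e))
    stop_format("non-numeric cell at line ", i + which(is.na(o) | is.na(e))[1])
  need <- setdiff(c("sample_id", "fraction", "shear_stress_Pa", "temperature_C"),
                  names(meta))
  if (length(need))
    warning("curve CSV missing metadata (defaults applied): ",
            paste(need, collapse = ", "))
  fr <- meta$fraction %||% NA_character_
  if (identical(fr, "NA")) fr <- NA_character_
  osmoscan_curve(o, e,
                 sample_id = meta$sample_id %||% "sample",
                 fraction = fr,
                 shear_stress_Pa = as.numeric(meta$shear_stress_Pa %||% 30),
                 temperature_C = as.numeric(meta$temperature_C %||% 37))
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run with documented defaults.
#' Unknown keys are rejected by name.
#'
#' @param extraction Extraction settings, see [extract_config()].
#' @param cohort Cohort settings, see [cohort_config()].
#' @param alpha Test level for gates and significance calls.
#' @param lo_q,hi_q Reference-interval quantiles.
#' @param min_n Minimum stratum size for reference intervals (the default
#'   suits a pilot-sized cohort split into age decades).
#' @param pixel_size,min_area_px,binwidth Morphometry settings.
#' @param curve_noise_sd EI noise of the simulated scans.
#' @param p_adjust `"none"` (default; no correction is applied) or
#'   `"holm"` to add Holm-adjusted p-values to the fraction comparisons.
#' @param seed Global seed; all stage substreams derive from it.
#' @param out_dir Output directory for [run_pipeline()]. Unknown keys are
#'   rejected with an error naming the key.
#' @return Object of class `run_config`.
#' @export
run_config <- function(extraction = extract_config(),
                       cohort = cohort_config(),
                       alpha = 0.05, lo_q = 0.025, hi_q = 0.975, min_n = 5,
                       pixel_size = 1, min_area_px = 50, binwidth = 500,
                       curve_noise_sd = 0.005, p_adjust = c("none", "holm"),
                       seed = 1L, out_dir = tempfile("osmoscan_run")) {
  p_adjust <- match.arg(p_adjust)
  cfg <- list(extraction = extraction, cohort = cohort, alpha = alpha,
              lo_q = lo_q, hi_q = hi_q, min_n = min_n,
              pixel_size = pixel_size, min_area_px = min_area_px,
              binwidth = binwidth, curve_noise_sd = curve_noise_sd,
              p_adjust = p_adjust,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# reject unknown keys by name (run_config has no ... in its formals on
# purpose: R itself raises `unused argument (<key> = ...)`)

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("pipeline stage '", name, "' failed: ",
                               conditionMessage(e)),
                        class = c("osmoscan_pipeline_error", class(e))))
  })
}

#' Run the full simulate - extract - analyze pipeline
#'
#' Generates a replica cohort, synthesizes per-donor osmoscan curves for
#' whole blood, mock-Percoll-treated blood and the three density
#' fractions, extracts the Lorrca indices from every curve, applies the
#' hypochromic QC filter, fits `index ~ age + gender` for each index on
#' the whole-blood values, runs the gated paired comparisons for every
#' fraction pair and WB vs WBP, and computes O_hyper reference intervals
#' by age decade. All tables are written as CSV plus a JSON manifest; the
#' run is fully reproducible from the global seed.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- substream_seeds(config$seed, c("cohort", "curves", "markers"))
  ccfg <- config$cohort
  ccfg$seed <- unname(seeds["cohort"])
  cohort <- stage("simulate_cohort", simulate_cohort(ccfg))
  qc <- stage("qc_filter", qc_filter(cohort))
  cohort <- qc$cohort

  curve_seeds <- substream_seeds(seeds["curves"], cohort$donor_id)
  idx_tab <- stage("extract_indices", do.call(rbind, lapply(
    seq_len(nrow(cohort)), function(i) {
      donor <- cohort[i, ]
      params <- donor_fraction_params(donor, ccfg,
                                      noise_sd = config$curve_noise_sd,
                                      seed = unname(curve_seeds[donor$donor_id]))
      do.call(rbind, lapply(names(params), function(lab) {
        cv <- synth_curve(params[[lab]],
                          sample_id = paste0(donor$donor_id, "_", lab),
                          fraction = lab)
        ix <- extract_indices(cv$curve, config$extraction)
        cbind(data.frame(donor_id = donor$donor_id, fraction = lab),
              indices_to_df(list(ix)))
      }))
    })))

  wb_idx <- idx_tab[idx_tab$fraction == "WB", ]
  model_cohort <- merge(cohort[, c("donor_id", "age", "gender")],
                        wb_idx, by = "donor_id")
  index_cols <- c("o_min", "ei_min", "o_eimax", "ei_max", "o_hyper",
                  "ei_hyper", "area")
  models <- stage("fit_index_model", do.call(rbind, lapply(
    index_cols, function(ix) {
      fm <- fit_index_model(model_cohort, ix)
      cf <- fm$coefficients
      cf$index <- ix
      cf
    })))

  pairs <- list(c("L", "M"), c("M", "H"), c("L", "H"), c("WB", "WBP"))
  frac_tests <- stage("paired_compare", do.call(rbind, lapply(
    pairs, function(pr) {
      a <- idx_tab[idx_tab$fraction == pr[1], ]
      b <- idx_tab[idx_tab$fraction == pr[2], ]
      b <- b[match(a$donor_id, b$donor_id), ]
      do.call(rbind, lapply(index_cols, function(ix) {
        r <- paired_compare(a[[ix]], b[[ix]], alpha = config$alpha)
        r$pair <- paste(pr, collapse = ":")
        r$index <- ix
        r
      }))
    })))

  if (config$p_adjust == "holm")
    frac_tests$p_holm <- stats::p.adjust(frac_tests$p_value, method = "holm")

  decade <- paste0(floor(model_cohort$age / 10) * 10, "s")
  ri <- stage("reference_interval",
              reference_interval(model_cohort$o_hyper, decade,
                                 lo_q = config$lo_q, hi_q = config$hi_q,
                                 min_n = config$min_n))

  files <- c(cohort = "cohort.csv", indices = "indices.csv",
             models = "index_models.csv", fraction_tests = "fraction_tests.csv",
             reference_intervals = "reference_intervals.csv")
  utils::write.csv(cohort, file.path(config$out_dir, files["cohort"]), row.names = FALSE)
  utils::write.csv(idx_tab, file.path(config$out_dir, files["indices"]), row.names = FALSE)
  utils::write.csv(models, file.path(config$out_dir, files["models"]), row.names = FALSE)
  utils::write.csv(frac_tests, file.path(config$out_dir, files["fraction_tests"]), row.names = FALSE)
  utils::write.csv(ri, file.path(config$out_dir, files["reference_intervals"]), row.names = FALSE)

  manifest <- list(
    package = "osmoscan",
    version = tryCatch(as.character(utils::packageVersion("osmoscan")),
                       error = function(e) "dev"),
    seed = config$seed,
    substreams = as.list(seeds),
    n_donors = nrow(cohort),
    n_curves = nrow(idx_tab),
    qc_dropped = nrow(qc$flags),
    qc_flagged_donors = qc$flags$donor_id,
    curve_qc_flags = sum(nzchar(idx_tab$qc_flags)),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
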