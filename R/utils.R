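# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream. With `seed = NULL` the expression runs on the
#' current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive named substream seeds from one global seed
#'
#' Every stage of the pipeline draws from its own integer seed derived
#' deterministically from the global one, so stages can be re-run in
#' isolation. Seeds stay below 2^31.
#' @noRd
substream_seeds <- function(seed, names) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(names))
    stats::setNames(s, names)
  })
}

# Centered moving average of odd width, shrinking symmetrically at the ends:
# point i is averaged over i +/- min(halfwidth, distance to either end).
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

# Linear interpolation of y at x0 on an (x, y) grid; x strictly increasing.
interp_at <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, rule = 2, ties = "ordered")$y
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("osmoscan_param_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("osmoscan_format_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
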