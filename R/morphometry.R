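# Per-cell morphometry from labeled segmentation masks.
#
# Upstream single-cell segmentation (e.g. a Mask R-CNN) yields an integer
# raster in which 0 is background and each positive label one cell. From
# the pixel set of each cell we report the projected area and the
# moment-equivalent ellipse axes; "sphericity" is the shortest-to-longest
# diameter ratio of that ellipse (1 = circular). A synthetic ellipse-mask
# generator provides an exact oracle for these measurements.

#' Labeled segmentation mask
#'
#' @param pixels Integer matrix; 0 = background, k >= 1 = cell k.
#' @param pixel_size Physical pixel edge length (micrometers per pixel).
#' @return Object of class `labeled_mask`.
#' @export
labeled_mask <- function(pixels, pixel_size = 1) {
  if (!is.matrix(pixels)) stop_format("mask pixels must be a matrix")
  if (any(pixels != round(pixels)) || any(pixels < 0))
    stop_format("mask must contain non-negative integer labels")
  if (pixel_size <= 0) stop_param("pixel_size must be > 0")
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 pixel_size = pixel_size),
            class = "labeled_mask")
}

#' Measure per-cell morphology from a labeled mask
#'
#' For every label: projected area (pixel count times `pixel_size^2`),
#' centroid, and the major/minor axes of the moment-equivalent ellipse
#' (axis length = 4 sqrt(eigenvalue) of the second central moment matrix,
#' with the 1/12 per-pixel variance correction). Sphericity is
#' minor/major. Components below `min_area_px` pixels are dropped (count
#' returned as an attribute); cells touching the image border are flagged
#' `border = TRUE` and should be excluded from aggregates, since their
#' truncated outlines bias area histograms.
#'
#' @param mask A [labeled_mask()].
#' @param min_area_px Minimum component size in pixels.
#' @return data.frame with one row per retained cell: `label`, `area`,
#'   `major_axis`, `minor_axis`, `sphericity`, `centroid_x`, `centroid_y`,
#'   `border`. Attribute `n_dropped` counts removed small components.
#' @export
measure_cells <- function(mask, min_area_px = 50) {
  if (!inherits(mask, "labeled_mask")) mask <- labeled_mask(mask)
  px <- mask$pixels
  ps <- mask$pixel_size
  labs <- sort(unique(px[px > 0]))
  rows <- vector("list", length(labs))
  n_dropped <- 0L
  for (k in seq_along(labs)) {
    idx <- which(px == labs[k], arr.ind = TRUE)
    npix <- nrow(idx)
    if (npix < min_area_px) { n_dropped <- n_dropped + 1L; next }
    border <- any(idx[, 1] == 1 | idx[, 1] == nrow(px) |
                    idx[, 2] == 1 | idx[, 2] == ncol(px))
    x <- idx[, 2]; y <- idx[, 1]
    cx <- mean(x); cy <- mean(y)
    # second central moments with the per-pixel 1/12 variance term
    mu20 <- mean((x - cx)^2) + 1 / 12
    mu02 <- mean((y - cy)^2) + 1 / 12
    mu11 <- mean((x - cx) * (y - cy))
    ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
    major <- 4 * sqrt(max(ev[1], 0)) * ps
    minor <- 4 * sqrt(max(ev[2], 0)) * ps
    rows[[k]] <- data.frame(
      label = labs[k], area = npix * ps^2, major_axis = major,
      minor_axis = minor,
      sphericity = if (major > 0) minor / major else 1,
      centroid_x = cx, centroid_y = cy, border = border)
  }
  out <- if (all(vapply(rows, is.null, TRUE))) {
    data.frame(label = integer(0), area = numeric(0), major_axis = numeric(0),
               minor_axis = numeric(0), sphericity = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               border = logical(0))
  } else do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Histogram of projected cell areas
#'
#' Left-closed, right-open bins `[k b, (k+1) b)` from 0 through the
#' maximal area; counts sum to the number of cells.
#'
#' @param shapes data.frame from [measure_cells()] (uses the `area`
#'   column).
#' @param binwidth Bin width in area units.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
area_histogram <- function(shapes, binwidth = 500) {
  if (binwidth <= 0) stop_param("binwidth must be > 0")
  areas <- shapes$area
  if (length(areas) == 0) stop_param("shapes must be non-empty")
  nbin <- floor(max(areas) / binwidth) + 1L
  bin <- findInterval(areas, seq(0, nbin * binwidth, by = binwidth),
                      rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = nbin)
  data.frame(bin_lo = (seq_len(nbin) - 1) * binwidth,
             bin_hi = seq_len(nbin) * binwidth,
             count = counts)
}

# pixel rows/cols covered by a rotated ellipse; centers at integer
# coordinates (row, col)
ellipse_pixels <- function(cy, cx, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cy - a - 1)); r1 <- min(nr, ceiling(cy + a + 1))
  c0 <- max(1L, floor(cx - a - 1)); c1 <- min(nc, ceiling(cx + a + 1))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  gr <- expand.grid(row = r0:r1, col = c0:c1)
  dx <- gr$col - cx
  dy <- gr$row - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  cbind(row = gr$row[inside], col = gr$col[inside])
}

#' Generate a synthetic labeled mask of non-overlapping ellipses
#'
#' Places `n_cells` rotated ellipses with sampled areas and axis ratios by
#' rejection sampling, leaving at least a one-pixel gap between cells and
#' the border. Returns the per-cell ground truth, making the mask an exact
#' oracle for [measure_cells()].
#'
#' @param n_cells Number of cells.
#' @param area_sampler Function `n -> areas` in px^2.
#' @param sphericity_sampler Function `n -> axis ratios` in (0, 1\].
#' @param image_shape `c(rows, cols)` of the raster.
#' @param pixel_size Micrometers per pixel stored on the mask.
#' @param seed Integer seed.
#' @param max_attempts Placement attempts per cell before a packing error.
#' @return List with `mask` (a [labeled_mask()]) and `truth` (data.frame
#'   of `label`, `area` in px^2, `sphericity`, `theta`, centroid).
#' @export
synth_mask <- function(n_cells,
                       area_sampler = function(n) stats::runif(n, 900, 1600),
                       sphericity_sampler = function(n) stats::runif(n, 0.5, 0.95),
                       image_shape = c(512, 512), pixel_size = 1,
                       seed = NULL, max_attempts = 200) {
  nr <- image_shape[1]; nc <- image_shape[2]
  px <- matrix(0L, nr, nc)
  if (n_cells == 0)
    return(list(mask = labeled_mask(px, pixel_size),
                truth = data.frame(label = integer(0), area = numeric(0),
                                   sphericity = numeric(0), theta = numeric(0),
                                   centroid_x = numeric(0), centroid_y = numeric(0))))
  with_seed(seed, {
    areas <- area_sampler(n_cells)
    sph <- sphericity_sampler(n_cells)
    if (sum(areas) > 0.4 * nr * nc)
      stop(errorCondition(
        "packing infeasible: requested total cell area exceeds 40% of the image; use a larger image",
        class = c("osmoscan_packing_error", "error")))
    truth <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
      a <- sqrt(areas[k] / (pi * sph[k]))
      b <- sph[k] * a
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        theta <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, a + 2, nr - a - 2)
        cx <- stats::runif(1, a + 2, nc - a - 2)
        # 1-px clearance: test an enlarged footprint before committing
        guard <- ellipse_pixels(cy, cx, a + 1.5, b + 1.5, theta, nr, nc)
        if (any(px[guard] != 0L)) next
        cell <- ellipse_pixels(cy, cx, a, b, theta, nr, nc)
        px[cell] <- k
        truth[[k]] <- data.frame(label = k, area = pi * a * b,
                                 sphericity = sph[k], theta = theta,
                                 centroid_x = cx, centroid_y = cy)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(errorCondition(
          sprintf("packing failed for cell %d after %d attempts; use a larger image",
                  k, max_attempts),
          class = c("osmoscan_packing_error", "error")))
    }
    list(mask = labeled_mask(px, pixel_size), truth = do.call(rbind, truth))
  })
}

#' Compare morphology metrics across fractions
#'
#' Aggregates per-cell measurements to per-donor means of area and
#' sphericity within each fraction (border cells excluded), then runs the
#' normality-gated paired comparison for every fraction pair and metric.
#'
#' @param cells data.frame with columns `donor_id`, `fraction`, `area`,
#'   `sphericity` (and optionally `border`).
#' @param fractions Fraction labels to compare (default L, M, H).
#' @param alpha Shapiro-Wilk gate level.
#' @return data.frame: one [stat_result()] row per (pair, metric), plus
#'   `pair` and `metric` columns. Attribute `donor_means` holds the
#'   aggregated table.
#' @export
compare_fraction_morphology <- function(cells, fractions = c("L", "M", "H"),
                                        alpha = 0.05) {
  need <- c("donor_id", "fraction", "area", "sphericity")
  if (!all(need %in% names(cells)))
    stop_format("cells must have columns: ", paste(need, collapse = ", "))
  if (!is.null(cells$border)) cells <- cells[!cells$border, , drop = FALSE]
  cells <- cells[cells$fraction %in% fractions, , drop = FALSE]
  agg <- stats::aggregate(cells[, c("area", "sphericity")],
                          by = list(donor_id = cells$donor_id,
                                    fraction = cells$fraction), mean)
  donors <- unique(agg$donor_id)
  for (f in fractions) {
    have <- agg$donor_id[agg$fraction == f]
    if (!setequal(have, donors))
      stop_param("pairing error: fraction ", f, " missing for donor(s) ",
                 paste(setdiff(donors, have), collapse = ", "))
  }
  pairs <- utils::combn(fractions, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(c("area", "sphericity"), function(metric) {
      xa <- agg[agg$fraction == pr[1], ]
      xb <- agg[agg$fraction == pr[2], ]
      xb <- xb[match(xa$donor_id, xb$donor_id), ]
      r <- paired_compare(xa[[metric]], xb[[metric]], alpha = alpha)
      r$pair <- paste(pr, collapse = ":")
      r$metric <- metric
      r
    }))
  }))
  attr(out, "donor_means") <- agg
  out
}

#' Read / write a labeled mask as 16-bit TIFF or 8-bit PNG
#'
#' Labels are stored as gray values (16-bit for TIFF, 8-bit for PNG, i.e.
#' at most 255 cells per PNG image); `read_mask` restores the integer
#' raster.
#'
#' @param mask A [labeled_mask()].
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size Micrometers per pixel to attach on read.
#' @return `write_mask` returns `path` invisibly; `read_mask` a
#'   [labeled_mask()].
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(mask$pixels) > 65535) stop_param("labels exceed 16-bit range")
    tiff::writeTIFF(mask$pixels / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(mask$pixels) > 255)
      stop_param("labels exceed the 8-bit PNG range; use TIFF")
    png::writePNG(mask$pixels / 255, path)
  } else stop_format("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop_format("unsupported mask format: .", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  depth <- if (ext == "png") 255 else 65535
  labeled_mask(matrix(as.integer(round(img * depth)), nrow(img)), pixel_size)
}
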