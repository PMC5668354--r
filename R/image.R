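#' Midplane image container
#'
#' A single- or multi-channel fluorescence (or DIC) image taken at the
#' cross-sectional midplane of a confined cell, with its physical pixel size.
#' Channels are numeric matrices indexed `[row, col]` with the origin at the
#' top-left; reported coordinates are 0-based.
#'
#' @param channels Named list of numeric matrices of identical dimensions,
#'   finite and non-negative (e.g. `myosin`, `actin`, `membrane`, `dna`).
#' @param pixel_size Physical pixel size in um/px.
#' @return An object of class `midplane_image`.
#' @export
midplane_image <- function(channels, pixel_size) {
  if (is.matrix(channels)) channels <- list(signal = channels)
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort("`channels` must be a named list of matrices.",
          class = "mitomech_invalid_input")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) {
    abort("all channels must share the same dimensions.",
          class = "mitomech_invalid_input")
  }
  ok <- vapply(channels, function(m) all(is.finite(m)) && all(m >= 0), TRUE)
  if (!all(ok)) {
    abort("intensities must be finite and non-negative.",
          class = "mitomech_invalid_input")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/px).",
          class = "mitomech_invalid_input")
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "midplane_image")
}

#' @export
print.midplane_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<midplane_image> %d x %d px, %g um/px; channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Segment the cell at the midplane
#'
#' Standard parameter-light segmentation: Gaussian smoothing, global Otsu
#' threshold, largest connected component, hole filling. The midplane
#' cross-sectional area is the mask pixel count times the pixel area.
#'
#' @param image A [midplane_image()].
#' @param channel Channel to segment on (name or index; default first).
#' @param sigma Smoothing sigma in pixels (default 1).
#' @return A list of class `segmentation_result` with elements `mask` (logical
#'   matrix), `A_m_um2`, `centroid` (0-based `(row, col)`), and `boundary`
#'   (closed polygon of 0-based `(row, col)` coordinates).
#' @export
segment_midplane <- function(image, channel = 1, sigma = 1) {
  stopifnot(inherits(image, "midplane_image"))
  m <- image$channels[[channel]]
  if (is.null(m)) {
    abort("channel not found.", class = "mitomech_invalid_input")
  }
  sm <- EBImage::gblur(m, sigma = sigma)
  rng <- range(sm)
  if (rng[2] <= rng[1]) {
    abort("no cell found: image is flat.", class = "mitomech_no_cell")
  }
  sm01 <- (sm - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(sm01), range = c(0, 1))
  fg <- sm01 > thr
  if (!any(fg)) {
    abort("no cell found: empty foreground.", class = "mitomech_no_cell")
  }
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  counts <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(counts)
  mask <- EBImage::fillHull(lab == keep)
  mask_m <- matrix(as.logical(EBImage::imageData(mask)), nrow = nrow(m))
  idx <- which(mask_m, arr.ind = TRUE)
  centroid <- c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
  contour <- EBImage::ocontour(mask)[[1]]   # (first-dim, second-dim), 0-based
  boundary <- rbind(contour, contour[1, , drop = FALSE])
  colnames(boundary) <- c("row", "col")
  structure(list(mask = mask_m,
                 A_m_um2 = nrow(idx) * image$pixel_size^2,
                 centroid = centroid,
                 boundary = boundary),
            class = "segmentation_result")
}

# Nearest-pixel intensity lookup at fractional 0-based (row, col); NA outside.
sample_intensity <- function(m, row, col) {
  i <- round(row) + 1L
  j <- round(col) + 1L
  ok <- i >= 1L & i <= nrow(m) & j >= 1L & j <= ncol(m)
  out <- rep(NA_real_, length(i))
  out[ok] <- m[cbind(i[ok], j[ok])]
  out
}

# Radius of the mask edge along a ray from the centroid (in px), by marching
# outward in half-pixel steps until the ray leaves the mask.
ray_boundary_radius <- function(mask, centroid, theta) {
  rmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  steps <- seq(0, rmax, by = 0.5)
  rr <- centroid[1] + steps * sin(theta)
  cc <- centroid[2] + steps * cos(theta)
  inside <- sample_intensity(mask * 1, rr, cc)
  inside[is.na(inside)] <- 0
  out <- which(inside < 0.5)
  if (length(out) == 0L || out[1] == 1L) return(NA_real_)
  steps[out[1] - 1L]
}

#' Cortex-to-cytoplasm localization ratio
#'
#' Quantifies cortical enrichment of a fluorescence marker at the cell
#' midplane (the myosin/actin localization ratio, MLR/ALR). Rays are cast from
#' the cell centroid; per ray the cortex sample is the peak intensity within
#' `band_um` of the segmentation boundary crossing. The cytoplasm reference is
#' the median intensity over the 30-60% normalized-radius annulus and the
#' background the median intensity outside the mask dilated by `2 * band_um`.
#' The ratio is the mean over rays of
#' `(cortex - background) / (cytoplasm - background)`.
#'
#' @param image A [midplane_image()].
#' @param seg A [segment_midplane()] result.
#' @param channel Channel to quantify (name or index).
#' @param n_rays Number of rays (default 72; minimum 8).
#' @param band_um Half-width of the cortex search band in um (default 0.7).
#' @return A one-row tibble: `ratio`, `cortex_mean`, `cytoplasm_mean`,
#'   `background`, `n_rays`.
#' @export
cortical_ratio <- function(image, seg, channel = 1, n_rays = 72, band_um = 0.7) {
  stopifnot(inherits(image, "midplane_image"),
            inherits(seg, "segmentation_result"))
  if (n_rays < 8) {
    abort("`n_rays` must be at least 8.", class = "mitomech_invalid_input")
  }
  m <- image$channels[[channel]]
  if (is.null(m)) abort("channel not found.", class = "mitomech_invalid_input")
  band_px <- band_um / image$pixel_size
  mask <- seg$mask
  ctr <- seg$centroid

  thetas <- seq(0, 2 * pi, length.out = n_rays + 1L)[seq_len(n_rays)]
  radii <- vapply(thetas, function(th) ray_boundary_radius(mask, ctr, th), 0)
  valid <- is.finite(radii)
  if (!any(valid)) {
    abort("degenerate segmentation: no boundary crossings found.",
          class = "mitomech_degenerate_signal")
  }

  # cortex: per-ray peak within +/- band of the boundary crossing
  cortex <- vapply(which(valid), function(i) {
    th <- thetas[i]
    ss <- seq(max(radii[i] - band_px, 0), radii[i] + band_px, by = 0.25)
    vals <- sample_intensity(m, ctr[1] + ss * sin(th), ctr[2] + ss * cos(th))
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }, 0)
  cortex <- cortex[is.finite(cortex)]

  # cytoplasm: median over the 30-60% normalized-radius annulus
  idx <- which(mask, arr.ind = TRUE)
  dr <- idx[, 1] - 1 - ctr[1]
  dc <- idx[, 2] - 1 - ctr[2]
  dist <- sqrt(dr^2 + dc^2)
  ang <- atan2(dr, dc) %% (2 * pi)
  # interpolate the per-ray boundary radius at each pixel's angle
  ord_th <- c(thetas[valid], thetas[valid][1] + 2 * pi)
  ord_r <- c(radii[valid], radii[valid][1])
  r_at <- stats::approx(ord_th, ord_r, xout = ang, rule = 2)$y
  rel <- dist / r_at
  cyto_px <- m[cbind(idx[, 1], idx[, 2])][rel >= 0.3 & rel <= 0.6]
  if (length(cyto_px) == 0L) {
    abort("degenerate segmentation: empty cytoplasm annulus.",
          class = "mitomech_degenerate_signal")
  }
  cytoplasm <- median(cyto_px)

  # background: outside the mask dilated by 2*band
  brush_r <- max(1L, ceiling(2 * band_px))
  brush <- EBImage::makeBrush(2L * brush_r + 1L, shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(mask * 1), brush)
  outside <- m[as.logical(EBImage::imageData(dil)) == FALSE]
  background <- if (length(outside)) median(outside) else 0

  if (cytoplasm - background <= 0) {
    abort("degenerate signal: cytoplasm does not exceed background.",
          class = "mitomech_degenerate_signal")
  }
  ratios <- (cortex - background) / (cytoplasm - background)
  tibble(ratio = mean(ratios),
         cortex_mean = mean(cortex),
         cytoplasm_mean = cytoplasm,
         background = background,
         n_rays = length(cortex))
}

#' Quantify a midplane image across channels
#'
#' Convenience wrapper: segments on one channel, then computes the
#' cortex-to-cytoplasm ratio for each requested channel, returning one tidy
#' row per channel.
#'
#' @param image A [midplane_image()].
#' @param channels Channels to quantify (default: all).
#' @param seg_channel Channel to segment on (default first).
#' @param cell_id Identifier copied into the output.
#' @inheritParams cortical_ratio
#' @return A tibble with columns `cell_id`, `channel`, `A_m_um2`, `ratio`,
#'   `cortex_mean`, `cytoplasm_mean`, `background`.
#' @export
quantify_midplane <- function(image, channels = NULL, seg_channel = 1,
                              cell_id = NA_character_, n_rays = 72,
                              band_um = 0.7) {
  stopifnot(inherits(image, "midplane_image"))
  channels <- channels %||% names(image$channels)
  seg <- segment_midplane(image, seg_channel)
  purrr::map_dfr(channels, function(ch) {
    dplyr::bind_cols(
      tibble(cell_id = cell_id, channel = ch, A_m_um2 = seg$A_m_um2),
      cortical_ratio(image, seg, ch, n_rays = n_rays, band_um = band_um)
    )
  })
}

#' Read and write midplane TIFF images
#'
#' Multi-channel images are stored as multi-page TIFF (one page per channel),
#' 16-bit; intensities are integer counts in `[0, 65535]`.
#'
#' @param path File path.
#' @param pixel_size Pixel size in um/px (not stored in the TIFF; supplied by
#'   the caller, typically from the metadata table).
#' @param channel_labels Channel names, one per page.
#' @param image A [midplane_image()] to write.
#' @return `read_midplane_tiff()` returns a [midplane_image()];
#'   `write_midplane_tiff()` returns `path` invisibly.
#' @name tiff_io
NULL

#' @rdname tiff_io
#' @export
read_midplane_tiff <- function(path, pixel_size, channel_labels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) round(p * 65535))
  labels <- channel_labels %||% paste0("ch", seq_along(pages))
  midplane_image(setNames(pages, labels), pixel_size)
}

#' @rdname tiff_io
#' @export
write_midplane_tiff <- function(image, path) {
  stopifnot(inherits(image, "midplane_image"))
  pages <- lapply(image$channels, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L)
  invisible(path)
}
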