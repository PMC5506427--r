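#' Masked intensity features
#'
#' `mean_pixel()` is the mean of background-subtracted pixels within the
#' mask — the feature used to score SA-beta-gal darkness on the bright-field
#' channel (negative for cells darker than their background). `max_pixel()`
#' and `total_intensity()` are the maximum and the sum of background-
#' subtracted pixels within the mask.
#'
#' @param image Channel image (numeric matrix).
#' @param mask Logical mask of the same shape.
#' @param background Background level; computed with [background_level()]
#'   when `NULL`.
#' @return Scalar feature value.
#' @export
mean_pixel <- function(image, mask, background = NULL) {
  check_mask(image, mask)
  background <- background %||% background_level(image, mask)
  mean(image[mask]) - background
}

#' @rdname mean_pixel
#' @export
max_pixel <- function(image, mask, background = NULL) {
  check_mask(image, mask)
  background <- background %||% background_level(image, mask)
  max(image[mask]) - background
}

#' @rdname mean_pixel
#' @export
total_intensity <- function(image, mask, background = NULL) {
  check_mask(image, mask)
  background <- background %||% background_level(image, mask)
  sum(image[mask] - background)
}

#' Mask area and aspect ratio
#'
#' Area is the mask pixel count scaled by `pixel_size_um^2`. Aspect ratio is
#' minor/major axis length of the ellipse with the same second central
#' moments as the mask (in `[0, 1]`; `1` for masks with fewer than two
#' distinct pixel positions). Used for bright-field singlet gating and for
#' cell-size comparisons between gated populations.
#'
#' @param mask Logical mask matrix.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return Named list with `area_um2` and `aspect_ratio`.
#' @export
area_aspect <- function(mask, pixel_size_um) {
  if (!any(mask)) abort("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx) * pixel_size_um^2
  if (nrow(unique(idx)) < 2) return(list(area_um2 = area, aspect_ratio = 1))
  xy <- sweep(idx, 2, colMeans(idx))
  cxx <- mean(xy[, 1]^2); cyy <- mean(xy[, 2]^2); cxy <- mean(xy[, 1] * xy[, 2])
  tr <- cxx + cyy
  det2 <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det2, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ar <- if (l1 <= .Machine$double.eps) 1 else sqrt(max(l2, 0) / l1)
  list(area_um2 = area, aspect_ratio = ar)
}

#' Focus-quality features
#'
#' `gradient_rms()` is the root-mean-square of the central-difference
#' gradient magnitude over mask pixels (0 for a constant image; decreases
#' monotonically under Gaussian blurring). `px_contrast()` is the robust
#' Michelson-style contrast `(p95 - p5)/(p95 + p5 + eps)` of the raw pixels
#' within the mask. Both are used to gate out defocused cells.
#'
#' @inheritParams mean_pixel
#' @return Scalar feature value.
#' @export
gradient_rms <- function(image, mask) {
  check_mask(image, mask)
  n <- nrow(image); m <- ncol(image)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  if (n >= 3) gx[2:(n - 1), ] <- (image[3:n, ] - image[1:(n - 2), ]) / 2
  if (n >= 2) { gx[1, ] <- image[2, ] - image[1, ]; gx[n, ] <- image[n, ] - image[n - 1, ] }
  if (m >= 3) gy[, 2:(m - 1)] <- (image[, 3:m] - image[, 1:(m - 2)]) / 2
  if (m >= 2) { gy[, 1] <- image[, 2] - image[, 1]; gy[, m] <- image[, m] - image[, m - 1] }
  sqrt(mean((gx^2 + gy^2)[mask]))
}

#' @rdname gradient_rms
#' @param eps Stabiliser in the denominator.
#' @export
px_contrast <- function(image, mask, eps = 1e-6) {
  check_mask(image, mask)
  q <- quantile(image[mask], c(0.05, 0.95), names = FALSE)
  (q[2] - q[1]) / (q[2] + q[1] + eps)
}

#' Parameters for nuclear focus (spot) counting
#'
#' @param spot_radius_px Structuring-element radius of the white top-hat
#'   filter; spots wider than this are suppressed.
#' @param k Threshold in units of the robust noise scale (1.4826 x MAD of
#'   the top-hat response inside the nucleus).
#' @param min_area_px Minimum connected-component area kept as a spot.
#' @return List of class `spot_params`.
#' @export
spot_params <- function(spot_radius_px = 3, k = 5, min_area_px = 2) {
  structure(list(spot_radius_px = spot_radius_px, k = k,
                 min_area_px = min_area_px), class = "spot_params")
}

#' Count bright nuclear foci
#'
#' Separates bright spots from the background inside the nucleus: white
#' top-hat filter (disc radius `spot_radius_px`), threshold at `k` times the
#' robust noise scale of the top-hat response within the nucleus, then
#' connected components of at least `min_area_px` pixels. Touching foci
#' merge into one spot (no watershed splitting); counts are deterministic.
#'
#' @param foci Focus-marker channel image (e.g. gamma-H2AX).
#' @param nucleus Nuclear mask from [nuclear_mask()].
#' @param params A [spot_params()] list.
#' @return List with `count` (integer) and `mask` (logical spot mask,
#'   a subset of `nucleus`).
#' @export
spot_count <- function(foci, nucleus, params = spot_params()) {
  check_mask(foci, nucleus)
  # EBImage grayscale morphology works on [0,1]; normalise and restore scale
  rng <- range(foci)
  scl <- max(diff(rng), 1)
  th <- as.matrix(EBImage::whiteTopHat((foci - rng[1]) / scl,
                                       disc_brush(params$spot_radius_px))) * scl
  # a 1-px erosion drops the soft nuclear rim, whose top-hat residue would
  # otherwise contribute to the noise estimate; anything stronger shrinks
  # the core so much that crowded foci corrupt the MAD scale
  core <- EBImage::erode(nucleus, disc_brush(1L))
  core <- matrix(as.logical(core), nrow(nucleus), ncol(nucleus))
  if (any(core)) nucleus <- new_mask(core, "nucleus")
  vals <- th[nucleus]
  cutoff <- params$k * mad(vals)  # mad() includes the 1.4826 consistency factor
  spots <- th > cutoff & unclass(nucleus)
  lab <- EBImage::bwlabel(spots)
  lab <- as.matrix(lab)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_area_px)
    spots <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    count <- length(keep)
  } else {
    spots <- matrix(FALSE, nrow(lab), ncol(lab))
    count <- 0L
  }
  list(count = as.integer(count), mask = new_mask(spots, "spot"))
}

#' Feature-extraction parameters
#'
#' @param sigma Gaussian smoothing sigma (px) for mask derivation.
#' @param close_radius Morphological closing radius (px) for mask derivation.
#' @param nuclear_channels Channels measured on the nuclear mask when a DAPI
#'   channel is present (nuclear senescence markers).
#' @param spot_channel Channel on which nuclear foci are counted.
#' @param spot A [spot_params()] list.
#' @return List of class `feature_params`.
#' @export
feature_params <- function(sigma = 1, close_radius = 2,
                           nuclear_channels = c("gH2AX", "HMGB1", "Ki67", "BrdU"),
                           spot_channel = "gH2AX",
                           spot = spot_params()) {
  structure(list(sigma = sigma, close_radius = close_radius,
                 nuclear_channels = nuclear_channels,
                 spot_channel = spot_channel, spot = spot),
            class = "feature_params")
}

extract_one <- function(cell, params) {
  ps <- cell$pixel_size_um
  bf <- cell$channels[["BF"]]
  cmask <- cell_mask(bf, params$sigma, params$close_radius)
  bf_bg <- background_level(bf, cmask)
  aa <- area_aspect(cmask, ps)
  row <- tibble(
    cell_id = cell$cell_id,
    sample_id = cell$sample_id,
    bf_mean_pixel = mean_pixel(bf, cmask, bf_bg),
    area_um2 = aa$area_um2,
    aspect_ratio = aa$aspect_ratio,
    gradient_rms = gradient_rms(bf, cmask),
    contrast = px_contrast(bf, cmask))

  nmask <- NULL
  if ("DAPI" %in% names(cell$channels)) {
    dapi <- cell$channels[["DAPI"]]
    nmask <- tryCatch(nuclear_mask(dapi, params$sigma, params$close_radius),
                      error = function(e) NULL)
    if (!is.null(nmask)) {
      fg <- dapi_foreground(dapi, params$sigma, params$close_radius)
      dbg <- background_level(dapi, fg)
      row$dapi_area_um2 <- sum(fg) * ps^2
      row$dapi_intensity <- total_intensity(dapi, fg, dbg)
    } else {
      row$dapi_area_um2 <- NA_real_
      row$dapi_intensity <- NA_real_
    }
  }

  for (ch in setdiff(names(cell$channels), c("BF", "DAPI"))) {
    img <- cell$channels[[ch]]
    msk <- if (ch %in% params$nuclear_channels && !is.null(nmask)) nmask else cmask
    bg <- background_level(img, msk)
    row[[paste0("mean_px_", ch)]] <- mean_pixel(img, msk, bg)
    row[[paste0("max_px_", ch)]] <- max_pixel(img, msk, bg)
    row[[paste0("intensity_", ch)]] <- total_intensity(img, msk, bg)
  }

  if (params$spot_channel %in% names(cell$channels)) {
    if (!is.null(nmask)) {
      sc <- spot_count(cell$channels[[params$spot_channel]], nmask, params$spot)
      row$spot_count <- sc$count
    } else {
      row$spot_count <- NA_integer_
    }
  }
  row
}

#' Extract per-cell scalar features
#'
#' Computes every applicable feature for one cell record or a list of them:
#' bright-field mean pixel, area, aspect ratio, focus metrics, DAPI totals,
#' per-channel mean/max/total background-subtracted intensities, and the
#' nuclear focus count. Features whose required channel is absent are
#' missing (`NA`), never zero.
#'
#' @param cells A [cell_record()] or list of them.
#' @param params A [feature_params()] list.
#' @param on_error `"abort"` (default) stops at the first failing cell;
#'   `"skip"` drops failing cells and records them in the
#'   `"failed_cells"` attribute of the result.
#' @return Tibble with one row per successfully measured cell.
#' @export
extract_features <- function(cells, params = feature_params(),
                             on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (inherits(cells, "cell_record")) cells <- list(cells)
  failed <- character(0)
  rows <- map(cells, function(cell) {
    tryCatch(extract_one(cell, params), error = function(e) {
      if (on_error == "abort")
        abort(sprintf("cell '%s': %s", cell$cell_id, conditionMessage(e)))
      failed <<- c(failed, cell$cell_id)
      NULL
    })
  })
  out <- bind_rows(compact(rows))
  attr(out, "failed_cells") <- failed
  out
}
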