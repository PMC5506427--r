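# Mask derivation. The imaging software shipped with the instrument does not
# publish its mask algorithms; these are transparent reconstructions built
# from standard operators (deviation-from-background -> Gaussian smooth ->
# Otsu -> morphological closing -> hole filling -> component selection).

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

# Label foreground objects in one channel image. Returns an integer label
# matrix (0 = background). Errors when no object rises above the noise.
segment_channel <- function(img, sigma = 1, close_radius = 2) {
  if (length(img) == 0) abort("empty image")
  border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
  bg0 <- median(border)
  dev <- abs(img - bg0)
  if (diff(range(dev)) <= .Machine$double.eps)
    abort("no cell detected: constant image")
  g <- EBImage::gblur(dev, sigma = sigma)
  th <- EBImage::otsu(EBImage::Image(g), range = range(g))
  # guard against Otsu splitting pure noise: the threshold must clear the
  # smoothed-background level (outermost two pixel rows/cols) by a robust
  # margin, otherwise there is no object above the noise
  gb <- c(g[1:2, ], g[(nrow(g) - 1):nrow(g), ], g[, 1:2], g[, (ncol(g) - 1):ncol(g)])
  crit <- median(gb) + 6 * mad(gb)
  if (th <= crit || th <= 1e-8)
    abort("no cell detected: no signal above background noise")
  m <- g > th
  m <- EBImage::closing(m, disc_brush(close_radius))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) abort("no cell detected")
  as.matrix(lab)
}

new_mask <- function(m, kind) {
  mode(m) <- "logical"
  structure(m, kind = kind)
}

largest_component <- function(lab) {
  sizes <- tabulate(lab[lab > 0])
  which.max(sizes)
}

#' Derive the whole-cell mask from a bright-field image
#'
#' Absolute deviation from the estimated background, Gaussian smoothing
#' (`sigma` px), Otsu thresholding, morphological closing (disc radius
#' `close_radius` px), hole filling, then the largest connected component.
#' Works for both dark (X-gal stained) and rim-contrast (unstained) cells
#' because the deviation image is unsigned.
#'
#' @param bf Bright-field image (numeric matrix).
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param close_radius Closing structuring-element radius in pixels.
#' @return Logical mask matrix (attribute `kind = "cell"`).
#' @export
cell_mask <- function(bf, sigma = 1, close_radius = 2) {
  lab <- segment_channel(bf, sigma = sigma, close_radius = close_radius)
  new_mask(lab == largest_component(lab), "cell")
}

#' Derive the nuclear mask from a DNA-stain image
#'
#' Same recipe as [cell_mask()] applied to the DAPI channel.
#'
#' @inheritParams cell_mask
#' @param dapi DNA-stain (DAPI) image.
#' @return Logical mask matrix (attribute `kind = "nucleus"`).
#' @export
nuclear_mask <- function(dapi, sigma = 1, close_radius = 2) {
  lab <- segment_channel(dapi, sigma = sigma, close_radius = close_radius)
  new_mask(lab == largest_component(lab), "nucleus")
}

# All DAPI-positive foreground (every component above a speck size), used for
# doublet discrimination: a two-nuclei event doubles total area and intensity
# while the largest-component nuclear mask would hide the second nucleus.
dapi_foreground <- function(dapi, sigma = 1, close_radius = 2, min_px = 16) {
  lab <- segment_channel(dapi, sigma = sigma, close_radius = close_radius)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  new_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)), "nucleus")
}

#' Estimate the local background level of a channel
#'
#' Median of the pixels outside the mask dilated by `dilate_radius` px.
#' If the dilated mask covers the whole frame, falls back to the median of
#' the one-pixel image border.
#'
#' @param image Channel image.
#' @param mask Logical mask from [cell_mask()]/[nuclear_mask()].
#' @param dilate_radius Dilation radius in pixels before exclusion.
#' @return Background level (scalar).
#' @export
background_level <- function(image, mask, dilate_radius = 3) {
  check_mask(image, mask)
  if (all(mask)) {
    outside <- numeric(0)
  } else {
    dil <- EBImage::dilate(mask, disc_brush(dilate_radius))
    outside <- image[!dil]
  }
  if (length(outside) == 0) {
    outside <- c(image[1, ], image[nrow(image), ], image[, 1], image[, ncol(image)])
    if (length(outside) == 0) abort("cannot estimate background: empty border")
  }
  median(outside)
}

check_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    abort("mask shape does not match image shape")
  if (!any(mask)) abort("empty mask")
  invisible(TRUE)
}
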