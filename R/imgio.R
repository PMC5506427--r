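#' Write a dataset of cell records to disk
#'
#' Each cell is written as one multi-page TIFF (pages = channels in the
#' declared order, unsigned 16-bit) next to a `manifest.csv` describing the
#' dataset. Pixel values are rounded to integers and clipped to the uint16
#' range `[0, 65535]`; integer images round-trip losslessly.
#'
#' @param cells List of [cell_record()] objects.
#' @param out_dir Output directory (created if absent).
#' @return The manifest as a tibble (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
write_dataset <- function(cells, out_dir) {
  if (inherits(cells, "cell_record")) cells <- list(cells)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- map(cells, function(cell) {
    validate_cell_record(cell)
    bad <- !vapply(cell$channels, function(m) all(is.finite(m)), logical(1))
    if (any(bad))
      abort(sprintf("cell '%s': non-finite pixel values in channel(s) %s",
                    cell$cell_id, paste(names(cell$channels)[bad], collapse = ",")))
    fname <- paste0(cell$cell_id, ".tif")
    pages <- map(cell$channels, function(m) {
      pmin(pmax(round(m), 0), 65535) / 65535
    })
    tiff::writeTIFF(unname(pages), file.path(out_dir, fname),
                    bits.per.sample = 16L, compression = "none")
    tibble(cell_id = cell$cell_id,
           sample_id = cell$sample_id,
           file = fname,
           channels = paste(names(cell$channels), collapse = ";"),
           pixel_size_um = cell$pixel_size_um)
  })
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` written by [write_dataset()].
#' @return Tibble with columns `cell_id`, `sample_id`, `file`, `channels`
#'   (semicolon-separated channel names in page order) and `pixel_size_um`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         cell_id = readr::col_character(),
                         sample_id = readr::col_character(),
                         file = readr::col_character(),
                         channels = readr::col_character(),
                         pixel_size_um = readr::col_double()))
  if (anyDuplicated(m$cell_id))
    abort("manifest contains duplicated cell_id values")
  m
}

#' Read a dataset of cell records
#'
#' Loads every cell listed in a manifest, in manifest order. Each cell's TIFF
#' pages are mapped to channels in the manifest-declared order and scaled
#' back to integer counts.
#'
#' @param manifest Path to `manifest.csv`, or a manifest tibble (in which
#'   case `base_dir` locates the image files).
#' @param base_dir Directory holding the TIFFs; defaults to the manifest's
#'   directory when `manifest` is a path.
#' @return List of [cell_record()] objects in manifest order.
#' @export
read_dataset <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) abort("base_dir is required with an in-memory manifest")
  purrr::pmap(manifest, function(cell_id, sample_id, file, channels,
                                 pixel_size_um, ...) {
    path <- file.path(base_dir, file)
    if (!file.exists(path))
      abort(sprintf("cell '%s': image file missing: %s", cell_id, path))
    ch_names <- strsplit(channels, ";", fixed = TRUE)[[1]]
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != length(ch_names))
      abort(sprintf("cell '%s': %d TIFF pages but %d declared channels",
                    cell_id, length(pages), length(ch_names)))
    imgs <- map(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grayscale-as-RGB
      round(p * 65535)
    })
    names(imgs) <- ch_names
    cell_record(cell_id, sample_id, imgs, pixel_size_um)
  })
}

#' Write / read a per-cell feature table
#'
#' CSV with header; numeric values round-trip at full double precision.
#' Missing features (e.g. `spot_count` for a cell without the focus channel)
#' are written as empty fields and read back as `NA`, never silently zero.
#'
#' @param table Feature table (tibble with unique `cell_id`).
#' @param path Output CSV path.
#' @return `table`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(table$cell_id))
    abort("feature table contains duplicated cell_id values")
  readr::write_csv(table, path, na = "")
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("feature table not found: %s", path))
  tb <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  if (!"cell_id" %in% names(tb)) abort("feature table lacks a cell_id column")
  tb$cell_id <- as.character(tb$cell_id)
  if ("sample_id" %in% names(tb)) tb$sample_id <- as.character(tb$sample_id)
  if (anyDuplicated(tb$cell_id))
    abort(sprintf("duplicated cell_id on read: %s",
                  paste(unique(tb$cell_id[duplicated(tb$cell_id)]), collapse = ",")))
  tb
}
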