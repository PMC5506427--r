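#' Construct a per-cell image record
#'
#' A cell record is the atomic unit flowing through the pipeline: one cell's
#' multi-channel image stack plus metadata. All channel images must share one
#' height x width; a bright-field channel named `"BF"` is always required.
#' Pixel values are non-negative camera-style counts (stored as doubles in
#' memory, unsigned 16-bit on disk).
#'
#' @param cell_id Unique cell identifier (string).
#' @param sample_id Sample the cell belongs to (string).
#' @param channels Named list of 2-D numeric matrices, one per channel.
#'   Must contain `"BF"`.
#' @param pixel_size_um Physical pixel edge length in micrometres (> 0).
#' @param ground_truth Optional named list of phenotype labels; only present
#'   for synthetic data.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(cell_id, sample_id, channels, pixel_size_um = 0.5,
                        ground_truth = NULL) {
  rec <- structure(
    list(cell_id = as.character(cell_id),
         sample_id = as.character(sample_id),
         channels = channels,
         pixel_size_um = as.numeric(pixel_size_um),
         ground_truth = ground_truth),
    class = "cell_record")
  validate_cell_record(rec)
}

#' @export
print.cell_record <- function(x, ...) {
  dims <- dim(x$channels[[1]])
  cat(sprintf("<cell_record %s | sample %s | %d channel(s): %s | %dx%d px @ %.3g um/px>\n",
              x$cell_id, x$sample_id, length(x$channels),
              paste(names(x$channels), collapse = ","),
              dims[1], dims[2], x$pixel_size_um))
  invisible(x)
}

validate_cell_record <- function(rec) {
  if (!is.list(rec$channels) || length(rec$channels) == 0 ||
      is.null(names(rec$channels)) || any(names(rec$channels) == ""))
    abort("channels must be a non-empty named list of matrices")
  if (!"BF" %in% names(rec$channels))
    abort(sprintf("cell '%s': required channel 'BF' is missing", rec$cell_id))
  dims <- lapply(rec$channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    abort(sprintf("cell '%s': all channels must be 2-D matrices", rec$cell_id))
  ref <- dims[[1]]
  same <- vapply(dims, function(d) identical(d, ref), logical(1))
  if (!all(same))
    abort(sprintf("cell '%s': channel images differ in shape", rec$cell_id))
  if (!is.numeric(rec$pixel_size_um) || length(rec$pixel_size_um) != 1 ||
      !is.finite(rec$pixel_size_um) || rec$pixel_size_um <= 0)
    abort(sprintf("cell '%s': pixel_size_um must be a single positive number",
                  rec$cell_id))
  rec
}
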