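#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gating result
#'
#' One row per sample x gate with counts, ungated tally and percent of
#' parent — the long-format report table.
#'
#' @param x A `gating_result` from [apply_gates()].
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.gating_result <- function(x, ...) x$counts

#' @rdname tidy.gating_result
#' @export
glance.gating_result <- function(x, ...) {
  tibble(n_cells = nrow(x$membership),
         n_samples = dplyr::n_distinct(x$membership$sample_id),
         n_gates = length(x$gates))
}

#' Tidy a pipeline run
#'
#' @param x A `senescan_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The run's report tibble (per sample x gate).
#' @export
tidy.senescan_run <- function(x, ...) x$report

#' @rdname tidy.senescan_run
#' @export
glance.senescan_run <- function(x, ...) {
  tibble(n_cells = nrow(x$features),
         n_samples = dplyr::n_distinct(x$features$sample_id),
         n_gates = length(x$result$gates),
         synthetic = !is.null(x$truth))
}
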