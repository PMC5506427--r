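#' Read / write a gating configuration
#'
#' YAML gating configs are an ordered list of gate entries with `name`,
#' optional `parent`, a `type` (`threshold`, `interval`, `rect2d`,
#' `boolean`, `control_threshold`, `singlet_bf`, `singlet_dapi`, `focus`)
#' and the type's parameters. The order is the evaluation order, so parents
#' and boolean members must precede their dependants. `singlet_dapi`
#' entries are placed relative to the dataset's median nucleus at run time.
#'
#' @param path YAML file path.
#' @return List of [gates] objects (with `singlet_dapi` entries left as
#'   deferred specs for [run_pipeline()] to resolve).
#' @export
read_gates <- function(path) {
  if (!file.exists(path)) abort(sprintf("gates config not found: %s", path))
  entries <- yaml::read_yaml(path)
  map(entries, gate_from_entry)
}

gate_from_entry <- function(e) {
  if (is.null(e$name) || is.null(e$type))
    abort("every gate entry needs 'name' and 'type'")
  num <- function(x, default = NULL) {
    if (is.null(x)) return(default)
    if (identical(x, ".inf") || identical(x, "Inf")) return(Inf)
    if (identical(x, "-.inf") || identical(x, "-Inf")) return(-Inf)
    as.numeric(x)
  }
  switch(e$type,
    threshold = gate_threshold(e$name, e$feature, e$direction, num(e$cutoff),
                               parent = e$parent),
    interval = gate_interval(e$name, e$feature, num(e$lo, -Inf), num(e$hi, Inf),
                             parent = e$parent),
    rect2d = gate_rect2d(e$name, e$feature_x, e$feature_y,
                         num(e$x_lo, -Inf), num(e$x_hi, Inf),
                         num(e$y_lo, -Inf), num(e$y_hi, Inf),
                         parent = e$parent),
    boolean = gate_boolean(e$name, e$op, unlist(e$members), parent = e$parent),
    control_threshold = gate_control_threshold(e$name, e$feature, e$direction,
                                               num(e$quantile), parent = e$parent),
    singlet_bf = singlet_gate_bf(e$name, num(e$min_ar, 0.6),
                                 num(e$area_lo, 50), num(e$area_hi, 5000),
                                 parent = e$parent),
    singlet_dapi = new_gate(e$name, "singlet_dapi", e$parent,
                            list(area_rel = c(num(e$area_lo_rel, 0.3),
                                              num(e$area_hi_rel, 3.5)),
                                 int_rel = c(num(e$int_lo_rel, 0.5),
                                             num(e$int_hi_rel, 1.55)))),
    focus = focus_gate(e$name, num(e$min_grms, 9), num(e$min_contrast, 0.015),
                       parent = e$parent),
    abort(sprintf("gate '%s': unknown type '%s'", e$name, e$type)))
}

resolve_table_gates <- function(gates, table) {
  map(gates, function(g) {
    if (inherits(g, "gate") && g$type == "singlet_dapi")
      singlet_gate_dapi(table, g$name, g$area_rel, g$int_rel, parent = g$parent)
    else g
  })
}

#' Assemble a pipeline run configuration
#'
#' Exactly one input source is allowed: a synthetic-population config
#' (`simulate`) or a dataset manifest path (`manifest`).
#'
#' @param simulate A [synth_config()], a plain list, or a YAML path.
#' @param manifest Path to a `manifest.csv` dataset.
#' @param gates List of [gates] objects or a gates YAML path.
#' @param control_samples Sample ids used as unstained reference.
#' @param features A [feature_params()] list.
#' @param out_dir Output directory (`NULL` = in-memory run, nothing written).
#' @param seed Seed for simulation.
#' @param n_per_sample Optional override of simulated cells per sample.
#' @param samples Optional subset of sample ids to run.
#' @param fail_frac Tolerated fraction of cells with feature-extraction
#'   failures before the run aborts.
#' @param write_images Also write the simulated TIFF dataset under
#'   `out_dir/images` (off by default; reports do not need it).
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = NULL, manifest = NULL, gates = list(),
                       control_samples = NULL, features = feature_params(),
                       out_dir = NULL, seed = 1, n_per_sample = NULL,
                       samples = NULL, fail_frac = 0.05,
                       write_images = FALSE) {
  if (is.null(simulate) == is.null(manifest))
    abort("exactly one of 'simulate' or 'manifest' must be given")
  if (is.character(simulate)) simulate <- read_synth_config(simulate)
  if (!is.null(simulate) && !inherits(simulate, "synth_config"))
    simulate <- synth_config(simulate)
  if (is.character(gates)) gates <- read_gates(gates)
  structure(list(simulate = simulate, manifest = manifest, gates = gates,
                 control_samples = control_samples, features = features,
                 out_dir = out_dir, seed = seed, n_per_sample = n_per_sample,
                 samples = samples, fail_frac = fail_frac,
                 write_images = write_images),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Orchestrates simulate/load -> feature extraction -> gating -> report.
#' Per-cell extraction failures are logged and the cell excluded; the run
#' aborts if more than `fail_frac` of cells fail. When `out_dir` is set the
#' run writes `features.csv`, `report.csv`, `run.log` and
#' `resolved_config.yaml` (plus `ground_truth.csv` for synthetic input);
#' reruns with the same config and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return A `senescan_run`: list with `features`, `truth` (or `NULL`),
#'   `result` (gating result), `report` (tibble) and `log` (character).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logln <- character(0)
  note <- function(...) logln <<- c(logln, sprintf(...))

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!is.null(config$samples)) {
      keep <- vapply(sim$samples, function(s) s$sample_id %in% config$samples,
                     logical(1))
      if (!any(keep)) abort("no configured sample matches 'samples'")
      sim$samples <- sim$samples[keep]
    }
    note("simulating population '%s' (seed %d)", sim$name, config$seed)
    gen <- generate_population(sim, seed = config$seed,
                               out_dir = if (isTRUE(config$write_images) &&
                                             !is.null(config$out_dir))
                                 file.path(config$out_dir, "images") else NULL,
                               n_per_sample = config$n_per_sample)
    cells <- gen$cells
    truth <- gen$truth
  } else {
    note("loading dataset from %s", config$manifest)
    cells <- read_dataset(config$manifest)
    if (!is.null(config$samples))
      cells <- keep(cells, function(c) c$sample_id %in% config$samples)
  }
  if (length(cells) == 0) abort("empty dataset: no cells to analyse")
  note("loaded %d cells", length(cells))

  feats <- extract_features(cells, config$features, on_error = "skip")
  failed <- attr(feats, "failed_cells")
  note("extracted features for %d cells; %d cell-level failure(s)",
       nrow(feats), length(failed))
  if (length(failed) > length(cells) * config$fail_frac)
    abort(sprintf("%d of %d cells failed feature extraction (> %.0f%% tolerance)",
                  length(failed), length(cells), 100 * config$fail_frac))

  gates <- resolve_table_gates(config$gates, feats)
  result <- apply_gates(feats, gates, control_samples = config$control_samples)
  for (g in result$gates) {
    cnt <- result$counts[result$counts$gate == g$name, ]
    note("gate %-18s: %d / %d cells (%d ungated)", g$name,
         sum(cnt$n_in_gate), sum(cnt$n_parent), sum(cnt$ungated))
  }

  areas <- result$membership |>
    pivot_longer(cols = -c("cell_id", "sample_id"),
                 names_to = "gate", values_to = "member") |>
    filter(.data$member) |>
    left_join(select(feats, "cell_id", "area_um2"), by = "cell_id") |>
    group_by(.data$sample_id, .data$gate) |>
    summarise(mean_area_um2 = mean(.data$area_um2),
              sem = sd(.data$area_um2) / sqrt(dplyr::n()), .groups = "drop")
  report <- result$counts |>
    left_join(areas, by = c("sample_id", "gate")) |>
    select("sample_id", "gate", "n_parent", "n_in_gate", "ungated",
           "percent", "mean_area_um2", "sem")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(feats, file.path(config$out_dir, "features.csv"))
    readr::write_csv(report, file.path(config$out_dir, "report.csv"))
    if (!is.null(truth))
      readr::write_csv(select(truth, -"cell_seed"),
                       file.path(config$out_dir, "ground_truth.csv"))
    yaml::write_yaml(serialize_run_config(config, result),
                     file.path(config$out_dir, "resolved_config.yaml"))
    writeLines(logln, file.path(config$out_dir, "run.log"))
  }

  structure(list(features = feats, truth = truth, result = result,
                 report = report, config = config, log = logln),
            class = "senescan_run")
}

serialize_run_config <- function(config, result = NULL) {
  gates <- if (!is.null(result)) result$gates else config$gates
  list(
    input = if (!is.null(config$simulate)) list(simulate = unclass(config$simulate))
            else list(manifest = config$manifest),
    control_samples = config$control_samples,
    seed = config$seed,
    n_per_sample = config$n_per_sample,
    samples = config$samples,
    fail_frac = config$fail_frac,
    gates = map(unname(gates), function(g) {
      out <- unclass(g)
      out[!vapply(out, is.null, logical(1))]
    }))
}

#' Reload a resolved run configuration
#'
#' Reads the `resolved_config.yaml` written by [run_pipeline()] back into a
#' [run_config()]. Control-referenced and data-placed gates were already
#' resolved to fixed cutoffs when the file was written, so replaying the
#' configuration reproduces `report.csv` exactly.
#'
#' @param path Path to a `resolved_config.yaml`.
#' @param out_dir Optional output directory for the replay.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  run_config(
    simulate = if (!is.null(y$input$simulate)) synth_config(y$input$simulate),
    manifest = y$input$manifest,
    gates = map(y$gates, gate_from_entry),
    control_samples = unlist(y$control_samples),
    out_dir = out_dir,
    seed = y$seed,
    n_per_sample = y$n_per_sample,
    samples = unlist(y$samples),
    fail_frac = y$fail_frac %||% 0.05)
}

#' @export
print.senescan_run <- function(x, ...) {
  cat(sprintf("<senescan_run: %d cells, %d gates>\n",
              nrow(x$features), length(x$result$gates)))
  print(x$report, n = 30)
  invisible(x)
}

#' Named analysis recipes
#'
#' Packaged scenario presets pairing a synthetic population with the
#' matching gating tree and control sample: `dis_fibroblasts` (etoposide-
#' induced senescent vs growing human fibroblasts, bright-field SA-beta-gal
#' gate, cell-area report), `dis_timecourse` (days after DNA damage;
#' gamma-H2AX foci, nuclear HMGB1 and Ki67 loss, combined marker gates),
#' `tumor_regression` (dissociated tumors; GFP+ tumor vs CD45+ immune
#' cells, viability gate), `lung_fibrosis` (dissociated fibrotic lung; pCK+
#' epithelial vs CD45+ immune cells, proliferation-marker combinations) and
#' `aging_tissues` (tissues from young vs old mice).
#'
#' @param name Recipe name (see [recipes()]).
#' @param ... Overrides passed to [run_config()] (e.g. `out_dir`, `seed`,
#'   `n_per_sample`, `samples`).
#' @return A [run_config()].
#' @export
recipe <- function(name, ...) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "senescan")
  if (path == "")
    abort(sprintf("unknown recipe '%s'; available: %s", name,
                  paste(recipes(), collapse = ", ")))
  spec <- yaml::read_yaml(path)
  run_config(simulate = synth_config(spec$simulate),
             gates = map(spec$gates, gate_from_entry),
             control_samples = unlist(spec$control_samples),
             ...)
}

#' @rdname recipe
#' @export
recipes <- function() {
  dir <- system.file("extdata", "presets", package = "senescan")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}
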