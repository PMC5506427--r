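#' Gate constructors
#'
#' Gates are named predicates over feature-table columns, arranged in a tree
#' via `parent`. A cell is a member of a gate iff it satisfies the predicate
#' and is a member of the parent gate; cells with missing features for a
#' gate fall out of that gate and are tallied as "ungated".
#'
#' * `gate_threshold()` — one-sided cut on a feature (`direction` `"above"`
#'   keeps values > cutoff, `"below"` keeps values < cutoff).
#' * `gate_interval()` — `lo <= feature <= hi`.
#' * `gate_rect2d()` — axis-aligned box on two features.
#' * `gate_boolean()` — `AND` / `OR` over previously defined gates, or `NOT`
#'   of a single gate (within the parent).
#' * `gate_control_threshold()` — deferred threshold whose cutoff is set at
#'   evaluation time from a control sample (see [threshold_from_control()]).
#'
#' @param name Gate name (unique within a tree).
#' @param feature,feature_x,feature_y Feature column name(s).
#' @param direction `"above"` or `"below"`.
#' @param cutoff Threshold value.
#' @param lo,hi,x_lo,x_hi,y_lo,y_hi Interval/box limits (may be `-Inf`/`Inf`).
#' @param op `"AND"`, `"OR"` or `"NOT"`.
#' @param members Names of previously defined gates combined by `op`.
#' @param quantile Control quantile for the deferred threshold (defaults to
#'   0.99 for `"above"`, 0.01 for `"below"`).
#' @param parent Parent gate name, or `NULL` for a root gate.
#' @return A list of class `gate`.
#' @name gates
NULL

new_gate <- function(name, type, parent, fields) {
  stopifnot(is.character(name), nchar(name) > 0)
  structure(c(list(name = name, type = type, parent = parent), fields),
            class = "gate")
}

#' @rdname gates
#' @export
gate_threshold <- function(name, feature, direction = c("above", "below"),
                           cutoff, parent = NULL) {
  direction <- match.arg(direction)
  new_gate(name, "threshold", parent,
           list(feature = feature, direction = direction, cutoff = cutoff))
}

#' @rdname gates
#' @export
gate_interval <- function(name, feature, lo, hi, parent = NULL) {
  if (lo > hi) abort(sprintf("gate '%s': lo > hi", name))
  new_gate(name, "interval", parent, list(feature = feature, lo = lo, hi = hi))
}

#' @rdname gates
#' @export
gate_rect2d <- function(name, feature_x, feature_y, x_lo, x_hi, y_lo, y_hi,
                        parent = NULL) {
  new_gate(name, "rect2d", parent,
           list(feature_x = feature_x, feature_y = feature_y,
                x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi))
}

#' @rdname gates
#' @export
gate_boolean <- function(name, op = c("AND", "OR", "NOT"), members,
                         parent = NULL) {
  op <- match.arg(op)
  if (op == "NOT" && length(members) != 1)
    abort(sprintf("gate '%s': NOT takes exactly one member", name))
  if (op != "NOT" && length(members) < 2)
    abort(sprintf("gate '%s': %s needs at least two members", name, op))
  new_gate(name, "boolean", parent, list(op = op, members = members))
}

#' @rdname gates
#' @export
gate_control_threshold <- function(name, feature,
                                   direction = c("above", "below"),
                                   quantile = NULL, parent = NULL) {
  direction <- match.arg(direction)
  quantile <- quantile %||% if (direction == "above") 0.99 else 0.01
  new_gate(name, "control_threshold", parent,
           list(feature = feature, direction = direction, quantile = quantile))
}

#' Set a threshold gate from a control sample
#'
#' Reproduces reference gating against unstained control cells: the cutoff
#' is a quantile of the control distribution (linear-interpolation quantile,
#' so thresholds are bit-reproducible). Direction `"above"` (fluorescence
#' positivity) defaults to the 0.99 quantile; `"below"` (SA-beta-gal
#' darkness on `bf_mean_pixel`) defaults to the 0.01 quantile.
#'
#' @param control_values Numeric feature values of the control cells
#'   (at least 50 finite values).
#' @param quantile Control quantile in (0, 1); default depends on direction.
#' @param direction `"above"` or `"below"`.
#' @param feature Feature column the gate applies to.
#' @param name Gate name.
#' @param parent Parent gate name.
#' @return A threshold [gates] object with the resolved cutoff.
#' @export
threshold_from_control <- function(control_values, quantile = NULL,
                                   direction = c("above", "below"),
                                   feature = "value", name = "positive",
                                   parent = NULL) {
  direction <- match.arg(direction)
  if (any(!is.finite(control_values)))
    abort("control values contain non-finite entries")
  if (length(control_values) < 50)
    abort(sprintf("need >= 50 control values, got %d", length(control_values)))
  quantile <- quantile %||% if (direction == "above") 0.99 else 0.01
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  cutoff <- unname(quantile(control_values, quantile, type = 7))
  gate_threshold(name, feature, direction, cutoff, parent = parent)
}

#' Standard structural gates
#'
#' `singlet_gate_bf()` excludes doublets/aggregates and debris on the
#' bright-field image: aspect ratio at least `min_ar` and area within
#' `[area_lo, area_hi]` square micrometres. `singlet_gate_dapi()` does the
#' same for dissociated-tissue data using total DAPI foreground area and
#' intensity; its box is placed relative to the table's median nucleus
#' (doublets sit near twice the median in both coordinates and fall
#' outside). `focus_gate()` keeps in-focus cells by thresholding the
#' bright-field gradient RMS and contrast.
#'
#' @param name Gate name.
#' @param min_ar Minimum aspect ratio (bright-field singlets).
#' @param area_lo,area_hi Bright-field area window, square micrometres.
#' @param table Feature table (used by the DAPI singlet gate to locate the
#'   singlet mode).
#' @param area_rel,int_rel Length-2 windows relative to the median DAPI
#'   foreground area and integrated intensity.
#' @param min_grms,min_contrast Focus thresholds; defaults were calibrated
#'   once as the 5th percentile of in-focus synthetic renders.
#' @param parent Parent gate name.
#' @return A [gates] object.
#' @name structural_gates
NULL

#' @rdname structural_gates
#' @export
singlet_gate_bf <- function(name = "singlets", min_ar = 0.6,
                            area_lo = 50, area_hi = 5000, parent = NULL) {
  gate_rect2d(name, "area_um2", "aspect_ratio",
              area_lo, area_hi, min_ar, 1, parent = parent)
}

#' @rdname structural_gates
#' @export
singlet_gate_dapi <- function(table, name = "singlets",
                              area_rel = c(0.3, 3.5),
                              int_rel = c(0.5, 1.55), parent = NULL) {
  if (!all(c("dapi_area_um2", "dapi_intensity") %in% names(table)))
    abort("table lacks dapi_area_um2/dapi_intensity columns")
  med_a <- median(table$dapi_area_um2, na.rm = TRUE)
  med_i <- median(table$dapi_intensity, na.rm = TRUE)
  if (!is.finite(med_a) || !is.finite(med_i))
    abort("cannot place DAPI singlet gate: no finite DAPI features")
  # DAPI integrated intensity tracks DNA content (~2N for every singlet),
  # so the intensity window is tight while the area window stays wide
  # enough for cell-type nucleus-size differences
  gate_rect2d(name, "dapi_area_um2", "dapi_intensity",
              area_rel[1] * med_a, area_rel[2] * med_a,
              int_rel[1] * med_i, int_rel[2] * med_i, parent = parent)
}

#' @rdname structural_gates
#' @export
focus_gate <- function(name = "focused", min_grms = 9, min_contrast = 0.015,
                       parent = NULL) {
  gate_rect2d(name, "gradient_rms", "contrast",
              min_grms, Inf, min_contrast, Inf, parent = parent)
}

validate_gates <- function(gates, features) {
  if (inherits(gates, "gate")) gates <- list(gates)
  names(gates) <- vapply(gates, `[[`, character(1), "name")
  if (anyDuplicated(names(gates)))
    abort("duplicated gate names in tree")
  seen <- character(0)
  for (g in gates) {
    if (!is.null(g$parent) && !g$parent %in% seen)
      abort(sprintf("gate '%s': parent '%s' not defined before it (tree must be topologically ordered and acyclic)",
                    g$name, g$parent))
    if (g$type == "boolean") {
      missing_m <- setdiff(g$members, seen)
      if (length(missing_m))
        abort(sprintf("gate '%s': boolean members not defined before it: %s",
                      g$name, paste(missing_m, collapse = ",")))
    } else {
      feats <- switch(g$type,
                      threshold = , control_threshold = , interval = g$feature,
                      rect2d = c(g$feature_x, g$feature_y))
      missing_f <- setdiff(feats, names(features))
      if (length(missing_f))
        abort(sprintf("gate '%s': unknown feature(s): %s",
                      g$name, paste(missing_f, collapse = ",")))
    }
    seen <- c(seen, g$name)
  }
  gates
}

gate_predicate <- function(g, features) {
  switch(g$type,
    threshold = {
      v <- features[[g$feature]]
      if (g$direction == "above") v > g$cutoff else v < g$cutoff
    },
    interval = {
      v <- features[[g$feature]]
      v >= g$lo & v <= g$hi
    },
    rect2d = {
      x <- features[[g$feature_x]]; y <- features[[g$feature_y]]
      x >= g$x_lo & x <= g$x_hi & y >= g$y_lo & y <= g$y_hi
    },
    abort(sprintf("gate '%s': unsupported predicate type '%s'", g$name, g$type)))
}

#' Evaluate a gating tree on a feature table
#'
#' Computes per-cell membership for every gate in topological order,
#' enforcing hierarchy containment (a cell belongs to a gate only if it
#' belongs to the parent). Deferred control-referenced thresholds are
#' resolved in the same pass: their cutoff is the configured quantile of the
#' feature over control-sample cells inside the parent gate. Cells with
#' missing features for a gate are excluded from it and counted in the
#' per-gate `ungated` tally.
#'
#' @param table Feature table (tibble with `cell_id`, `sample_id`).
#' @param gates List of [gates] objects in topological order.
#' @param control_samples Character vector of `sample_id`s used to resolve
#'   [gate_control_threshold()] gates (required when any are present).
#' @return A `gating_result`: list with `membership` (tibble of logicals per
#'   gate), `counts` (per sample x gate: `n_parent`, `n_in_gate`,
#'   `ungated`, `percent`) and `gates` (with resolved cutoffs).
#' @export
apply_gates <- function(table, gates, control_samples = NULL) {
  gates <- validate_gates(gates, table)
  n <- nrow(table)
  membership <- list()
  resolved <- list()
  for (g in gates) {
    par_m <- if (is.null(g$parent)) rep(TRUE, n) else membership[[g$parent]]
    if (g$type == "control_threshold") {
      if (is.null(control_samples))
        abort(sprintf("gate '%s' needs control_samples to resolve its cutoff",
                      g$name))
      ctrl <- table[[g$feature]][par_m & table$sample_id %in% control_samples]
      ctrl <- ctrl[is.finite(ctrl)]
      g <- threshold_from_control(ctrl, g$quantile, g$direction,
                                  g$feature, g$name, g$parent)
    }
    if (g$type == "boolean") {
      mats <- lapply(g$members, function(m) membership[[m]])
      p <- switch(g$op,
                  AND = Reduce(`&`, mats),
                  OR = Reduce(`|`, mats),
                  NOT = !mats[[1]])
    } else {
      p <- gate_predicate(g, table)
    }
    membership[[g$name]] <- ifelse(is.na(p), FALSE, p) & par_m
    attr(membership[[g$name]], "ungated") <- is.na(p) & par_m
    resolved[[g$name]] <- g
  }
  counts <- map_dfr(resolved, function(g) {
    m <- membership[[g$name]]
    par_m <- if (is.null(g$parent)) rep(TRUE, n) else membership[[g$parent]]
    tibble(sample_id = table$sample_id, parent = par_m, member = m,
           ungated = attr(m, "ungated")) |>
      group_by(.data$sample_id) |>
      summarise(n_parent = sum(.data$parent),
                n_in_gate = sum(.data$member),
                ungated = sum(.data$ungated),
                .groups = "drop") |>
      mutate(gate = g$name,
             percent = ifelse(.data$n_parent > 0,
                              100 * .data$n_in_gate / .data$n_parent, NA_real_),
             .before = 1)
  })
  memb_tb <- bind_cols(table[c("cell_id", "sample_id")],
                       as_tibble(lapply(membership, as.logical)))
  structure(list(membership = memb_tb, counts = counts, gates = resolved),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result: %d cells, %d gates>\n",
              nrow(x$membership), length(x$gates)))
  print(x$counts, n = 20)
  invisible(x)
}

#' Percent positive per sample
#'
#' Fraction of parent-gate cells falling in `gate`, as a percent per sample
#' — the reporting primitive for "percent SA-beta-gal positive" style
#' results. Aggregate across samples with [pop_summary()].
#'
#' @param result A `gating_result` from [apply_gates()].
#' @param gate Gate name.
#' @param parent Denominator gate name; defaults to the gate's own parent
#'   (all cells when the gate is a root).
#' @return Tibble: `sample_id`, `gate`, `n_parent`, `n_in_gate`, `percent`.
#' @export
percent_positive <- function(result, gate, parent = NULL) {
  stopifnot(inherits(result, "gating_result"))
  if (!gate %in% names(result$gates)) abort(sprintf("unknown gate '%s'", gate))
  parent <- parent %||% result$gates[[gate]]$parent
  m <- result$membership
  par_m <- if (is.null(parent)) rep(TRUE, nrow(m)) else {
    if (!parent %in% names(result$gates)) abort(sprintf("unknown parent gate '%s'", parent))
    m[[parent]]
  }
  tibble(sample_id = m$sample_id, parent = par_m, member = m[[gate]] & par_m) |>
    group_by(.data$sample_id) |>
    summarise(n_parent = sum(.data$parent), n_in_gate = sum(.data$member),
              .groups = "drop") |>
    mutate(gate = gate, .after = "sample_id") |>
    mutate(percent = ifelse(.data$n_parent > 0,
                            100 * .data$n_in_gate / .data$n_parent, NA_real_))
}

#' Mean and SEM across samples
#'
#' Aggregates a per-sample statistic (e.g. [percent_positive()] output) into
#' mean +/- SEM across samples, the standard reporting convention.
#'
#' @param stats Tibble with one row per sample.
#' @param value Column to aggregate (default `percent`).
#' @return One-row tibble: `mean`, `sem`, `n_samples`.
#' @export
pop_summary <- function(stats, value = "percent") {
  v <- stats[[value]]
  v <- v[is.finite(v)]
  tibble(mean = mean(v),
         sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
         n_samples = length(v))
}

#' Cell area inside vs outside a gate
#'
#' Compares a size feature between members and non-members of a gate within
#' the same parent population (e.g. area of SA-beta-gal positive vs negative
#' cells), per sample, with the per-sample SEM over cells.
#'
#' @param table Feature table used for gating.
#' @param result A `gating_result`.
#' @param gate Gate name splitting the parent population.
#' @param parent Parent gate (defaults to the gate's own parent).
#' @param feature Size feature column (default `area_um2`).
#' @return Tibble: `sample_id`, `population` (`in_gate`/`out_gate`), `n`,
#'   `mean_area_um2`, `sem`.
#' @export
area_by_gate <- function(table, result, gate, parent = NULL,
                         feature = "area_um2") {
  stopifnot(inherits(result, "gating_result"))
  if (!gate %in% names(result$gates)) abort(sprintf("unknown gate '%s'", gate))
  parent <- parent %||% result$gates[[gate]]$parent
  m <- result$membership
  par_m <- if (is.null(parent)) rep(TRUE, nrow(m)) else m[[parent]]
  ing <- m[[gate]] & par_m
  if (!any(ing)) abort(sprintf("gate '%s' is empty", gate))
  tb <- tibble(sample_id = m$sample_id,
               population = ifelse(ing, "in_gate", "out_gate"),
               value = table[[feature]][match(m$cell_id, table$cell_id)])
  tb <- tb[par_m, ]
  tb |>
    group_by(.data$sample_id, .data$population) |>
    summarise(n = dplyr::n(),
              mean_area_um2 = mean(.data$value, na.rm = TRUE),
              sem = sd(.data$value, na.rm = TRUE) / sqrt(dplyr::n()),
              .groups = "drop")
}

#' Unpaired two-tailed Student's t-test
#'
#' Classic equal-variance (pooled) two-sample t statistic with the p-value
#' from the t distribution on `n_a + n_b - 2` degrees of freedom.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `estimate` (mean difference a - b), `t`, `df`,
#'   `p_value`.
#' @export
two_sample_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2)
    abort("both groups need at least 2 finite values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tval <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  df <- na + nb - 2
  tibble(estimate = mean(a) - mean(b), t = tval, df = df,
         p_value = if (se == 0) 1 else 2 * pt(-abs(tval), df))
}
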