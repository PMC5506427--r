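#' Build a synthetic-population configuration
#'
#' Full generative description of a synthetic imaging-flow-cytometry run:
#' per-sample population structure (senescence prevalence, X-gal staining
#' sensitivity/false-positive rate or per-cell-type staining probabilities),
#' per-phenotype cell-size distributions (lognormal, parameterised by target
#' mean area and CV), the bright-field darkening model, nuclear focus
#' counts, nuclear/cell-type marker intensity models, read noise, defocus
#' and doublet fractions. The same config plus the same seed reproduces the
#' dataset bit for bit.
#'
#' @param config Named list (or path handled by [read_synth_config()])
#'   merged over the defaults; see the package vignette for the schema.
#' @return List of class `synth_config` with all defaults resolved.
#' @export
synth_config <- function(config = list()) {
  defaults <- list(
    name = "synthetic",
    pixel_size_um = 0.5,
    image_size_px = 96,
    channels = c("BF"),
    bf = list(background = 600, base_contrast = 45, ring_amp = 15,
              darkness_pos_mean = 150, darkness_pos_sd = 25,
              darkness_neg_sd = 6, read_noise = 8),
    fluor_background = 100,
    # DAPI is rendered at constant integrated intensity per nucleus (DNA
    # content is ~2N regardless of cell size), so doublets double the total
    # while large singlet nuclei do not
    nucleus = list(frac = 0.5, dapi_total = 150000, dapi_total_cv = 0.1),
    foci = list(amp = 250, sigma_px = 1, min_sep_px = 4.5, place_frac = 0.65,
                base_level = 15, lambda_pos_extra = 1.5, lambda_neg = 0.3,
                pos_min = 4, pos_cap = 8, neg_cap = 2),
    markers = list(
      HMGB1 = list(level_pos = 350, level_neg = 15, cv = 0.3),
      Ki67 = list(level_pos = 350, level_neg = 15, cv = 0.3),
      BrdU = list(level_pos = 350, level_neg = 15, cv = 0.3)),
    type_channels = list(
      CD45 = list(level_pos = 400, level_neg = 12, cv = 0.3),
      pCK = list(level_pos = 400, level_neg = 12, cv = 0.3),
      GFP = list(level_pos = 400, level_neg = 12, cv = 0.3)),
    viability = list(channel = "Zombie", level_dead = 500, level_viable = 10,
                     cv = 0.3),
    doublet_fraction = 0.02,
    defocus_fraction = 0.03,
    defocus_sigma = 6,
    population = list(
      senescent_prev = 0,
      p_stained_sen = 0.95,
      p_stained_nonsen = 0.05,
      p_stained = NULL,
      p_focus_pos = list(sen = 0.9, nonsen = 0.05),
      p_marker_pos = list(),
      p_viable = 1,
      cell_types = NULL,
      area = list(sen = list(mean_um2 = 668.9, cv = 0.22),
                  nonsen = list(mean_um2 = 461, cv = 0.22))),
    samples = list(list(sample_id = "sample1", n_cells = 500)))
  cfg <- deep_merge(defaults, config)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

deep_merge <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base)) return(override)
  for (nm in names(override)) {
    if (!is.null(nm) && nm != "" && nm %in% names(base) &&
        is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

check_prob <- function(p, what) {
  ps <- unlist(p)
  if (any(!is.finite(ps) | ps < 0 | ps > 1))
    abort(sprintf("%s must be probabilities in [0, 1]", what))
}

validate_synth_config <- function(cfg) {
  if (!"BF" %in% cfg$channels) abort("channels must include BF")
  if (cfg$pixel_size_um <= 0) abort("pixel_size_um must be > 0")
  if (cfg$image_size_px < 16) abort("image_size_px too small")
  check_prob(cfg$doublet_fraction, "doublet_fraction")
  check_prob(cfg$defocus_fraction, "defocus_fraction")
  pops <- c(list(cfg$population),
            lapply(cfg$samples, function(s) s))
  for (p in pops) {
    for (key in c("senescent_prev", "p_stained_sen", "p_stained_nonsen",
                  "p_stained", "p_focus_pos", "p_viable"))
      if (!is.null(p[[key]])) check_prob(p[[key]], key)
    if (!is.null(p$p_marker_pos)) check_prob(p$p_marker_pos, "p_marker_pos")
  }
  ids <- vapply(cfg$samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) abort("duplicated sample_id in samples")
  invisible(cfg)
}

#' @rdname synth_config
#' @param path Path to a YAML config file.
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  synth_config(yaml::read_yaml(path))
}

# lognormal draw with a target arithmetic mean and coefficient of variation;
# truncated at +/- trunc_z log-sd (keeps the mean within ~0.1% and bounds the
# size tail so cells always fit their frame)
rlnorm_mean_cv <- function(n, mean, cv, trunc_z = 2.75) {
  sdlog <- sqrt(log(1 + cv^2))
  lo <- stats::pnorm(-trunc_z); hi <- stats::pnorm(trunc_z)
  z <- stats::qnorm(runif(n, lo, hi))
  exp(log(mean) - sdlog^2 / 2 + sdlog * z)
}

# resolve a probability spec that may be a scalar, a {sen, nonsen} pair,
# a {stained, unstained} pair, or a per-cell-type mapping
resolve_prob <- function(p, senescent, stained, type) {
  if (is.null(p)) return(rep(0, length(senescent)))
  if (is.numeric(p) && length(p) == 1) return(rep(p, length(senescent)))
  nm <- names(p)
  if (all(c("sen", "nonsen") %in% nm))
    return(ifelse(senescent, p$sen, p$nonsen))
  if (all(c("stained", "unstained") %in% nm))
    return(ifelse(stained, p$stained, p$unstained))
  if (all(unique(type) %in% nm))
    return(vapply(type, function(tt) p[[tt]], numeric(1)))
  abort("unrecognised probability spec (need scalar, sen/nonsen, stained/unstained, or per-type)")
}
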