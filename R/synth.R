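#' Sample ground-truth phenotypes for a synthetic population
#'
#' Draws every per-cell label that the renderer and the downstream pipeline
#' will be validated against: cell type, senescence, X-gal staining status
#' and bright-field darkness, nuclear focus count, marker positivity,
#' viability, doublet/defocus status and target cell area. Per-sample
#' fields override the shared `population` block of the config. Each cell
#' also carries a child seed derived from the root seed by counter, so
#' rendering is reproducible cell by cell.
#'
#' @param config A [synth_config()].
#' @param seed Root seed (integer).
#' @param n_per_sample Optional override of every sample's `n_cells`.
#' @return Tibble with one row per cell (ground-truth table).
#' @export
sample_phenotypes <- function(config, seed = 1, n_per_sample = NULL) {
  config <- if (inherits(config, "synth_config")) config else synth_config(config)
  set.seed(seed)
  rows <- map(config$samples, function(smp) {
    pop <- deep_merge(config$population, smp)
    # probability specs are alternatives (scalar | sen/nonsen |
    # stained/unstained | per-type): a sample-level spec replaces the
    # population default wholesale instead of key-merging with it
    for (key in c("p_focus_pos", "p_stained", "p_viable"))
      if (!is.null(smp[[key]])) pop[[key]] <- smp[[key]]
    for (mm in names(smp$p_marker_pos))
      pop$p_marker_pos[[mm]] <- smp$p_marker_pos[[mm]]
    n <- n_per_sample %||% pop$n_cells %||% 500
    unstained <- isTRUE(pop$unstained)

    # cell types
    if (is.null(pop$cell_types)) {
      type <- rep("default", n)
      pos_for <- list(default = character(0))
    } else {
      tnames <- vapply(pop$cell_types, `[[`, character(1), "type")
      prevs <- vapply(pop$cell_types, `[[`, numeric(1), "prev")
      if (abs(sum(prevs) - 1) > 1e-6) abort("cell type prevalences must sum to 1")
      type <- sample(tnames, n, replace = TRUE, prob = prevs)
      pos_for <- setNames(lapply(pop$cell_types,
                                 function(ct) ct$positive_for %||% character(0)),
                          tnames)
    }

    # senescence and staining
    if (!is.null(pop$p_stained)) {
      p_st <- resolve_prob(pop$p_stained, rep(FALSE, n), rep(FALSE, n), type)
      stained <- rbinom(n, 1, p_st) == 1
      senescent <- stained  # staining defines the senescent label in vivo
    } else {
      senescent <- rbinom(n, 1, pop$senescent_prev) == 1
      p_st <- ifelse(senescent, pop$p_stained_sen, pop$p_stained_nonsen)
      stained <- rbinom(n, 1, p_st) == 1
    }
    if (unstained) stained <- rep(FALSE, n)
    darkness <- ifelse(stained,
                       rnorm(n, config$bf$darkness_pos_mean, config$bf$darkness_pos_sd),
                       rnorm(n, 0, config$bf$darkness_neg_sd))
    darkness <- pmax(darkness, 0)

    # nuclear foci
    fc <- config$foci
    p_fp <- resolve_prob(pop$p_focus_pos, senescent, stained, type)
    if (unstained) p_fp <- rep(0, n)
    focus_pos <- rbinom(n, 1, p_fp) == 1
    foci_n <- ifelse(focus_pos,
                     pmin(fc$pos_min + rpois(n, fc$lambda_pos_extra), fc$pos_cap),
                     pmin(rpois(n, fc$lambda_neg), fc$neg_cap))

    # area by phenotype (optionally per type)
    area_cfg <- pop$area
    area_for <- function(i) {
      ac <- area_cfg
      if (!is.null(pop$cell_types)) {
        ct <- purrr::detect(pop$cell_types, function(x) x$type == type[i])
        if (!is.null(ct$area)) ac <- ct$area
      }
      ph <- if (senescent[i]) "sen" else "nonsen"
      a <- ac[[ph]] %||% ac[["nonsen"]] %||% ac
      rlnorm_mean_cv(1, a$mean_um2, a$cv)
    }
    area_um2 <- vapply(seq_len(n), area_for, numeric(1))

    out <- tibble(
      cell_id = sprintf("%s_%05d", smp$sample_id, seq_len(n)),
      sample_id = smp$sample_id,
      cell_type = type,
      senescent = senescent,
      stained = stained,
      darkness = darkness,
      foci_n = as.integer(foci_n),
      viable = rbinom(n, 1, pop$p_viable %||% 1) == 1,
      doublet = rbinom(n, 1, config$doublet_fraction) == 1,
      defocused = rbinom(n, 1, config$defocus_fraction) == 1,
      area_um2_target = area_um2,
      unstained_sample = unstained)

    # marker positivity per rendered marker channel
    for (m in intersect(names(config$markers), config$channels)) {
      p <- resolve_prob(pop$p_marker_pos[[m]], senescent, stained, type)
      pos <- rbinom(n, 1, p) == 1
      if (unstained) pos <- rep(FALSE, n)
      out[[paste0("pos_", m)]] <- pos
    }
    # cell-type channel positivity follows the type label
    for (tc in intersect(names(config$type_channels), config$channels)) {
      out[[paste0("pos_", tc)]] <-
        map_lgl(seq_len(n), function(i) tc %in% pos_for[[type[i]]])
      if (unstained) out[[paste0("pos_", tc)]] <- rep(FALSE, n)
    }
    out
  })
  truth <- bind_rows(rows)
  truth$cell_seed <- (as.numeric(seed) * 48271 + seq_len(nrow(truth)) * 1009) %%
    2147483647
  truth
}

frame_grid <- function(S) {
  list(X = matrix(rep(seq_len(S), S), S, S),
       Y = matrix(rep(seq_len(S), each = S), S, S))
}

soft_ellipse <- function(X, Y, cx, cy, a, b, theta, edge_w = 1.2) {
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  d <- sqrt((u / a)^2 + (v / b)^2)
  r_eff <- sqrt(a * b)
  # the darker cell rim sits just inside the boundary so that Otsu masks of
  # faint (unstained) cells are not inflated by the rim's smoothing halo
  list(field = stats::plogis((1 - d) * r_eff / edge_w),
       ring = exp(-(((d - 0.9) * r_eff) / 1.5)^2))
}

place_foci <- function(k, ncx, ncy, rn, min_sep, place_frac = 0.65) {
  if (k == 0) return(cbind(numeric(0), numeric(0)))
  pts <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    best <- NULL; best_d <- -Inf
    for (try in 1:60) {
      rho <- place_frac * rn * sqrt(runif(1))
      phi <- runif(1, 0, 2 * pi)
      cand <- c(ncx + rho * cos(phi), ncy + rho * sin(phi))
      d <- if (i == 1) Inf else
        min(sqrt((pts[1:(i - 1), 1] - cand[1])^2 + (pts[1:(i - 1), 2] - cand[2])^2))
      if (d >= min_sep) { best <- cand; break }
      if (d > best_d) { best_d <- d; best <- cand }
    }
    pts[i, ] <- best
  }
  pts
}

#' Render one synthetic cell record
#'
#' Composes the multi-channel image stack for one ground-truth row:
#' bright field = background minus (intrinsic contrast + X-gal darkness)
#' over a soft-edged elliptical cell body, with a darker cell rim; DAPI =
#' nuclear disc; focus channel = Gaussian puncta inside the nucleus;
#' nuclear markers = nuclear disc scaled by marker level; cell-type and
#' viability channels = cell body scaled by their levels. Additive Gaussian
#' read noise everywhere, optional whole-stack Gaussian blur for defocused
#' cells and a second tangent cell for doublets (the frame grows as needed
#' to contain the pair). Pixels are rounded to integer counts so that disk
#' round-trips are exact.
#'
#' @param labels One row of [sample_phenotypes()] output (list or one-row
#'   tibble).
#' @param config A [synth_config()].
#' @return A [cell_record()] with `ground_truth` attached.
#' @export
render_cell <- function(labels, config) {
  lb <- as.list(labels)
  set.seed(as.integer(lb$cell_seed %% 2147483647))
  ps <- config$pixel_size_um
  S <- config$image_size_px

  area_px <- lb$area_um2_target / ps^2
  r <- sqrt(area_px / pi)
  q <- runif(1, 0.8, 1)
  a <- r / sqrt(q); b <- r * sqrt(q)
  theta <- runif(1, 0, pi)
  margin <- 4
  if (2 * (a + margin) > S)
    abort(sprintf("cell '%s' larger than frame: increase image_size_px", lb$cell_id))

  partner <- NULL
  if (isTRUE(lb$doublet)) {
    r2 <- r * runif(1, 0.85, 1.1)
    q2 <- runif(1, 0.8, 1)
    partner <- list(a = r2 / sqrt(q2), b = r2 * sqrt(q2),
                    theta = runif(1, 0, pi), phi = runif(1, 0, 2 * pi),
                    dist = r + r2)
    need <- 2 * ceiling(a + partner$dist + partner$a + margin)
    if (need > S) S <- min(2 * ceiling(need / 2), 4 * config$image_size_px)
  }

  g <- frame_grid(S)
  cx <- S / 2 + runif(1, -2, 2); cy <- S / 2 + runif(1, -2, 2)
  if (!is.null(partner)) {  # centre the pair
    cx <- cx - partner$dist * cos(partner$phi) / 2
    cy <- cy - partner$dist * sin(partner$phi) / 2
  }
  e1 <- soft_ellipse(g$X, g$Y, cx, cy, a, b, theta)
  field <- e1$field; ring <- e1$ring
  if (!is.null(partner)) {
    p_cx <- cx + partner$dist * cos(partner$phi)
    p_cy <- cy + partner$dist * sin(partner$phi)
    e2 <- soft_ellipse(g$X, g$Y, p_cx, p_cy, partner$a, partner$b, partner$theta)
    field <- pmax(field, e2$field)
    ring <- pmax(ring, e2$ring)
  }

  # nucleus strictly inside the cell
  nf <- config$nucleus$frac
  rn <- nf * r
  jit <- (1 - nf) * r * 0.3
  ncx <- cx + runif(1, -jit, jit); ncy <- cy + runif(1, -jit, jit)
  dn <- sqrt((g$X - ncx)^2 + (g$Y - ncy)^2) / rn
  nucfield1 <- stats::plogis((1 - dn) * rn / 1.0)
  nucfield2 <- NULL
  if (!is.null(partner)) {
    rn2 <- nf * sqrt(partner$a * partner$b)
    dn2 <- sqrt((g$X - p_cx)^2 + (g$Y - p_cy)^2) / rn2
    nucfield2 <- stats::plogis((1 - dn2) * rn2 / 1.0)
  }
  nucfield <- if (is.null(nucfield2)) nucfield1 else pmax(nucfield1, nucfield2)

  noise_sd <- config$bf$read_noise
  fbg <- config$fluor_background
  channels <- list()
  for (ch in config$channels) {
    img <- if (ch == "BF") {
      config$bf$background -
        (config$bf$base_contrast + lb$darkness) * field -
        config$bf$ring_amp * ring
    } else if (ch == "DAPI") {
      tot <- rlnorm_mean_cv(1, config$nucleus$dapi_total, config$nucleus$dapi_total_cv)
      img <- fbg + (tot / (pi * rn^2)) * nucfield1
      if (!is.null(nucfield2)) {
        tot2 <- rlnorm_mean_cv(1, config$nucleus$dapi_total, config$nucleus$dapi_total_cv)
        rn2 <- nf * sqrt(partner$a * partner$b)
        img <- img + (tot2 / (pi * rn2^2)) * nucfield2
      }
      img
    } else if (ch %in% names(config$markers)) {
      mc <- config$markers[[ch]]
      pos <- isTRUE(lb[[paste0("pos_", ch)]])
      lvl <- rlnorm_mean_cv(1, if (pos) mc$level_pos else mc$level_neg, mc$cv)
      fbg + lvl * nucfield
    } else if (ch %in% names(config$type_channels)) {
      tc <- config$type_channels[[ch]]
      pos <- isTRUE(lb[[paste0("pos_", ch)]])
      lvl <- rlnorm_mean_cv(1, if (pos) tc$level_pos else tc$level_neg, tc$cv)
      fbg + lvl * field
    } else if (ch == config$viability$channel) {
      vc <- config$viability
      lvl <- if (isTRUE(lb$unstained_sample)) vc$level_viable
             else if (lb$viable) vc$level_viable else vc$level_dead
      fbg + rlnorm_mean_cv(1, lvl, vc$cv) * field
    } else {
      matrix(fbg, S, S)  # unknown channel: flat autofluorescence
    }
    channels[[ch]] <- img
  }

  # gamma-H2AX puncta ride on the focus channel's nuclear base
  spot_ch <- intersect("gH2AX", config$channels)
  if (length(spot_ch) == 1 && lb$foci_n > 0) {
    fc <- config$foci
    pts <- place_foci(lb$foci_n, ncx, ncy, rn, fc$min_sep_px,
                      fc$place_frac %||% 0.65)
    spots <- matrix(0, S, S)
    for (i in seq_len(nrow(pts)))
      spots <- spots + fc$amp *
        exp(-((g$X - pts[i, 1])^2 + (g$Y - pts[i, 2])^2) / (2 * fc$sigma_px^2))
    channels[[spot_ch]] <- channels[[spot_ch]] + spots
  }
  if ("gH2AX" %in% names(channels)) {
    # foci channel background inside the nucleus
    channels[["gH2AX"]] <- channels[["gH2AX"]] + config$foci$base_level * nucfield
  }

  if (isTRUE(lb$defocused)) {
    channels <- map(channels, function(m)
      as.matrix(EBImage::gblur(m, sigma = config$defocus_sigma)))
  }
  channels <- map(channels, function(m)
    pmax(round(m + rnorm(length(m), 0, noise_sd)), 0))

  cell_record(lb$cell_id, lb$sample_id, channels, ps,
              ground_truth = lb[setdiff(names(lb), "cell_seed")])
}

#' Generate a full synthetic population
#'
#' Samples ground truth with [sample_phenotypes()] and renders every cell
#' with [render_cell()]. When `out_dir` is given the dataset is written via
#' [write_dataset()] together with `ground_truth.csv` keyed by `cell_id`.
#'
#' @inheritParams sample_phenotypes
#' @param out_dir Optional output directory for TIFFs + manifest + truth.
#' @return List with `cells` (list of cell records), `truth` (tibble) and
#'   `manifest` (tibble or `NULL` when nothing was written).
#' @export
generate_population <- function(config, seed = 1, out_dir = NULL,
                                n_per_sample = NULL) {
  config <- if (inherits(config, "synth_config")) config else synth_config(config)
  truth <- sample_phenotypes(config, seed = seed, n_per_sample = n_per_sample)
  cells <- map(seq_len(nrow(truth)), function(i) render_cell(truth[i, ], config))
  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_dataset(cells, out_dir)
    readr::write_csv(select(truth, -"cell_seed"),
                     file.path(out_dir, "ground_truth.csv"))
  }
  list(cells = cells, truth = truth, manifest = manifest)
}

#' Render isolated nuclei with known focus counts
#'
#' Calibration harness for the focus-counting operator: renders `n_nuclei`
#' single nuclei with ground-truth focus counts drawn uniformly from
#' `counts`, well separated so the true count is recoverable.
#'
#' @param n_nuclei Number of nuclei.
#' @param counts Candidate ground-truth counts.
#' @param seed Seed.
#' @param radius_px Nucleus radius.
#' @param frame_px Frame size.
#' @param amp,sigma_px,min_sep_px,noise_sd,base_level Render parameters.
#' @return Tibble: `truth` count, `measured` count from [spot_count()].
#' @export
simulate_nuclei <- function(n_nuclei = 200, counts = 0:8, seed = 1,
                            radius_px = 16, frame_px = 64, amp = 150,
                            sigma_px = 1.2, min_sep_px = 6, noise_sd = 8,
                            base_level = 15) {
  set.seed(seed)
  g <- frame_grid(frame_px)
  cx <- frame_px / 2; cy <- frame_px / 2
  dn <- sqrt((g$X - cx)^2 + (g$Y - cy)^2) / radius_px
  nucfield <- stats::plogis((1 - dn) * radius_px / 1.0)
  truth_n <- sample(counts, n_nuclei, replace = TRUE)
  measured <- vapply(seq_len(n_nuclei), function(i) {
    k <- truth_n[i]
    img <- 100 + 1200 * nucfield
    foci <- base_level * nucfield
    pts <- place_foci(k, cx, cy, radius_px, min_sep_px)
    for (j in seq_len(k))
      foci <- foci + amp * exp(-((g$X - pts[j, 1])^2 + (g$Y - pts[j, 2])^2) /
                                 (2 * sigma_px^2))
    dapi <- pmax(round(img + rnorm(length(img), 0, noise_sd)), 0)
    fimg <- pmax(round(100 + foci + rnorm(length(foci), 0, noise_sd)), 0)
    nmask <- nuclear_mask(dapi)
    spot_count(fimg, nmask)$count
  }, integer(1))
  tibble(truth = as.integer(truth_n), measured = measured)
}
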