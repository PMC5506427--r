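# small deterministic renders used across test files

render_disk <- function(radius = 20, offset = -40, size = 96, background = 100,
                        noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rep(seq_len(size), size), size, size)
  Y <- t(X)
  d <- sqrt((X - size / 2)^2 + (Y - size / 2)^2)
  img <- background + offset * (d <= radius)
  if (noise > 0) img <- img + rnorm(length(img), 0, noise)
  img
}

render_rect_mask <- function(h, w, size = 64) {
  m <- matrix(FALSE, size, size)
  r0 <- floor((size - h) / 2); c0 <- floor((size - w) / 2)
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

# nucleus + spot-channel pair with known focus positions
render_nucleus_with_spots <- function(pts, radius = 12, size = 64, amp = 150,
                                      sigma = 1.2, noise = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rep(seq_len(size), size), size, size)
  Y <- t(X)
  c0 <- size / 2
  dn <- sqrt((X - c0)^2 + (Y - c0)^2) / radius
  nuc <- stats::plogis((1 - dn) * radius)
  dapi <- pmax(round(100 + 1200 * nuc + rnorm(length(nuc), 0, noise)), 0)
  foci <- 100 + 15 * nuc
  if (length(pts)) {
    pts <- matrix(pts, ncol = 2)
    for (i in seq_len(nrow(pts)))
      foci <- foci + amp * exp(-((X - c0 - pts[i, 1])^2 +
                                   (Y - c0 - pts[i, 2])^2) / (2 * sigma^2))
  }
  foci <- pmax(round(foci + rnorm(length(foci), 0, noise)), 0)
  list(dapi = dapi, foci = foci)
}

tiny_synth_config <- function(n = 40, channels = "BF", seed_areas = NULL, ...) {
  synth_config(modifyList(list(
    channels = channels,
    samples = list(
      list(sample_id = "test", n_cells = n, senescent_prev = 0.5,
           p_stained_sen = 1, p_stained_nonsen = 0),
      list(sample_id = "unstained", n_cells = n, unstained = TRUE))),
    list(...)))
}
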