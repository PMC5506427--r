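test_that("phenotype sampling is seeded, valid and hits its prevalences", {
  cfg <- synth_config(list(samples = list(
    list(sample_id = "a", n_cells = 4000, senescent_prev = 0.5))))
  t1 <- sample_phenotypes(cfg, seed = 42)
  t2 <- sample_phenotypes(cfg, seed = 42)
  expect_identical(t1, t2)

  # binomial 3-sigma window around the injected prevalence
  p_hat <- mean(t1$senescent)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 4000))

  zero <- synth_config(list(samples = list(
    list(sample_id = "z", n_cells = 300, senescent_prev = 0))))
  expect_equal(sum(sample_phenotypes(zero, seed = 1)$senescent), 0)

  expect_error(synth_config(list(samples = list(
    list(sample_id = "bad", n_cells = 10, senescent_prev = 1.7)))),
    "probabilities")
})

test_that("identical seeds render identical pixels", {
  cfg <- tiny_synth_config(n = 5, channels = c("BF", "DAPI"))
  g1 <- generate_population(cfg, seed = 13)
  g2 <- generate_population(cfg, seed = 13)
  for (i in seq_along(g1$cells))
    expect_identical(g1$cells[[i]]$channels, g2$cells[[i]]$channels)
  g3 <- generate_population(cfg, seed = 14)
  expect_false(identical(g1$cells[[1]]$channels$BF, g3$cells[[1]]$channels$BF))
})

test_that("rendered geometry matches the ground-truth labels", {
  cfg <- tiny_synth_config(n = 30, channels = "BF",
                           doublet_fraction = 0, defocus_fraction = 0)
  gen <- generate_population(cfg, seed = 4)
  ft <- extract_features(gen$cells)
  truth <- gen$truth[match(ft$cell_id, gen$truth$cell_id), ]
  # mean measured area tracks mean target area within 5%
  expect_lt(abs(mean(ft$area_um2) / mean(truth$area_um2_target) - 1), 0.05)
  # unstained cells read near zero after background subtraction; the soft
  # intrinsic cell contrast keeps them slightly negative
  expect_lt(mean(abs(ft$bf_mean_pixel[!truth$stained] + 45)), 25)
})

test_that("injected focus counts are recovered through the pipeline", {
  cfg <- synth_config(list(
    channels = c("BF", "DAPI", "gH2AX"),
    doublet_fraction = 0, defocus_fraction = 0,
    samples = list(list(sample_id = "s", n_cells = 30, senescent_prev = 1,
                        p_stained_sen = 1, p_focus_pos = 1))))
  gen <- generate_population(cfg, seed = 9)
  ft <- extract_features(gen$cells)
  truth <- gen$truth[match(ft$cell_id, gen$truth$cell_id), ]
  # crowded nuclei can merge touching foci (counted as one, by design), so
  # exact recovery is checked loosely and focus-positivity (>= 3) tightly
  expect_gte(mean(ft$spot_count == truth$foci_n), 0.75)
  expect_gte(mean((ft$spot_count >= 3) == (truth$foci_n >= 3)), 0.95)
})

test_that("doublets and defocused cells fail their structural gates", {
  cfg <- tiny_synth_config(n = 40, channels = "BF",
                           doublet_fraction = 0.5, defocus_fraction = 0)
  gen <- generate_population(cfg, seed = 15)
  ft <- extract_features(gen$cells)
  truth <- gen$truth[match(ft$cell_id, gen$truth$cell_id), ]
  expect_lt(max(ft$aspect_ratio[truth$doublet]), 0.6)
  expect_gt(min(ft$aspect_ratio[!truth$doublet]), 0.6)

  cfg2 <- tiny_synth_config(n = 30, channels = "BF",
                            doublet_fraction = 0, defocus_fraction = 0.5)
  gen2 <- generate_population(cfg2, seed = 16)
  ft2 <- extract_features(gen2$cells)
  tr2 <- gen2$truth[match(ft2$cell_id, gen2$truth$cell_id), ]
  blurred <- ft2$gradient_rms[tr2$defocused & !tr2$stained]
  crisp <- ft2$gradient_rms[!tr2$defocused & !tr2$stained]
  expect_lt(max(blurred), 9)   # default focus gate excludes them
  expect_gt(min(crisp), 9)
})

test_that("oversized cells raise the frame-size error", {
  cfg <- synth_config(list(image_size_px = 48, samples = list(
    list(sample_id = "s", n_cells = 2, senescent_prev = 1,
         p_stained_sen = 1))))
  truth <- sample_phenotypes(cfg, seed = 1)
  truth$area_um2_target <- 5000
  expect_error(render_cell(truth[1, ], cfg), "image_size_px")
})

test_that("written populations carry their ground truth", {
  cfg <- tiny_synth_config(n = 6, channels = "BF")
  dir <- withr::local_tempdir()
  gen <- generate_population(cfg, seed = 2, out_dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  gt <- readr::read_csv(file.path(dir, "ground_truth.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(gt), 12)
  expect_setequal(gt$cell_id, gen$truth$cell_id)
})
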