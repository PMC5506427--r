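test_that("masked intensity features equal brute-force loops on random patches", {
  for (s in 1:25) {
    set.seed(s)
    img <- matrix(runif(64, 0, 1000), 8, 8)
    mask <- matrix(runif(64) < 0.5, 8, 8)
    if (!any(mask)) mask[3, 3] <- TRUE
    bg <- runif(1, 0, 50)
    n <- 0; mx <- -Inf; acc <- 0
    for (i in 1:8) for (j in 1:8) if (mask[i, j]) {
      v <- img[i, j] - bg
      acc <- acc + v; n <- n + 1; mx <- max(mx, v)
    }
    expect_equal(mean_pixel(img, mask, bg), acc / n)
    expect_equal(max_pixel(img, mask, bg), mx)
    expect_equal(total_intensity(img, mask, bg), acc)
  }
})

test_that("mean pixel matches hand-computed values", {
  img <- matrix(90, 8, 8)
  m <- render_rect_mask(4, 4, 8)
  expect_equal(mean_pixel(img, m, background = 10), 80)
  expect_equal(mean_pixel(img, m, background = 90), 0)

  img2 <- matrix(0, 3, 3); img2[] <- seq(10, 90, by = 10)
  expect_equal(mean_pixel(img2, matrix(TRUE, 3, 3), background = 5), 45)
  expect_error(mean_pixel(img, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("area and aspect ratio follow the second-moment ellipse", {
  full <- matrix(TRUE, 10, 10)
  aa <- area_aspect(full, pixel_size_um = 1)
  expect_equal(aa$area_um2, 100)

  rect <- render_rect_mask(20, 40)
  expect_equal(area_aspect(rect, 1)$aspect_ratio, 0.5, tolerance = 0.01)

  disk <- render_disk(radius = 15, offset = -40) < 80
  expect_equal(area_aspect(disk, 1)$aspect_ratio, 1, tolerance = 0.02)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(area_aspect(one, 2)$aspect_ratio, 1)
  expect_equal(area_aspect(one, 2)$area_um2, 4)
})

test_that("aspect ratio agrees with the EBImage moment computation", {
  set.seed(11)
  for (i in 1:5) {
    h <- sample(6:30, 1); w <- sample(6:30, 1)
    m <- render_rect_mask(h, w)
    mom <- EBImage::computeFeatures.moment(matrix(as.integer(m), 64, 64))
    ours <- area_aspect(m, 1)$aspect_ratio
    # eccentricity e relates to minor/major via ar = sqrt(1 - e^2)
    theirs <- sqrt(1 - mom[1, "m.eccentricity"]^2)
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  }
})

test_that("gradient RMS is zero for flat fields and matches a step-edge oracle", {
  m <- matrix(TRUE, 16, 16)
  expect_equal(gradient_rms(matrix(7, 16, 16), m), 0)

  h <- 40
  img <- matrix(0, 16, 16); img[, 9:16] <- h
  gx <- matrix(0, 16, 16); gy <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    gy[i, j] <- if (j == 1) img[i, 2] - img[i, 1]
                else if (j == 16) img[i, 16] - img[i, 15]
                else (img[i, j + 1] - img[i, j - 1]) / 2
  }
  expect_equal(gradient_rms(img, m), sqrt(mean(gx^2 + gy^2)))
})

test_that("Gaussian blurring never increases gradient RMS", {
  img <- render_disk(radius = 14, offset = -60, noise = 5, size = 64)
  m <- matrix(TRUE, 64, 64)
  sigmas <- c(0.8, 1.5, 3, 6)
  vals <- vapply(sigmas, function(s)
    gradient_rms(as.matrix(EBImage::gblur(img, s)), m), numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("contrast matches the percentile definition", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(px_contrast(matrix(5, 10, 10), m), 0)

  step <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  expect_gt(px_contrast(step, m), 0.99)

  set.seed(2)
  img <- matrix(runif(100, 10, 500), 10, 10)
  q <- quantile(img, c(.05, .95), names = FALSE)
  expect_equal(px_contrast(img, m), (q[2] - q[1]) / (q[2] + q[1] + 1e-6))
})

test_that("spot counting finds well-separated foci and merges touching ones", {
  pair0 <- render_nucleus_with_spots(NULL)
  nm <- nuclear_mask(pair0$dapi)
  expect_equal(spot_count(pair0$foci, nm)$count, 0L)

  pts3 <- rbind(c(-6, -4), c(6, -4), c(0, 6))
  pair3 <- render_nucleus_with_spots(pts3)
  sc3 <- spot_count(pair3$foci, nuclear_mask(pair3$dapi))
  expect_equal(sc3$count, 3L)
  expect_true(all(nuclear_mask(pair3$dapi)[sc3$mask]))  # spot mask in nucleus

  # centres 2 px apart fuse into one component
  pair2 <- render_nucleus_with_spots(rbind(c(-1, 0), c(1, 0)))
  expect_equal(spot_count(pair2$foci, nuclear_mask(pair2$dapi))$count, 1L)

  expect_error(spot_count(pair0$foci, matrix(FALSE, 64, 64)), "empty mask")
})

test_that("bright-field mean pixel decreases monotonically with darkness", {
  darks <- c(0, 30, 60, 90, 150)
  vals <- vapply(darks, function(d) {
    img <- render_disk(radius = 18, offset = -(20 + d), noise = 3, seed = 5)
    m <- cell_mask(img)
    mean_pixel(img, m)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("extract_features reports missing channels as NA, not zero", {
  cfg <- tiny_synth_config(n = 4, channels = c("BF", "DAPI", "gH2AX"),
                           doublet_fraction = 0, defocus_fraction = 0)
  gen <- generate_population(cfg, seed = 2)
  ft <- extract_features(gen$cells)
  expect_true(all(!is.na(ft$spot_count)))

  no_dapi <- gen$cells[[1]]
  no_dapi$channels$DAPI <- NULL
  row <- extract_features(no_dapi)
  expect_true(is.na(row$spot_count))       # no nucleus -> no focus count
  expect_false("dapi_area_um2" %in% names(row))
  expect_false(is.na(row$bf_mean_pixel))
})

test_that("DIS-like and growing-like cells separate on bf_mean_pixel", {
  cfg <- tiny_synth_config(n = 24, channels = "BF",
                           doublet_fraction = 0, defocus_fraction = 0)
  gen <- generate_population(cfg, seed = 6)
  ft <- extract_features(gen$cells)
  truth <- gen$truth
  stained <- truth$stained[match(ft$cell_id, truth$cell_id)]
  expect_lt(max(ft$bf_mean_pixel[stained]), min(ft$bf_mean_pixel[!stained]))
  expect_lt(mean(ft$bf_mean_pixel[stained]), -100)
})
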