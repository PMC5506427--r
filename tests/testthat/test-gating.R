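test_that("control-referenced thresholds use interpolated quantiles", {
  g <- threshold_from_control(1:100, 0.99, "above", "f", "pos")
  expect_equal(g$cutoff, 99.01)
  expect_equal(mean(1:100 > g$cutoff), 0.01)

  # symmetric distribution: below at q and above at 1-q capture equal tails
  set.seed(1)
  x <- rnorm(5001)
  lo <- threshold_from_control(x, 0.05, "below", "f", "lo")
  hi <- threshold_from_control(x, 0.95, "above", "f", "hi")
  expect_equal(mean(x < lo$cutoff), mean(x > hi$cutoff), tolerance = 1e-6)

  expect_error(threshold_from_control(1:49, 0.99, "above"), ">= 50")
  expect_error(threshold_from_control(c(1:60, NA), 0.99, "above"), "finite")
  expect_error(threshold_from_control(1:100, 1.2, "above"), "quantile")
})

test_that("a population shifted far below the control is almost fully gated", {
  set.seed(7)
  control <- rnorm(2000, 0, 10)
  shifted <- rnorm(2000, -50, 10)   # -5 sigma shift
  g <- threshold_from_control(control, 0.01, "below", "bf_mean_pixel", "sa_pos")
  expect_gte(mean(shifted < g$cutoff), 0.95)
})

test_that("gate membership respects hierarchy and tallies missing features", {
  tb <- tibble::tibble(
    cell_id = sprintf("c%d", 1:10), sample_id = "s",
    x = c(1:9, 100), y = c(rep(1, 8), NA, 1))
  gates <- list(gate_threshold("low_x", "x", "below", 50),
                gate_threshold("has_y", "y", "below", 10, parent = "low_x"))
  res <- apply_gates(tb, gates)
  expect_equal(sum(res$membership$low_x), 9)
  expect_equal(sum(res$membership$has_y), 8)
  cnt <- res$counts[res$counts$gate == "has_y", ]
  expect_equal(cnt$ungated, 1)          # NA y inside parent
  expect_true(all(res$membership$has_y <= res$membership$low_x))
})

test_that("boolean gates reproduce the truth table", {
  tb <- tibble::tibble(cell_id = sprintf("c%d", 1:4), sample_id = "s",
                       sa = c(1, 1, 0, 0), hm = c(1, 0, 1, 0))
  gates <- list(
    gate_threshold("sa_pos", "sa", "above", 0.5),
    gate_threshold("hmgb1_pos", "hm", "above", 0.5),
    gate_boolean("hmgb1_neg", "NOT", "hmgb1_pos"),
    gate_boolean("sen", "AND", c("sa_pos", "hmgb1_neg")),
    gate_boolean("either", "OR", c("sa_pos", "hmgb1_pos")))
  res <- apply_gates(tb, gates)
  expect_equal(res$membership$sen, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$membership$either, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$membership$hmgb1_neg, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("random gate trees match brute-force per-cell evaluation", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 60
    tb <- tibble::tibble(cell_id = sprintf("c%d", 1:n),
                         sample_id = sample(c("a", "b"), n, TRUE),
                         f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
    cut1 <- rnorm(1); lo <- -1; hi <- 1
    gates <- list(
      gate_threshold("g1", "f1", "above", cut1),
      gate_interval("g2", "f2", lo, hi, parent = "g1"),
      gate_rect2d("g3", "f1", "f3", -2, 2, -0.5, 3, parent = "g1"),
      gate_boolean("g4", "AND", c("g2", "g3"), parent = "g1"))
    res <- apply_gates(tb, gates)
    m1 <- tb$f1 > cut1
    m2 <- m1 & tb$f2 >= lo & tb$f2 <= hi
    m3 <- m1 & tb$f1 >= -2 & tb$f1 <= 2 & tb$f3 >= -0.5 & tb$f3 <= 3
    m4 <- m2 & m3 & m1
    expect_identical(res$membership$g2, m2)
    expect_identical(res$membership$g3, m3)
    expect_identical(res$membership$g4, m4)
  }
})

test_that("invalid trees fail before evaluation", {
  tb <- tibble::tibble(cell_id = "c", sample_id = "s", x = 1)
  expect_error(apply_gates(tb, list(gate_threshold("g", "nope", "above", 0))),
               "unknown feature")
  expect_error(apply_gates(tb, list(
    gate_threshold("a", "x", "above", 0, parent = "b"),
    gate_threshold("b", "x", "above", 0))), "not defined before")
  expect_error(apply_gates(tb, list(
    gate_threshold("a", "x", "above", 0),
    gate_threshold("a", "x", "below", 1))), "duplicated gate names")
})

test_that("percent positive and its summary follow the counting identities", {
  tb <- tibble::tibble(cell_id = sprintf("c%d", 1:30),
                       sample_id = rep(c("s1", "s2", "s3"), each = 10),
                       v = rep(c(rep(1, 8), 0, 0), 3))
  tb$v[tb$sample_id == "s1"][9] <- 1       # s1: 9/10
  tb$v[tb$sample_id == "s3"][c(9, 10)] <- 1  # s3: 10/10
  res <- apply_gates(tb, list(gate_threshold("pos", "v", "above", 0.5)))
  pp <- percent_positive(res, "pos")
  expect_equal(pp$percent[pp$sample_id == "s1"], 90)
  expect_equal(pp$percent[pp$sample_id == "s2"], 80)
  expect_equal(pp$percent[pp$sample_id == "s3"], 100)
  sm <- pop_summary(pp)
  expect_equal(sm$mean, 90)
  expect_equal(sm$sem, 5.7735, tolerance = 1e-4)

  zero <- apply_gates(tb, list(gate_threshold("none", "v", "above", 2)))
  expect_equal(percent_positive(zero, "none")$percent, c(0, 0, 0))
})

test_that("the SA+/SA- sum rule holds exactly", {
  set.seed(3)
  tb <- tibble::tibble(cell_id = sprintf("c%d", 1:200),
                       sample_id = sample(c("a", "b"), 200, TRUE),
                       bf = rnorm(200))
  gates <- list(gate_threshold("root", "bf", "above", -10),
                gate_threshold("sa_pos", "bf", "below", -0.3, parent = "root"),
                gate_boolean("sa_neg", "NOT", "sa_pos", parent = "root"))
  res <- apply_gates(tb, gates)
  pos <- percent_positive(res, "sa_pos")
  neg <- percent_positive(res, "sa_neg")
  expect_equal(pos$percent + neg$percent, c(100, 100))
})

test_that("area comparison inside vs outside a gate recovers an injected shift", {
  set.seed(5)
  n <- 400
  big <- rbinom(n, 1, 0.3) == 1
  tb <- tibble::tibble(cell_id = sprintf("c%d", 1:n), sample_id = "s",
                       area_um2 = ifelse(big, rnorm(n, 650, 40), rnorm(n, 450, 40)),
                       marker = ifelse(big, 1, 0))
  res <- apply_gates(tb, list(gate_threshold("pos", "marker", "above", 0.5)))
  ab <- area_by_gate(tb, res, "pos")
  m_in <- ab$mean_area_um2[ab$population == "in_gate"]
  m_out <- ab$mean_area_um2[ab$population == "out_gate"]
  expect_equal(m_in, 650, tolerance = 0.02)
  expect_equal(m_out, 450, tolerance = 0.02)

  same <- tb; same$area_um2 <- 500
  res2 <- apply_gates(same, list(gate_threshold("pos", "marker", "above", 0.5)))
  ab2 <- area_by_gate(same, res2, "pos")
  expect_equal(unique(ab2$mean_area_um2), 500)

  empty <- apply_gates(tb, list(gate_threshold("none", "marker", "above", 5)))
  expect_error(area_by_gate(tb, empty, "none"), "empty")
})

test_that("the pooled t-test matches the closed form and base R", {
  out <- two_sample_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$t, -1.224745, tolerance = 1e-6)
  expect_equal(out$df, 4)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-9)

  swap <- two_sample_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swap$t, -out$t)
  expect_equal(swap$p_value, out$p_value)

  same <- two_sample_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(two_sample_test(1, c(1, 2)), "at least 2")
})
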