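pair_row <- function(b_i = 0.8, b_j = 0.3, l_i = 5L, l_j = 2L, s_i = 0, s_j = 0) {
  tibble::tibble(b_i = b_i, b_j = b_j, l_i = l_i, l_j = l_j, s_i = s_i, s_j = s_j)
}

test_that("hinge losses reproduce direct formula evaluations", {
  cfg <- loss_config(c = 0.2, r = 0.2)
  # value-based: margin met / violated / saturated
  expect_equal(hinge_value_loss(pair_row(b_i = 0.8, b_j = 0.3, s_i = 0.7, s_j = 0), cfg), 0)
  expect_equal(hinge_value_loss(pair_row(b_i = 0.8, b_j = 0.3, s_i = 0.4, s_j = 0), cfg), 0.3)
  expect_equal(hinge_value_loss(pair_row(s_i = 1e6, s_j = 0), cfg), 0)
  # level-based: margin r*(l_i - l_j); independent of b
  expect_equal(hinge_level_loss(pair_row(l_i = 5L, l_j = 1L, s_i = 1, s_j = 0), cfg), 0)
  expect_equal(hinge_level_loss(pair_row(l_i = 3L, l_j = 2L, s_i = 0, s_j = 0), cfg), 0.2)
  expect_equal(hinge_level_loss(pair_row(b_i = 0.99, l_i = 3L, l_j = 2L), cfg),
               hinge_level_loss(pair_row(b_i = 0.01, l_i = 3L, l_j = 2L), cfg))
  # constrained: same-level tolerance band
  expect_equal(hinge_constrained_loss(pair_row(l_i = 3L, l_j = 3L, s_i = 0.1, s_j = 0), cfg), 0)
  expect_equal(hinge_constrained_loss(pair_row(l_i = 3L, l_j = 3L, s_i = 0.5, s_j = 0), cfg), 0.3)
  # cross-level pairs must be ordered
  expect_error(hinge_value_loss(pair_row(l_i = 2L, l_j = 5L)), class = "peprank_pair_error")
  expect_error(hinge_level_loss(pair_row(l_i = 3L, l_j = 3L)), class = "peprank_pair_error")
})

test_that("constrained hinge equals the level hinge on cross-level pairs", {
  withr::with_seed(5, {
    pairs <- tibble::tibble(
      l_i = sample(2:5, 200, replace = TRUE))
    pairs$l_j <- vapply(pairs$l_i, function(l) sample.int(l - 1L, 1), integer(1))
    pairs$b_i <- runif(200); pairs$b_j <- runif(200)
    pairs$s_i <- rnorm(200); pairs$s_j <- rnorm(200)
    expect_equal(hinge_constrained_loss(pairs), hinge_level_loss(pairs))
  })
})

test_that("hinge losses are piecewise-linear in the score gap with slope -1 then 0", {
  cfg <- loss_config()
  gaps <- seq(-2, 2, by = 0.01)
  pr <- pair_row(b_i = 0.7, b_j = 0.2, l_i = 4L, l_j = 2L)
  for (fn in list(hinge_value_loss, hinge_level_loss, hinge_constrained_loss)) {
    vals <- vapply(gaps, function(g) fn(dplyr::mutate(pr, s_i = g, s_j = 0), cfg), numeric(1))
    expect_true(all(vals >= 0))
    slopes <- diff(vals) / diff(gaps)
    expect_true(all(abs(slopes + 1) < 1e-9 | abs(slopes) < 1e-9))
    # below the margin the slope is -1, above it 0
    expect_equal(vals[1], vals[2] + 0.01, tolerance = 1e-9)
    expect_equal(vals[length(vals)], 0)
  }
})

test_that("mean-square loss follows the piecewise one-sided definition", {
  mk <- function(kind, b, level, score) {
    tibble::tibble(kind = kind, b = b, level = level, score = score)
  }
  expect_equal(mean_square_loss(mk("quantitative", 0.4, 3L, 0.6)), 0.04)
  # negative qualitative entries are free below the threshold
  expect_equal(mean_square_loss(mk("qualitative", NA, 1L, 0.1)), 0)
  b5000 <- level_threshold_affinity(1)
  expect_equal(mean_square_loss(mk("qualitative", NA, 1L, 0.5)), (0.5 - b5000)^2)
  # positive qualitative entries are penalized only below their threshold
  b100 <- normalize_affinity(100)
  expect_equal(mean_square_loss(mk("qualitative", NA, 5L, 0.3)), (b100 - 0.3)^2)
  expect_equal(mean_square_loss(mk("qualitative", NA, 5L, 0.95)), 0)
  expect_error(mean_square_loss(mk("quantitative", 0.4, 3L, 1.2)),
               class = "peprank_pair_error")
})

test_that("losses match brute-force formula evaluation on random tuples", {
  cfg <- loss_config()
  withr::with_seed(42, {
    n <- 500
    l_i <- sample(2:5, n, replace = TRUE)
    l_j <- vapply(l_i, function(l) sample.int(l - 1L, 1), integer(1))
    tup <- tibble::tibble(l_i = l_i, l_j = l_j, b_i = runif(n), b_j = runif(n),
                          s_i = rnorm(n), s_j = rnorm(n))
    expect_equal(hinge_value_loss(tup, cfg),
                 pmax(0, 0.2 + (tup$b_i - tup$b_j) - (tup$s_i - tup$s_j)),
                 tolerance = 1e-12)
    expect_equal(hinge_level_loss(tup, cfg),
                 pmax(0, 0.2 * (tup$l_i - tup$l_j) - (tup$s_i - tup$s_j)),
                 tolerance = 1e-12)
  })
})

test_that("batch aggregation is a mean, invariant to pair order", {
  withr::with_seed(9, {
    scores <- rnorm(10)
    pairs <- tibble::tibble(i = sample(1:5, 30, TRUE), j = sample(6:10, 30, TRUE),
                            b_i = runif(30), b_j = runif(30),
                            l_i = 5L, l_j = 2L)
    out <- peprank:::.batch_loss_grad(scores, "hv", pairs = pairs)
    perm <- sample.int(30)
    out2 <- peprank:::.batch_loss_grad(scores, "hv", pairs = pairs[perm, ])
    expect_equal(out$loss, out2$loss)
    expect_equal(out$dscore, out2$dscore)
    manual <- mean(hinge_value_loss(dplyr::mutate(pairs, s_i = scores[i], s_j = scores[j])))
    expect_equal(out$loss, manual)
  })
})
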