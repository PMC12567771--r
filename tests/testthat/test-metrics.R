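test_that("ARI matches hand-derived and degenerate cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  # hand evaluation of the pair-counting formula
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # one-cluster partition against anything: expected-index degeneracy
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0.0)
  expect_error(adjusted_rand_index(1:4, 1:5), "shape")
  expect_error(adjusted_rand_index(1, 1), "two")
})

test_that("ARI equals the brute-force pair-counting oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    ka <- sample(2:6, 1); kb <- sample(2:6, 1)
    a <- sample(seq_len(ka), n, replace = TRUE)
    b <- sample(seq_len(kb), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (rep in 1:10) {
    a <- sample(1:4, 150, replace = TRUE)
    b <- sample(1:3, 150, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI is bounded, permutation-invariant and centred near zero", {
  set.seed(55)
  vals <- replicate(1000, {
    a <- sample(1:3, 100, replace = TRUE)
    b <- sample(1:3, 100, replace = TRUE)
    adjusted_rand_index(a, b)
  })
  expect_true(all(vals >= -1 & vals <= 1))
  expect_lt(abs(mean(vals)), 0.02)

  a <- sample(1:4, 80, replace = TRUE)
  b <- sample(1:4, 80, replace = TRUE)
  perm <- c(4, 1, 3, 2)
  expect_equal(adjusted_rand_index(a, b),
               adjusted_rand_index(perm[a], b), tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, b),
               adjusted_rand_index(a, perm[b]), tolerance = 1e-12)
})

test_that("Davies-Bouldin matches hand computation and its invariances", {
  # 1-D clusters {0, 1} and {10, 11}: S = 0.5 each, M = 10 -> DBI = 0.1
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(0, 0, 1, 1)
  expect_equal(davies_bouldin(X, lab), 0.1, tolerance = 1e-12)

  # invariance to scaling, translation, rotation
  set.seed(17)
  P <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 5), 20, 2))
  l2 <- rep(0:1, each = 20)
  d0 <- davies_bouldin(P, l2)
  expect_equal(davies_bouldin(3.7 * P, l2), d0, tolerance = 1e-9)
  expect_equal(davies_bouldin(P + 100, l2), d0, tolerance = 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(davies_bouldin(P %*% R, l2), d0, tolerance = 1e-9)

  # separating clusters drives the index monotonically toward zero
  seps <- c(5, 10, 20, 40)
  dbis <- vapply(seps, function(s) {
    Q <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, s), 20, 2))
    davies_bouldin(Q, l2)
  }, numeric(1))
  expect_true(all(diff(dbis) < 0))

  expect_error(davies_bouldin(X, rep(1, 4)), "two clusters")
  expect_error(davies_bouldin(matrix(c(0, 0, 1, 1), 4, 1),
                              c(0, 1, 0, 1)), "coincident")
})

test_that("segmentation comparison handles resolution mismatch", {
  p <- small_phantom(seed = 5, cv = 0)
  truth <- as_segmentation(p$labels, p$pitch)

  # self comparison and label-permuted comparison both give ARI 1
  expect_equal(compare_segmentations(truth, truth)$ari, 1.0)
  perm <- c(2L, 0L, 4L, 3L, 1L)
  permuted <- as_segmentation(matrix(perm[p$labels + 1L],
                                     nrow(p$labels)), p$pitch)
  expect_equal(compare_segmentations(truth, permuted)$ari, 1.0)

  # 4x block degradation: agreement drops but stays structured
  coarse <- as_segmentation(
    p$labels[seq(1, nrow(p$labels), 4), seq(1, ncol(p$labels), 4)],
    p$pitch * 4
  )
  cmp <- compare_segmentations(truth, coarse)
  expect_lt(cmp$ari, 1)
  expect_gt(cmp$ari, 0.5)
  expect_equal(cmp$pitch_b, p$pitch * 4)
})

test_that("contingency tables carry consistent marginals", {
  a <- c(0, 0, 1, 1, 2)
  b <- c(0, 1, 1, 1, 2)
  tab <- contingency_table(a, b)
  expect_equal(sum(tab), 5)
  expect_equal(as.vector(rowSums(tab)), c(2, 2, 1))
  expect_equal(as.vector(colSums(tab)), c(1, 3, 1))
})

test_that("contrast curve follows the square-wave Gaussian MTF", {
  curve <- contrast_curve(spot_profile(22), raster_grid(5))
  expect_equal(nrow(curve), 18)
  # near-DC limit: >= 0.99 at 1.25 lp/mm, never above 1 + tolerance
  expect_gte(curve$contrast[1], 0.99)
  expect_true(all(curve$contrast <= 1.001))

  # closed form within 3% for f <= 80 lp/mm
  keep <- curve$frequency <= 80
  sigma_mm <- 5.5e-3
  theory <- exp(-2 * pi^2 * sigma_mm^2 * curve$frequency[keep]^2)
  expect_true(all(abs(curve$contrast[keep] / theory - 1) < 0.03))

  # strictly decreasing over the measurable ladder
  meas <- curve$contrast[!curve$aliased]
  expect_true(all(diff(meas) < 0))

  # frequencies beyond the raster Nyquist are flagged, not measured
  curve20 <- contrast_curve(spot_profile(22), raster_grid(20))
  expect_true(all(curve20$aliased[curve20$frequency > 25]))
  expect_true(all(curve20$contrast[curve20$aliased] == 0))
})

test_that("resolution limit reads the threshold crossing of the curve", {
  curve <- tibble::tibble(frequency = c(10, 20, 40),
                          contrast = c(0.9, 0.5, 0.1),
                          aliased = FALSE)
  expect_equal(resolution_limit(curve, 0.2), 20)
  expect_equal(resolution_limit(curve, 0.05), 40)  # all above threshold
  expect_equal(resolution_limit(curve, 0.95), 0)   # none above

  # monotonicity in spot size and sampling rate
  lim <- function(d, step) {
    resolution_limit(contrast_curve(spot_profile(d), raster_grid(step)))
  }
  expect_lte(lim(30, 5), lim(22, 5))
  expect_lte(lim(22, 20), lim(22, 5))
  # near-ideal system resolves the entire ladder
  expect_equal(lim(1, 1), 250)
})
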