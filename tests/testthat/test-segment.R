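blob_cube <- function(centers, n_per = 40, spread = 0.1, seed = 1) {
  # synthetic feature cube: k well-separated Gaussian blobs laid out as
  # two layers of a rectangular image
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rnorm(n_per, centers[i, 1], spread),
          rnorm(n_per, centers[i, 2], spread))
  }))
  n <- nrow(X)
  datacube(list(a = matrix(X[, 1], n, 1), b = matrix(X[, 2], n, 1)),
           pitch = 1)
}

test_that("k = 1 reduces to the global mean in closed form", {
  cube <- blob_cube(matrix(c(0, 0, 5, 5), 2, byrow = TRUE), seed = 3)
  X <- cube_matrix(cube)
  fit <- fit_kmeans(cube, k = 1, n_init = 2, seed = 1)
  expect_equal(as.vector(fit$centroids), unname(colMeans(X)),
               tolerance = 1e-12)
  expect_equal(fit$inertia, sum(scale(X, scale = FALSE)^2),
               tolerance = 1e-9)
})

test_that("well-separated blobs are recovered near their true means", {
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, byrow = TRUE)
  cube <- blob_cube(centers, spread = 0.5, seed = 5)
  fit <- fit_kmeans(cube, k = 3, seed = 2)
  # each true mean has a centroid within 0.1 * spread * sqrt(n) slack
  for (i in seq_len(3)) {
    d <- sqrt(rowSums((fit$centroids -
                         matrix(centers[i, ], 3, 2, byrow = TRUE))^2))
    expect_lt(min(d), 0.1 * 0.5 * 3)
  }
})

test_that("restarts keep the best inertia and stay deterministic", {
  cube <- blob_cube(matrix(c(0, 0, 4, 0, 0, 4, 4, 4), 4, byrow = TRUE),
                    spread = 0.8, seed = 7)
  fit <- fit_kmeans(cube, k = 4, n_init = 10, seed = 3)
  expect_true(all(fit$inertia <= fit$restart_inertias + 1e-9))
  fit2 <- fit_kmeans(cube, k = 4, n_init = 10, seed = 3)
  expect_identical(fit$centroids, fit2$centroids)
  # the alternative initialization reading also runs
  fitc <- fit_kmeans(cube, k = 4, n_init = 10, seed = 3,
                     init_method = "candidates")
  expect_s3_class(fitc, "miraf_kmeans")

  expect_error(fit_kmeans(datacube(list(a = matrix(1, 4, 4)), 1), k = 2),
               "distinct")
})

test_that("inertia is non-increasing in k on fixed data and seed", {
  cube <- blob_cube(matrix(c(0, 0, 6, 0, 0, 6, 6, 6, 3, 3), 5,
                           byrow = TRUE), spread = 0.7, seed = 11)
  inertias <- vapply(2:6, function(k) {
    fit_kmeans(cube, k = k, seed = 4)$inertia
  }, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
})

test_that("segmentation assigns nearest centroids with stable ties", {
  cube <- blob_cube(matrix(c(0, 0, 8, 8), 2, byrow = TRUE), seed = 9)
  fit <- fit_kmeans(cube, k = 2, seed = 1)
  seg <- segment_cube(cube, fit)
  expect_true(all(seg$labels %in% c(0L, 1L)))

  # a pixel equal to a centroid gets that centroid's label
  probe <- datacube(list(a = matrix(fit$centroids[2, 1], 1, 1),
                         b = matrix(fit$centroids[2, 2], 1, 1)),
                    pitch = 1)
  expect_equal(as.vector(segment_cube(probe, fit)$labels), 1L)

  # relabeling (permuting) centroids permutes labels identically
  fitp <- fit
  fitp$centroids <- fit$centroids[c(2, 1), ]
  segp <- segment_cube(cube, fitp)
  expect_equal(segp$labels, 1L - seg$labels)

  # equidistant point: tie broken toward the lowest index
  fit_tie <- fit
  fit_tie$centroids <- matrix(c(0, 2, 0, 2), 2)
  mid <- datacube(list(a = matrix(1, 1, 1), b = matrix(1, 1, 1)),
                  pitch = 1)
  expect_equal(as.vector(segment_cube(mid, fit_tie)$labels), 0L)

  expect_error(segment_cube(datacube(list(a = matrix(1, 2, 2)), 1), fit),
               "dimension")
})

test_that("Davies-Bouldin sweep selects the generative cluster count", {
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 18), 5, byrow = TRUE)
  cube <- blob_cube(centers, spread = 0.4, seed = 13)
  sw <- sweep_k(cube, k_range = 2:8, seed = 5)
  expect_equal(sw$best_k, 5)
  sw2 <- sweep_k(cube, k_range = 2:8, seed = 5)
  expect_identical(sw$scores, sw2$scores)
})

test_that("label harmonization finds the optimal assignment", {
  p <- small_phantom(seed = 4, cv = 0)
  seg_a <- as_segmentation(p$labels, p$pitch)
  # permuted copy harmonizes back to identity
  perm <- c(3L, 4L, 0L, 2L, 1L)
  seg_b <- as_segmentation(matrix(perm[p$labels + 1L], nrow(p$labels)),
                           p$pitch)
  h <- harmonize_labels(seg_a, seg_b)
  expect_identical(h$labels, seg_a$labels)
  # ARI unchanged by harmonization
  expect_equal(adjusted_rand_index(seg_a, seg_b),
               adjusted_rand_index(seg_a, h))

  # 3-label toy table against brute force over all 3! permutations
  set.seed(31)
  a <- sample(0:2, 60, replace = TRUE)
  b <- sample(0:2, 60, replace = TRUE)
  sa <- as_segmentation(matrix(a, 6), 1)
  sb <- as_segmentation(matrix(b, 6), 1)
  h3 <- harmonize_labels(sa, sb)
  agree <- sum(h3$labels == sa$labels)
  perms <- list(c(0, 1, 2), c(0, 2, 1), c(1, 0, 2), c(1, 2, 0),
                c(2, 0, 1), c(2, 1, 0))
  best <- max(vapply(perms, function(pm) {
    sum(pm[b + 1] == a)
  }, numeric(1)))
  expect_equal(agree, best)

  expect_error(harmonize_labels(sa, as_segmentation(matrix(0L, 2, 2), 1)),
               "shape")
})

test_that("noiseless cv = 0 cubes are segmented exactly (recovery oracle)", {
  p <- generate_brain_phantom(phantom_config(width = 128, height = 128,
                                             seed = 21),
                              tissue_classes(cv = 0))
  cube <- ideal_multimodal_cube(p, seed = 21)
  fit <- fit_kmeans(cube, k = 5, seed = 21)
  seg <- segment_cube(cube, fit)
  expect_equal(adjusted_rand_index(p$labels, seg$labels), 1.0)
  # harmonized labels literally equal the ground truth
  h <- harmonize_labels(as_segmentation(p$labels, p$pitch), seg)
  expect_identical(h$labels, p$labels)
})
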