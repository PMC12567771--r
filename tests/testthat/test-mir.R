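test_that("absorbance field follows the additive Beer-Lambert model", {
  p <- stripe_phantom()
  bands <- mir_bands()
  l3 <- bands[bands$id == "L3", ]

  # empty substrate: zero concentration -> zero absorbance
  p0 <- p
  for (s in names(p0$chem)) p0$chem[[s]][] <- 0
  expect_true(all(absorbance_field(p0, l3) == 0))

  # single species direct arithmetic: eps * c * l
  p1 <- p0
  p1$chem$lipid[] <- 0.25
  line <- l3; line$eps_lipid <- 2; line$eps_protein <- 0; line$eps_water <- 0
  expect_true(all(abs(absorbance_field(p1, line, l = 2) - 1) < 1e-12))

  # additivity over species equals the sum of single-species fields
  p2 <- p0; p2$chem$lipid <- p$chem$lipid
  p3 <- p0; p3$chem$protein <- p$chem$protein
  p4 <- p0; p4$chem$water <- p$chem$water
  A_sum <- absorbance_field(p2, l3) + absorbance_field(p3, l3) +
    absorbance_field(p4, l3)
  expect_equal(absorbance_field(p, l3), A_sum, tolerance = 1e-12)

  expect_error({
    pneg <- p; pneg$chem$lipid[1, 1] <- -1
    absorbance_field(pneg, l3)
  }, "negative")
})

test_that("scattering baseline follows the linear-in-wavenumber model", {
  bands <- mir_bands()
  A <- matrix(0.3, 8, 8)
  sc <- matrix(0.5, 8, 8)
  # zero scatter leaves absorbance unchanged
  expect_equal(signal_with_scatter(A, 0 * sc, bands[1, ]), A)
  # a reference laser over tissue carries only the baseline
  A0 <- 0 * A
  B <- signal_with_scatter(A0, sc, bands[1, ], b0 = 0.1, b1 = 5e-5)
  expect_equal(B, sc * (0.1 + 5e-5 * 3704))
  # flat baseline (b1 = 0) is identical at all four wavenumbers
  Bs <- lapply(seq_len(4), function(i) {
    signal_with_scatter(A0, sc, bands[i, ], b0 = 0.1, b1 = 0)
  })
  for (i in 2:4) expect_equal(Bs[[i]], Bs[[1]])
})

test_that("flying-spot scan transduces constant fields exactly", {
  f <- img2d(matrix(0.4, 60, 60), pitch = 5)
  scan <- flying_spot_scan(f, grid = raster_grid(20), noise_sd = 0,
                           i_ref = 50000)
  expect_true(all(abs(scan$values - 50000 * 10^(-0.4)) < 1e-9))
  expect_error(flying_spot_scan(f, i_ref = 0), "i_ref")
})

test_that("point response of the scan has the configured 1/e2 diameter", {
  n <- 201
  A <- matrix(0, n, n)
  A[101, 101] <- 1
  spot <- spot_profile(22)
  scan <- flying_spot_scan(img2d(A, pitch = 1), spot = spot,
                           grid = raster_grid(1), noise_sd = 0,
                           i_ref = 50000)
  deficit <- 50000 - scan$values
  # second-moment width of the (small-signal, hence linear) response
  xs <- seq_len(n) - 101
  w <- colSums(deficit)
  sigma_meas <- sqrt(sum(w * xs^2) / sum(w))
  expect_equal(4 * sigma_meas, spot$diameter_1e2, tolerance = 0.05)
})

test_that("sinusoidal modulation is attenuated by the Gaussian MTF", {
  # low-amplitude cosine absorbance at three frequencies
  spot <- spot_profile(22)
  for (f_lpmm in c(10, 25, 50)) {
    f_um <- f_lpmm / 1000
    period <- 1 / f_um
    n <- round(20 * period)
    x <- (seq_len(n) - 0.5)
    A <- matrix(0.2 + 0.01 * cos(2 * pi * f_um * x), 24, n, byrow = TRUE)
    scan <- flying_spot_scan(img2d(A, pitch = 1), spot = spot,
                             grid = raster_grid(5), noise_sd = 0,
                             i_ref = 50000)
    Arec <- to_absorbance(normalize_counts(scan), 50000 / 65535)
    prof <- colMeans(Arec$values)
    # drop the blur-contaminated edges and keep an integer number of
    # periods (the period is a multiple of the 5 um step at these
    # frequencies) so the projection is leakage-free
    per_samples <- period / 5
    i0 <- ceiling(4 * spot$sigma / 5) + 1
    avail <- length(prof) - 2 * (i0 - 1)
    m <- floor(avail / per_samples) * per_samples
    idx <- i0:(i0 + m - 1)
    xs <- (idx - 1) * 5
    coef <- sum((prof[idx] - mean(prof[idx])) *
                  exp(-2i * pi * f_um * xs)) / m
    meas <- 2 * Mod(coef) / 0.01
    expect_equal(meas, exp(-2 * pi^2 * (5.5 * f_um)^2), tolerance = 0.02)
  }
})

test_that("noiseless scans invert exactly to the spot-averaged field", {
  p <- small_phantom(seed = 2)
  bands <- mir_bands()
  line <- bands[bands$id == "L2", ]
  A_eff <- signal_with_scatter(absorbance_field(p, line), p$scatter, line)
  scan <- flying_spot_scan(img2d(A_eff, p$pitch, "L2"), noise_sd = 0,
                           i_ref = 50000)
  Arec <- to_absorbance(normalize_counts(scan), 50000 / 65535)
  oracle <- miraf:::spot_sample(img2d(A_eff, p$pitch, "L2"),
                                spot_profile(), raster_grid())
  expect_lt(max(abs(Arec$values - oracle)), 1e-9)
})

test_that("counts decrease monotonically with absorbance", {
  A <- matrix(seq(0, 2, length.out = 100), 10, 10)
  scan <- flying_spot_scan(img2d(A, pitch = 20), spot = spot_profile(1e-6),
                           grid = raster_grid(20), noise_sd = 0)
  o <- order(as.vector(A))
  expect_true(all(diff(as.vector(scan$values)[o]) <= 0))
})

test_that("simulate_mir honours sampling arithmetic and chemistry", {
  p <- generate_brain_phantom(phantom_config(width = 200, height = 200,
                                             seed = 2))
  s20 <- simulate_mir(p, grid = raster_grid(20), noise_sd = 0)
  s5 <- simulate_mir(p, grid = raster_grid(5), noise_sd = 0)
  expect_equal(dim(s5$images$L2), 4 * dim(s20$images$L2))

  # raster refinement: every 4th sample of the 5 um scan is the 20 um scan
  sub <- s5$images$L2[seq(1, nrow(s5$images$L2), 4),
                      seq(1, ncol(s5$images$L2), 4)]
  expect_equal(sub, s20$images$L2, tolerance = 1e-12)

  # white matter darker (more absorbing) than gray matter at 2928 cm-1,
  # verified against a per-pixel oracle on interior pixels
  lab20 <- p$labels[seq(1, 199, 10), seq(1, 199, 10)]
  wm <- s20$images$L3[lab20 == 3L]
  gm <- s20$images$L3[lab20 == 2L]
  expect_lt(mean(wm), mean(gm))

  # reference laser over a background-only phantom is ~uniform at i_ref
  p0 <- p
  p0$labels[] <- 0L
  for (s in names(p0$chem)) p0$chem[[s]][] <- 0
  for (s in names(p0$fluor)) p0$fluor[[s]][] <- 0
  p0$scatter[] <- 1e-6
  s0 <- simulate_mir(p0, noise_sd = 0, i_ref = 50000)
  expect_equal(mean(s0$images$L1), 50000, tolerance = 0.01)

  # determinism under seed
  expect_identical(simulate_mir(p, seed = 5), simulate_mir(p, seed = 5))
})

test_that("FTIR variant box-averages and reports absorbance directly", {
  p <- stripe_phantom(stripe_um = 10, n = 200)
  f6 <- simulate_ftir(p, pixel_pitch = 6.25, noise_sd = 0)
  f25 <- simulate_ftir(p, pixel_pitch = 25, noise_sd = 0)
  expect_equal(dim(f25$images$L3) * 4, dim(f6$images$L3))

  # noiseless constant-composition region: absorbance equals the
  # Beer-Lambert value plus the baseline, exactly
  line <- ftir_bands()[ftir_bands()$id == "L3", ]
  gm_val <- unique(absorbance_field(p, line)[p$labels == 2L]) +
    0.3 * (0.1 + 5e-5 * line$wavenumber)
  corner <- f6$images$L3[1:5, 1:5]
  expect_true(all(abs(corner - gm_val) < 1e-9))

  # a 10 um structure is visible at 6.25 um pitch, washed out at 25 um
  contrast <- function(img) {
    prof <- colMeans(img)
    (max(prof) - stats::median(prof)) / stats::median(prof)
  }
  expect_gt(contrast(f6$images$L3) / contrast(f25$images$L3), 2)
})
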