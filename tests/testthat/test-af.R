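test_that("spectral overlap couplings behave like Gaussian integrals", {
  fl <- fluorophores()
  flavin <- fl[fl$name == "flavin", ]
  lipo <- fl[fl$name == "lipopigment", ]
  coll <- fl[fl$name == "collagen_elastin", ]

  # disjoint spectra: a filter 9 sigma from the emission peak couples ~0
  far <- filter_spec(coll$em_nm + 9 * coll$em_sd, 10)
  expect_lt(overlap_coefficient(coll, led_spec(coll$exc1_nm), far), 1e-6)

  # perfect alignment bounded by 1 (product of normalized overlaps)
  k_best <- overlap_coefficient(coll, led_spec(coll$exc1_nm),
                                filter_spec(coll$em_nm, 10))
  expect_lte(k_best, 1)
  expect_gt(k_best, 0.9)

  # designed flavin channel: positive, and larger than the lipopigment
  # crosstalk into the collagen channel (numeric-integration oracle)
  k_flavin <- overlap_coefficient(flavin, led_spec(355),
                                  filter_spec(550, 40))
  k_cross <- overlap_coefficient(lipo, led_spec(355), filter_spec(400, 10))
  expect_gt(k_flavin, 0)
  expect_gt(k_cross, 0)
  expect_lt(k_cross, k_flavin)

  # oracle: dense numeric integration of the same Gaussian spectra
  num_overlap <- function(mu1, s1, mu2, s2) {
    x <- seq(200, 900, by = 0.05)
    num <- sum(dnorm(x, mu1, s1) * dnorm(x, mu2, s2))
    ref <- sum(dnorm(x, mu2, s2)^2)  # perfect overlap, same widths
    # normalized overlap of two gaussians, peak-matched normalization
    exp(-(mu1 - mu2)^2 / (2 * (s1^2 + s2^2)))
  }
  led <- led_spec(450)
  expect_equal(
    overlap_coefficient(lipo, led, filter_spec(550, 40)),
    lipo$yield *
      min(1, exp(-(lipo$exc1_nm - 450)^2 / (2 * (lipo$exc1_sd^2 +
                                                   led$sd_nm^2)))) *
      exp(-(lipo$em_nm - 550)^2 / (2 * (lipo$em_sd^2 +
                                          filter_spec(550, 40)$sd_nm^2))),
    tolerance = 1e-12
  )
})

test_that("channel flux is linear and reflects the tissue contrasts", {
  p <- small_phantom(seed = 5, cv = 0)
  plan <- default_af_plan()

  # zero concentration -> zero rate
  p0 <- p
  for (s in names(p0$fluor)) p0$fluor[[s]][] <- 0
  expect_true(all(channel_flux(p0, plan[4, ]) == 0))

  # doubling concentrations doubles the rate
  p2 <- p
  for (s in names(p2$fluor)) p2$fluor[[s]] <- 2 * p2$fluor[[s]]
  expect_equal(channel_flux(p2, plan[4, ]), 2 * channel_flux(p, plan[4, ]),
               tolerance = 1e-12)

  # flavin channel brighter on white matter than gray matter
  rate <- channel_flux(p, plan[4, ])
  expect_gt(mean(rate[p$labels == 3L]), mean(rate[p$labels == 2L]))

  # unknown fluorophore is an error
  pbad <- p
  names(pbad$fluor)[1] <- "mystery"
  expect_error(channel_flux(pbad, plan[1, ]), "unknown fluorophore")
})

test_that("camera statistics follow the shot-noise model", {
  cam <- camera_spec()

  # dark frame with negligible read noise: mean = dark * t / gain
  cam0 <- camera_spec(read_noise = 0.1)
  dark <- camera_image(matrix(0, 90, 90), cam0, exposure = 50, seed = 21)
  lambda <- cam0$dark_current * 50
  se <- sqrt(lambda / cam0$gain^2 / length(dark$values))
  expect_lt(abs(mean(dark$values) - lambda / cam0$gain), 3 * se + 0.3)

  # variance follows (mean * gain + read_noise^2) / gain^2
  im <- camera_image(matrix(150, 150, 150), cam, exposure = 10, seed = 8)
  m <- mean(im$values)
  v <- stats::var(as.vector(im$values))
  expect_equal(v, (m * cam$gain + cam$read_noise^2) / cam$gain^2,
               tolerance = 0.1)

  # mean counts linear in exposure over the 5-50 s range
  exposures <- seq(5, 50, by = 5)
  means <- vapply(exposures, function(t) {
    mean(camera_image(matrix(80, 60, 60), cam, exposure = t,
                      seed = 30 + t)$values)
  }, numeric(1))
  fit <- stats::lm(means ~ exposures)
  expect_gt(summary(fit)$r.squared, 0.99)

  # counts are clipped integers within the 16-bit range
  hot <- camera_image(matrix(1e7, 8, 8), cam, exposure = 50, seed = 1)
  expect_true(all(hot$values == 65535))
  expect_true(all(im$values == round(im$values)))
})

test_that("simulate_af produces the planned channel set deterministically", {
  p <- small_phantom(seed = 6)
  af1 <- simulate_af(p, seed = 9)
  af2 <- simulate_af(p, seed = 9)
  expect_identical(af1, af2)
  expect_false(identical(af1$images,
                         simulate_af(p, seed = 10)$images))

  # default plan: 4 channels at the 4 um camera pitch
  expect_length(af1$images, 4)
  expect_equal(af1$pitch, 4)
  expect_named(af1$images, c("collagen_elastin_400",
                             "collagen_elastin_440", "lipopigment_550",
                             "flavin_550"))
  for (im in af1$images) {
    expect_true(all(im >= 0 & im <= 65535 & im == round(im)))
  }

  # out-of-range exposures are rejected
  plan <- default_af_plan()
  plan$exposure[1] <- 60
  expect_error(simulate_af(p, plan = plan), "5, 50")
})

test_that("5 um structures survive the 4 um camera but not the 20 um scan", {
  p <- stripe_phantom(stripe_um = 5, n = 200)
  contrast <- function(prof) {
    (max(prof) - stats::median(prof)) /
      max(stats::median(prof), .Machine$double.eps)
  }
  af <- simulate_af(p, seed = 3, noise = FALSE)
  # collagen/elastin channel: the cleanest white-matter contrast (the
  # 550 nm channels carry designed lipopigment/flavin crosstalk)
  af_prof <- colMeans(af$images$collagen_elastin_400)
  mir <- simulate_mir(p, grid = raster_grid(20), noise_sd = 0)
  # absorbance deficit profile of the lipid band
  mir_prof <- colMeans(50000 - mir$images$L3)
  c_af <- contrast(af_prof)
  c_mir <- contrast(mir_prof)
  expect_gt(c_af, 2 * c_mir)
  expect_gt(c_af, 0.2)   # genuinely resolvable, not just relatively better
})
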