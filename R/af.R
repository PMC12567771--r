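# Forward model of the autofluorescence camera path: LED excitation,
# Gaussian fluorophore excitation/emission spectra, band-pass emission
# filters and a CCD camera with shot, dark and read noise.
#
# Because the emission bands of the endogenous fluorophores overlap
# substantially, channels are designed (not unmixed): each channel is an
# LED x filter combination targeting one biomolecule, and every fluorophore
# contributes to every channel through its spectral overlap. Only relative
# count images are produced; no operation reports absolute concentrations.

#' Endogenous fluorophore spectral table
#'
#' Gaussian approximations of the excitation and emission spectra of the
#' three modelled fluorophore groups: collagen/elastin (UV-excited,
#' 400-440 nm emission), flavins/FAD (dual excitation near 360 and 450 nm,
#' 500-600 nm emission) and lipopigments (lipofuscin-like; 400-500 nm
#' excitation, broad long-wavelength emission). Widths are Gaussian sigmas
#' in nm; `yield` is a relative quantum yield.
#'
#' @return A tibble with columns `name`, `exc1_nm`, `exc1_sd`, `exc2_nm`,
#'   `exc2_sd` (NA when the fluorophore has a single excitation peak),
#'   `em_nm`, `em_sd`, `yield`.
#' @export
fluorophores <- function() {
  tibble::tibble(
    name = c("collagen_elastin", "flavin", "lipopigment"),
    exc1_nm = c(340, 360, 450),
    exc1_sd = c(15, 15, 35),
    exc2_nm = c(NA, 450, NA),
    exc2_sd = c(NA, 15, NA),
    em_nm = c(420, 525, 570),
    em_sd = c(20, 35, 60),
    yield = c(1.0, 1.0, 0.8)
  )
}

#' LED illumination specification
#'
#' @param center_nm LED centre wavelength in nm (the instrument carries
#'   355, 395, 435 and 440 nm rings).
#' @param bandwidth_nm Full width at half maximum of the LED line in nm.
#' @param power Relative irradiance (> 0).
#' @return A list of class `miraf_led`.
#' @export
led_spec <- function(center_nm, bandwidth_nm = 12, power = 1) {
  stopifnot(center_nm > 0, bandwidth_nm > 0, power > 0)
  structure(list(center_nm = center_nm, bandwidth_nm = bandwidth_nm,
                 sd_nm = bandwidth_nm / (2 * sqrt(2 * log(2))),
                 power = power),
            class = "miraf_led")
}

#' Band-pass emission filter specification
#'
#' @param center_nm Filter centre in nm (400, 440 or 550 in the default
#'   channel plan).
#' @param fwhm_nm Filter bandwidth (FWHM) in nm (10, 10 or 40).
#' @return A list of class `miraf_filter`.
#' @export
filter_spec <- function(center_nm, fwhm_nm) {
  stopifnot(center_nm > 0, fwhm_nm > 0)
  structure(list(center_nm = center_nm, fwhm_nm = fwhm_nm,
                 sd_nm = fwhm_nm / (2 * sqrt(2 * log(2)))),
            class = "miraf_filter")
}

#' Camera specification
#'
#' Sensor characteristics of the CCD path, expressed at the sample plane:
#' the effective sample-plane pixel pitch (4 um, the fusion grid) absorbs
#' the magnification of the zoom optics.
#'
#' @param pixel_pitch_sample Effective sample-plane pixel pitch, um.
#' @param gain Conversion gain, electrons per ADU.
#' @param read_noise Read noise, electrons rms.
#' @param dark_current Dark current, electrons per second.
#' @param full_well_adu Saturation level in ADU (16-bit).
#' @param psf_fwhm Optical blur of the camera path as a Gaussian PSF FWHM
#'   in um (3 um resolution bound; 0 disables blur).
#' @return A list of class `miraf_camera`.
#' @export
camera_spec <- function(pixel_pitch_sample = 4, gain = 0.6, read_noise = 9,
                        dark_current = 0.25, full_well_adu = 65535,
                        psf_fwhm = 3) {
  stopifnot(pixel_pitch_sample > 0, gain > 0, read_noise > 0,
            dark_current > 0, psf_fwhm >= 0)
  structure(list(pixel_pitch_sample = pixel_pitch_sample, gain = gain,
                 read_noise = read_noise, dark_current = dark_current,
                 full_well_adu = full_well_adu, psf_fwhm = psf_fwhm),
            class = "miraf_camera")
}

#' Spectral coupling of a fluorophore into an LED x filter channel
#'
#' The unitless coupling `k = yield * O_exc * O_em`, where each overlap
#' factor is the normalized overlap integral of two Gaussians (unity at
#' perfect overlap): `O = exp(-(mu1 - mu2)^2 / (2 (s1^2 + s2^2)))`. A
#' dual-peak excitation spectrum contributes the sum of its peak overlaps,
#' capped at 1.
#'
#' @param fluor One row of [fluorophores()].
#' @param led A [led_spec()].
#' @param filt A [filter_spec()].
#' @return Coupling coefficient `k >= 0`.
#' @export
overlap_coefficient <- function(fluor, led, filt) {
  stopifnot(inherits(led, "miraf_led"), inherits(filt, "miraf_filter"))
  ov <- function(mu1, s1, mu2, s2) exp(-(mu1 - mu2)^2 / (2 * (s1^2 + s2^2)))
  o_exc <- ov(fluor$exc1_nm, fluor$exc1_sd, led$center_nm, led$sd_nm)
  if (!is.na(fluor$exc2_nm)) {
    o_exc <- o_exc + ov(fluor$exc2_nm, fluor$exc2_sd, led$center_nm,
                        led$sd_nm)
  }
  o_exc <- min(o_exc, 1)
  o_em <- ov(fluor$em_nm, fluor$em_sd, filt$center_nm, filt$sd_nm)
  fluor$yield * o_exc * o_em
}

#' Default autofluorescence channel plan
#'
#' The three designed biomolecule channels of the instrument, one of them
#' split over two emission filters: collagen/elastin via 355 nm excitation
#' with 400/10 and 440/10 detection, lipopigments via 440 nm excitation
#' with 550/40 detection, and flavins via combined 355 + 440 nm excitation
#' with 550/40 detection. Exposures lie within the instrument's 5-50 s
#' range.
#'
#' @return A tibble with columns `channel`, `leds` (list of [led_spec()]s),
#'   `filter` (list of [filter_spec()]s) and `exposure` (seconds).
#' @export
default_af_plan <- function() {
  tibble::tibble(
    channel = c("collagen_elastin_400", "collagen_elastin_440",
                "lipopigment_550", "flavin_550"),
    leds = list(list(led_spec(355)), list(led_spec(355)),
                list(led_spec(440)), list(led_spec(355), led_spec(440))),
    filter = list(filter_spec(400, 10), filter_spec(440, 10),
                  filter_spec(550, 40), filter_spec(550, 40)),
    exposure = c(30, 30, 10, 10)
  )
}

validate_af_plan <- function(plan) {
  stopifnot(all(c("channel", "leds", "filter", "exposure") %in%
                  names(plan)))
  if (any(plan$exposure < 5 | plan$exposure > 50)) {
    stop("exposures must lie within [5, 50] s", call. = FALSE)
  }
  if (anyDuplicated(plan$channel)) {
    stop("channel names must be unique", call. = FALSE)
  }
  invisible(plan)
}

#' Expected photoelectron rate field of one channel
#'
#' Linear superposition over every fluorophore and every LED of the
#' channel: `rate = brightness * sum_leds sum_f k(f, led, filt) * c_f *
#' power`. Every fluorophore contributes through its spectral overlap, so
#' channel crosstalk is part of the model.
#'
#' @param phantom A phantom (supplies the fluorophore concentration maps).
#' @param channel One row of a channel plan ([default_af_plan()]).
#' @param fluors Fluorophore table; every phantom fluorophore must appear.
#' @param brightness Photoelectron rate per unit concentration at unit
#'   coupling, e-/s (sets the overall signal scale).
#' @return Numeric matrix of expected photoelectron rates (e-/s) at the
#'   phantom pitch.
#' @export
channel_flux <- function(phantom, channel, fluors = fluorophores(),
                         brightness = 400) {
  stopifnot(inherits(phantom, "miraf_phantom"))
  unknown <- setdiff(names(phantom$fluor), fluors$name)
  if (length(unknown)) {
    stop("unknown fluorophore(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  filt <- channel$filter[[1]]
  rate <- 0
  for (led in channel$leds[[1]]) {
    for (i in seq_len(nrow(fluors))) {
      f <- fluors[i, ]
      if (!f$name %in% names(phantom$fluor)) next
      k <- overlap_coefficient(f, led, filt)
      rate <- rate + k * phantom$fluor[[f$name]] * led$power
    }
  }
  brightness * rate
}

#' Camera exposure of a photoelectron rate field
#'
#' Applies the optical blur of the camera path, resamples the rate field to
#' the sample-plane pixel grid, then draws per-pixel counts:
#' `adu = clip(round((Poisson((rate + dark) t) + Normal(0, read_noise)) /
#' gain), 0, full_well)`. With `noise = FALSE` the expected (noise-free)
#' counts are returned instead, still rounded and clipped.
#'
#' @param rate [img2d()] or matrix of expected photoelectron rates (e-/s);
#'   a plain matrix is assumed to already be on the camera grid.
#' @param cam A [camera_spec()].
#' @param exposure Exposure time in seconds (> 0).
#' @param seed Integer seed.
#' @param noise Draw shot/read noise (default TRUE).
#' @return [img2d()] of integer counts at the camera pitch.
#' @export
camera_image <- function(rate, cam = camera_spec(), exposure = 10,
                         seed = 1, noise = TRUE) {
  stopifnot(exposure > 0)
  if (inherits(rate, "miraf_img2d")) {
    v <- rate$values
    if (cam$psf_fwhm > 0) {
      v <- gaussian_blur(v, (cam$psf_fwhm / (2 * sqrt(2 * log(2)))) /
                           rate$pitch)
    }
    if (!isTRUE(all.equal(rate$pitch, cam$pixel_pitch_sample))) {
      step_px <- cam$pixel_pitch_sample / rate$pitch
      ys <- raster_positions(nrow(v), step_px)
      xs <- raster_positions(ncol(v), step_px)
      v <- bilinear_sample(v, ys, xs)
    }
  } else {
    v <- rate
  }
  lambda <- (v + cam$dark_current) * exposure
  if (noise) {
    e <- with_seed(seed, {
      matrix(stats::rpois(length(lambda), lambda) +
               stats::rnorm(length(lambda), sd = cam$read_noise),
             nrow(lambda))
    })
  } else {
    e <- lambda
  }
  adu <- pmin(pmax(round(e / cam$gain), 0), cam$full_well_adu)
  img2d(adu, pitch = cam$pixel_pitch_sample, channel = "")
}

#' Simulate the autofluorescence image set of a phantom
#'
#' One count image per channel of the plan at the camera's sample-plane
#' pitch; per-channel noise seeds are derived from `seed`.
#'
#' @param phantom A phantom.
#' @param plan Channel plan (default [default_af_plan()]).
#' @param cam A [camera_spec()].
#' @param seed Integer seed.
#' @param noise Draw camera noise (default TRUE).
#' @param brightness Signal scale passed to [channel_flux()].
#' @return An object of class `miraf_afset`: named count images plus the
#'   plan and camera metadata.
#' @export
simulate_af <- function(phantom, plan = default_af_plan(),
                        cam = camera_spec(), seed = 1, noise = TRUE,
                        brightness = 400) {
  validate_af_plan(plan)
  images <- list()
  for (i in seq_len(nrow(plan))) {
    ch <- plan[i, ]
    rate <- channel_flux(phantom, ch, brightness = brightness)
    img <- camera_image(img2d(rate, pitch = phantom$pitch,
                              channel = ch$channel),
                        cam = cam, exposure = ch$exposure,
                        seed = seed + 131L * i, noise = noise)
    images[[ch$channel]] <- img$values
  }
  structure(list(images = images, pitch = cam$pixel_pitch_sample,
                 plan = plan, cam = cam, seed = seed, kind = "af"),
            class = "miraf_afset")
}

#' @export
print.miraf_afset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<AF image set: %d channel(s), %dx%d px @ %g um>\n",
              length(x$images), d[1], d[2], x$pitch))
  invisible(x)
}
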