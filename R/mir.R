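# Forward model of the flying-spot MIR scanner and of an FTIR-like
# dense-band reference modality.
#
# Physics: per band, the Beer-Lambert absorbance A = sum_s eps_s c_s l over
# the chemical species, plus a scattering baseline B that varies slowly
# (linearly) in wavenumber. The scanner records I = I_ref 10^-<A_eff> where
# <.> is the Gaussian-weighted spot average, sampled on the raster comb,
# with additive detector noise, clipped to the 16-bit count range.

#' Four-laser MIR band set
#'
#' The scanner's laser lines: two reference lasers bracketing the
#' functional-group region for scattering detection (negligible tissue
#' absorption) and two target lasers on the CH2 lipid and NH protein
#' stretching bands. Molar absorptivities are arbitrary units per
#' concentration unit and micrometre of path; the CH2 band (2928 cm-1) is
#' lipid-dominant, the NH band (3352 cm-1) protein-dominant with a water
#' contribution (NH/OH overlap), following the standard vibrational
#' assignments.
#'
#' @return A tibble with columns `id`, `wavenumber` (cm-1), `role`
#'   (`"target"` or `"reference"`), and `eps_lipid`, `eps_protein`,
#'   `eps_water`.
#' @export
mir_bands <- function() {
  tibble::tibble(
    id = c("L1", "L2", "L3", "L4"),
    wavenumber = c(3704, 3352, 2928, 2792),
    role = c("reference", "target", "target", "reference"),
    eps_lipid   = c(0, 0.006, 0.045, 0),
    eps_protein = c(0, 0.040, 0.008, 0),
    eps_water   = c(0, 0.015, 0.002, 0)
  )
}

#' Ten-band FTIR band set
#'
#' The four scanner bands plus six diagnostically relevant absorption
#' bands (OH, CH, amide I/II/III, C-O) used by the dense-band reference
#' modality.
#'
#' @return A tibble in the same format as [mir_bands()].
#' @export
ftir_bands <- function() {
  dplyr::bind_rows(
    mir_bands(),
    tibble::tibble(
      id = c("B3450", "B2878", "B1655", "B1550", "B1320", "B1159"),
      wavenumber = c(3450, 2878, 1655, 1550, 1320, 1159),
      role = "target",
      eps_lipid   = c(0.000, 0.035, 0.002, 0.002, 0.004, 0.012),
      eps_protein = c(0.010, 0.010, 0.050, 0.038, 0.020, 0.008),
      eps_water   = c(0.050, 0.000, 0.008, 0.002, 0.000, 0.002)
    )
  )
}

validate_bands <- function(bands) {
  need <- c("id", "wavenumber", "role", "eps_lipid", "eps_protein",
            "eps_water")
  stopifnot(all(need %in% names(bands)))
  if (anyDuplicated(bands$wavenumber)) {
    stop("band wavenumbers must be unique", call. = FALSE)
  }
  if (any(bands$wavenumber <= 0)) stop("wavenumbers must be > 0",
                                       call. = FALSE)
  invisible(bands)
}

#' Gaussian spot profile of the scanning beam
#'
#' The spot "size" is interpreted as the 1/e^2 diameter of a Gaussian
#' irradiance profile (beam-profiler convention), so the Gaussian sigma is
#' `diameter_1e2 / 4`.
#'
#' @param diameter_1e2 1/e^2 spot diameter in micrometres (default 22, the
#'   instrument's measured spot).
#' @return A list of class `miraf_spot`.
#' @export
spot_profile <- function(diameter_1e2 = 22) {
  stopifnot(diameter_1e2 > 0)
  structure(list(diameter_1e2 = diameter_1e2, sigma = diameter_1e2 / 4,
                 shape = "gaussian"),
            class = "miraf_spot")
}

#' Raster sampling grid of the flying-spot scan
#'
#' @param step Raster step in micrometres (20 native; 5 for the
#'   super-sampled scan that raises the effective resolution to 10 um).
#' @param origin Scan origin offset in micrometres.
#' @return A list of class `miraf_raster`.
#' @export
raster_grid <- function(step = 20, origin = 0) {
  stopifnot(step > 0, origin >= 0)
  structure(list(step = step, origin = origin), class = "miraf_raster")
}

#' Beer-Lambert absorbance field for one band
#'
#' Additive multi-species Beer-Lambert model:
#' `A(x, y) = sum_s eps_s(nu) c_s(x, y) l`.
#'
#' @param phantom A [generate_brain_phantom()] phantom.
#' @param line One row of a band table ([mir_bands()]).
#' @param l Path length (section thickness) in micrometres; defaults to the
#'   phantom's thickness.
#' @return Numeric matrix of absorbance values (>= 0).
#' @export
absorbance_field <- function(phantom, line, l = phantom$thickness) {
  stopifnot(inherits(phantom, "miraf_phantom"), l > 0)
  A <- 0
  for (s in CHEM_SPECIES) {
    eps <- line[[paste0("eps_", s)]]
    cmap <- phantom$chem[[s]]
    if (any(cmap < 0)) stop("negative concentration input", call. = FALSE)
    A <- A + eps * cmap * l
  }
  A
}

#' Add the scattering baseline to an absorbance field
#'
#' The baseline is `B(x, y, nu) = scatter(x, y) (b0 + b1 nu)`: spatially it
#' follows the phantom's scattering field, spectrally it varies linearly in
#' wavenumber, so the two reference lasers bracket it exactly and the
#' two-point interpolation used downstream removes it without residual in
#' the noiseless limit. Reference lasers (zero tissue absorptivity) carry
#' only B.
#'
#' @param A Absorbance matrix.
#' @param scatter Scattering field matrix (same shape).
#' @param line Band-table row (supplies the wavenumber).
#' @param b0,b1 Baseline coefficients (offset, slope per cm-1).
#' @return Effective attenuation matrix `A + B`.
#' @export
signal_with_scatter <- function(A, scatter, line, b0 = 0.1, b1 = 5e-5) {
  if (!all(dim(A) == dim(scatter))) {
    stop("absorbance and scatter fields must share shape", call. = FALSE)
  }
  A + scatter * (b0 + b1 * line$wavenumber)
}

# Gaussian spot average of a fine-grid field followed by raster sampling.
# Returns the sampled matrix; used both for attenuation fields and for
# reflectance targets.
spot_sample <- function(field, spot, grid) {
  stopifnot(inherits(field, "miraf_img2d"), inherits(spot, "miraf_spot"),
            inherits(grid, "miraf_raster"))
  if (field$pitch > grid$step) {
    stop("field pitch must be <= raster step", call. = FALSE)
  }
  blurred <- gaussian_blur(field$values, spot$sigma / field$pitch)
  step_px <- grid$step / field$pitch
  org_px <- grid$origin / field$pitch
  ys <- raster_positions(nrow(blurred), step_px, org_px)
  xs <- raster_positions(ncol(blurred), step_px, org_px)
  bilinear_sample(blurred, ys, xs)
}

#' Flying-spot scan of an attenuation field
#'
#' Detected counts are
#' `clip(i_ref 10^(-<A_eff>_spot) + eta, 0, 65535)` where `<.>_spot` is the
#' Gaussian-weighted spot average, the result is sampled on the raster
#' comb, and `eta` is additive zero-mean detector noise. Counts are clipped,
#' not wrapped, and kept as floats (quantization is not modelled).
#'
#' @param field [img2d()] effective attenuation field on a fine grid.
#' @param spot A [spot_profile()].
#' @param grid A [raster_grid()]; `field$pitch` must not exceed the step.
#' @param noise_sd Detector noise standard deviation in counts (default 50).
#' @param i_ref Bare gold reference level in counts (> 0).
#' @param seed Integer seed for the noise draw.
#' @return [img2d()] count image at the raster pitch.
#' @export
flying_spot_scan <- function(field, spot = spot_profile(),
                             grid = raster_grid(), noise_sd = 50,
                             i_ref = 50000, seed = 1) {
  if (i_ref <= 0) stop("i_ref must be > 0", call. = FALSE)
  A_spot <- spot_sample(field, spot, grid)
  counts <- i_ref * 10^(-A_spot)
  if (noise_sd > 0) {
    counts <- counts + with_seed(seed, {
      matrix(stats::rnorm(length(counts), sd = noise_sd), nrow(counts))
    })
  }
  img2d(pmin(pmax(counts, 0), 65535), pitch = grid$step,
        channel = field$channel)
}

#' Simulate the four-laser MIR scan of a phantom
#'
#' Composes the Beer-Lambert absorbance, the scattering baseline and the
#' flying-spot scan for every band. Deterministic under `seed` (per-band
#' noise seeds are derived from it).
#'
#' @param phantom A phantom.
#' @param bands Band table (default [mir_bands()]).
#' @param spot,grid Spot and raster configuration.
#' @param noise_sd Detector noise sd in counts.
#' @param i_ref Gold reference counts.
#' @param seed Integer seed.
#' @param b0,b1 Scattering baseline coefficients, see
#'   [signal_with_scatter()].
#' @return An object of class `miraf_scanset`: per-laser count images plus
#'   acquisition metadata.
#' @export
simulate_mir <- function(phantom, bands = mir_bands(),
                         spot = spot_profile(), grid = raster_grid(),
                         noise_sd = 50, i_ref = 50000, seed = 1,
                         b0 = 0.1, b1 = 5e-5) {
  validate_bands(bands)
  images <- list()
  for (i in seq_len(nrow(bands))) {
    line <- bands[i, ]
    A <- absorbance_field(phantom, line)
    A_eff <- signal_with_scatter(A, phantom$scatter, line, b0 = b0, b1 = b1)
    images[[line$id]] <- flying_spot_scan(
      img2d(A_eff, pitch = phantom$pitch, channel = line$id),
      spot = spot, grid = grid, noise_sd = noise_sd, i_ref = i_ref,
      seed = seed + 97L * i
    )$values
  }
  structure(list(images = images, pitch = grid$step, i_ref = i_ref,
                 bands = bands, spot = spot, grid = grid,
                 noise_sd = noise_sd, seed = seed, b0 = b0, b1 = b1,
                 kind = "mir"),
            class = "miraf_scanset")
}

#' Simulate an FTIR-like dense-band acquisition
#'
#' Same absorption physics as the scanner, but with square-pixel box
#' averaging in place of the Gaussian spot and an ideal background
#' subtraction, so the output images are absorbance directly. Noise is
#' additive in absorbance units.
#'
#' @param phantom A phantom.
#' @param bands Band table (default the 10-band [ftir_bands()]).
#' @param pixel_pitch Imaging pixel pitch in micrometres (6.25 or 25).
#' @param noise_sd Absorbance noise sd (default 0.005).
#' @param seed Integer seed.
#' @param b0,b1 Scattering baseline coefficients.
#' @return A `miraf_scanset` whose images are absorbance fields
#'   (`kind = "ftir"`).
#' @export
simulate_ftir <- function(phantom, bands = ftir_bands(),
                          pixel_pitch = 6.25, noise_sd = 0.005, seed = 1,
                          b0 = 0.1, b1 = 5e-5) {
  validate_bands(bands)
  stopifnot(pixel_pitch >= phantom$pitch)
  images <- list()
  for (i in seq_len(nrow(bands))) {
    line <- bands[i, ]
    A <- absorbance_field(phantom, line)
    A_eff <- signal_with_scatter(A, phantom$scatter, line, b0 = b0, b1 = b1)
    Abox <- box_resample(A_eff, phantom$pitch, pixel_pitch)
    if (noise_sd > 0) {
      Abox <- Abox + with_seed(seed + 97L * i, {
        matrix(stats::rnorm(length(Abox), sd = noise_sd), nrow(Abox))
      })
    }
    images[[line$id]] <- Abox
  }
  structure(list(images = images, pitch = pixel_pitch, i_ref = NA_real_,
                 bands = bands, spot = NULL, grid = NULL,
                 noise_sd = noise_sd, seed = seed, b0 = b0, b1 = b1,
                 kind = "ftir"),
            class = "miraf_scanset")
}

#' @export
print.miraf_scanset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<%s scan set: %d band(s), %dx%d px @ %g um>\n",
              toupper(x$kind), length(x$images), d[1], d[2], x$pitch))
  invisible(x)
}
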