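# Raw-data processing chain: count normalization, absorbance conversion
# against the gold reference, dual-reference scattering correction, bicubic
# upscaling to the fusion grid, phase-correlation registration, and
# datacube assembly with per-layer standardization.

#' Normalize raw counts to [0, 1]
#'
#' @param image [img2d()] or matrix of counts in `[0, 65535]`.
#' @return Same type with values divided by 65535.
#' @export
normalize_counts <- function(image) {
  v <- if (inherits(image, "miraf_img2d")) image$values else image
  if (any(v < 0 | v > 65535)) {
    stop("counts out of range [0, 65535]", call. = FALSE)
  }
  out <- v / 65535
  if (inherits(image, "miraf_img2d")) {
    img2d(out, image$pitch, image$channel)
  } else {
    out
  }
}

#' Convert normalized intensity to decadic absorbance
#'
#' `A = -log10(max(value, eps_floor) / i_ref)` against the bare-reference
#' level (the gold-coated slide, the maximum signal). The floor of one
#' count (1/65535) avoids taking the log of zero.
#'
#' @param image [img2d()] or matrix of normalized intensities.
#' @param i_ref Normalized reference level (> 0).
#' @param eps_floor Intensity floor (default one count).
#' @return Same type, in absorbance units.
#' @export
to_absorbance <- function(image, i_ref, eps_floor = 1 / 65535) {
  if (i_ref <= 0) stop("i_ref must be > 0", call. = FALSE)
  v <- if (inherits(image, "miraf_img2d")) image$values else image
  out <- -log10(pmax(v, eps_floor) / i_ref)
  if (inherits(image, "miraf_img2d")) {
    img2d(out, image$pitch, image$channel)
  } else {
    out
  }
}

#' Dual-reference scattering correction
#'
#' For each target laser, the scattering baseline at its wavenumber is
#' estimated per pixel by linear interpolation (in wavenumber) between the
#' two reference-laser absorbance images, and subtracted:
#' `A_corr(t) = A(t) - [A(ref_lo) + (A(ref_hi) - A(ref_lo)) *
#' (nu_t - nu_lo) / (nu_hi - nu_lo)]`.
#' Corrected layers may contain small negatives under noise; they are not
#' clipped (clipping would bias cluster means). Exact (to rounding) when
#' the true baseline is linear in wavenumber and noise-free.
#'
#' @param cube [datacube()] of absorbance layers named by band id.
#' @param bands Band table with `id`, `wavenumber`, `role`; exactly two
#'   `"reference"` rows are required and every band must be a cube layer.
#' @return [datacube()] with one corrected layer per target band.
#' @export
scatter_correct <- function(cube, bands = mir_bands()) {
  stopifnot(inherits(cube, "miraf_cube"))
  validate_bands(bands)
  refs <- bands[bands$role == "reference", ]
  targets <- bands[bands$role == "target", ]
  if (nrow(refs) != 2L) {
    stop("exactly two reference bands are required", call. = FALSE)
  }
  missing_layers <- setdiff(bands$id, names(cube$layers))
  if (length(missing_layers)) {
    stop("missing reference/target layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  refs <- refs[order(refs$wavenumber), ]
  A_lo <- cube$layers[[refs$id[1]]]; nu_lo <- refs$wavenumber[1]
  A_hi <- cube$layers[[refs$id[2]]]; nu_hi <- refs$wavenumber[2]
  out <- list()
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    w <- (t$wavenumber - nu_lo) / (nu_hi - nu_lo)
    out[[t$id]] <- cube$layers[[t$id]] - (A_lo + (A_hi - A_lo) * w)
  }
  datacube(out, pitch = cube$pitch,
           provenance = paste0("mir_corrected:", names(out)))
}

#' Bicubic resampling to a new pixel pitch
#'
#' Separable cubic-convolution (Keys, a = -0.5) interpolation onto a grid
#' of pitch `target_pitch`; output size is rounded toward coverage
#' (`ceiling`). A no-op when pitches already match.
#'
#' @param image [img2d()] input.
#' @param target_pitch Output pixel pitch in micrometres.
#' @return [img2d()] at the target pitch.
#' @export
resize_bicubic <- function(image, target_pitch) {
  stopifnot(inherits(image, "miraf_img2d"), target_pitch > 0)
  if (isTRUE(all.equal(image$pitch, target_pitch))) return(image)
  r <- target_pitch / image$pitch
  n_out_r <- ceiling(nrow(image$values) / r)
  n_out_c <- ceiling(ncol(image$values) / r)
  ys <- (seq_len(n_out_r) - 0.5) * r + 0.5
  xs <- (seq_len(n_out_c) - 0.5) * r + 0.5
  img2d(bicubic_sample(image$values, ys, xs), pitch = target_pitch,
        channel = image$channel)
}

#' Translation registration by phase correlation
#'
#' Estimates the shift of `moving` relative to `fixed` as the peak of the
#' frequency-domain cross-correlation, refined to 0.1 px with a locally
#' upsampled discrete Fourier transform. A circularly shifted copy is
#' recovered exactly at integer shifts.
#'
#' @param moving,fixed [img2d()] images of the same pitch and size.
#' @param upsample Sub-pixel refinement factor (default 10, i.e. 0.1 px).
#' @return A list of class `miraf_shift`: `dy`, `dx` (pixels; the amount by
#'   which `moving` is displaced relative to `fixed`) and `score` (peak
#'   normalized cross-correlation).
#' @export
register_translation <- function(moving, fixed, upsample = 10) {
  mv <- if (inherits(moving, "miraf_img2d")) moving$values else moving
  fx <- if (inherits(fixed, "miraf_img2d")) fixed$values else fixed
  if (!all(dim(mv) == dim(fx))) {
    stop("images must share dimensions for registration", call. = FALSE)
  }
  if (stats::sd(mv) == 0 || stats::sd(fx) == 0) {
    stop("degenerate (constant) image: shift undefined", call. = FALSE)
  }
  mv <- mv - mean(mv); fx <- fx - mean(fx)
  nr <- nrow(fx); nc <- ncol(fx)
  Ff <- stats::fft(fx); Fm <- stats::fft(mv)
  R <- Fm * Conj(Ff)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  peak <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  score <- max(cc) / sqrt(sum(fx^2) * sum(mv^2))
  if (upsample > 1) {
    # matrix-multiply DFT upsampling of the cross-correlation in a
    # 3 x 3 px neighbourhood of the integer peak
    usfac <- upsample
    win <- 1.5
    nshift <- seq(-win, win, by = 1 / usfac)
    ky <- (0:(nr - 1)); ky[ky > nr / 2] <- ky[ky > nr / 2] - nr
    kx <- (0:(nc - 1)); kx[kx > nc / 2] <- kx[kx > nc / 2] - nc
    Ey <- exp(2i * pi * outer(dy + nshift, ky) / nr)
    Ex <- exp(2i * pi * outer(kx, dx + nshift) / nc)
    cc_up <- Re(Ey %*% R %*% Ex) / (nr * nc)
    pk <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    dy <- dy + nshift[pk[1]]
    dx <- dx + nshift[pk[2]]
    score <- max(cc_up) / sqrt(sum(fx^2) * sum(mv^2))
  }
  structure(list(dy = dy, dx = dx, score = score), class = "miraf_shift")
}

#' @export
print.miraf_shift <- function(x, ...) {
  cat(sprintf("<shift dy = %+.2f, dx = %+.2f px (score %.3f)>\n",
              x$dy, x$dx, x$score))
  invisible(x)
}

# forward-difference gradient magnitude; cross-modality registration runs
# on this so that layers with opposite contrast polarity (e.g. a protein
# absorbance map against a lipid-weighted fluorescence channel) still
# align on their shared edges.
gradient_magnitude <- function(m) {
  gy <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE]) - m
  gx <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE]) - m
  sqrt(gy^2 + gx^2)
}

#' Assemble co-registered layers into a clustering-ready data cube
#'
#' Each layer is resampled to the target pitch (bicubic), registered by
#' translation to a reference layer (the first autofluorescence layer if
#' `provenance` marks one, else the first layer), shifted by the rounded
#' estimate, cropped to the common overlap, and finally z-scored per layer
#' (zero mean, unit variance) so that no modality dominates the Euclidean
#' clustering metric. Registration is performed on gradient-magnitude
#' images, making it insensitive to contrast polarity between modalities.
#' Idempotent on an already-assembled cube.
#'
#' @param layers Named list of [img2d()] layers.
#' @param target_pitch Common grid pitch in micrometres (default 4, the
#'   autofluorescence resolution).
#' @param provenance Optional character vector tagging each layer
#'   (e.g. `"af:..."`, `"mir_corrected:..."`).
#' @param scale `"zscore"` (default) or `"none"`.
#' @return [datacube()] with registration shifts in attribute `"shifts"`.
#' @export
assemble_cube <- function(layers, target_pitch = 4, provenance = NULL,
                          scale = c("zscore", "none")) {
  scale <- match.arg(scale)
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)))
  provenance <- provenance %||% names(layers)
  resized <- lapply(layers, resize_bicubic, target_pitch = target_pitch)
  nr <- min(vapply(resized, function(l) nrow(l$values), integer(1)))
  nc <- min(vapply(resized, function(l) ncol(l$values), integer(1)))
  mats <- lapply(resized, function(l) l$values[seq_len(nr), seq_len(nc),
                                               drop = FALSE])
  ref_i <- grep("^af", provenance)[1]
  if (is.na(ref_i)) ref_i <- 1L
  shifts <- data.frame(layer = names(layers), dy = 0, dx = 0)
  if (length(mats) > 1L) {
    rlo <- 1L; rhi <- nr; clo <- 1L; chi <- nc
    for (i in seq_along(mats)) {
      if (i == ref_i) next
      sh <- tryCatch(register_translation(gradient_magnitude(mats[[i]]),
                                          gradient_magnitude(mats[[ref_i]])),
                     error = function(e) list(dy = 0, dx = 0))
      shifts$dy[i] <- sh$dy; shifts$dx[i] <- sh$dx
      ody <- round(sh$dy); odx <- round(sh$dx)
      # layers of one acquisition share a field of view; an implausibly
      # large estimate is a registration failure, not a real offset
      if (abs(ody) > nr / 4 || abs(odx) > nc / 4) { ody <- 0; odx <- 0 }
      if (ody != 0 || odx != 0) {
        mats[[i]] <- shift_matrix(mats[[i]], -ody, -odx)
        # rows/cols of the aligned layer backed by real samples
        rlo <- max(rlo, 1L - ody); rhi <- min(rhi, nr - ody)
        clo <- max(clo, 1L - odx); chi <- min(chi, nc - odx)
      }
    }
    if (rlo > rhi || clo > chi) {
      stop("empty overlap after registration", call. = FALSE)
    }
    mats <- lapply(mats, function(m) m[rlo:rhi, clo:chi, drop = FALSE])
  }
  if (scale == "zscore") {
    mats <- lapply(mats, function(m) {
      s <- stats::sd(m)
      if (s == 0) m - mean(m) else (m - mean(m)) / s
    })
  }
  cube <- datacube(mats, pitch = target_pitch, provenance = provenance)
  attr(cube, "shifts") <- shifts
  cube
}

#' Process a raw MIR scan set into absorbance layers
#'
#' Applies the normalization -> absorbance -> scattering-correction chain
#' of the pipeline to a `miraf_scanset`. FTIR-kind sets are already in
#' absorbance and pass through (optionally corrected).
#'
#' @param scan A `miraf_scanset` from [simulate_mir()] or
#'   [simulate_ftir()].
#' @param correct_scatter Apply the dual-reference correction and keep only
#'   target layers (default TRUE for the MIR scanner, FALSE for FTIR whose
#'   dense bands are clustered directly).
#' @return Named list of [img2d()] absorbance layers.
#' @export
process_scanset <- function(scan,
                            correct_scatter = identical(scan$kind, "mir")) {
  stopifnot(inherits(scan, "miraf_scanset"))
  if (scan$kind == "mir") {
    i_ref_norm <- scan$i_ref / 65535
    abs_layers <- lapply(scan$images, function(m) {
      to_absorbance(normalize_counts(m), i_ref_norm)
    })
  } else {
    abs_layers <- scan$images
  }
  if (correct_scatter) {
    cube <- datacube(abs_layers, pitch = scan$pitch)
    corrected <- scatter_correct(cube, scan$bands)
    abs_layers <- corrected$layers
  }
  lapply(stats::setNames(names(abs_layers), names(abs_layers)),
         function(nm) img2d(abs_layers[[nm]], pitch = scan$pitch,
                            channel = nm))
}
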