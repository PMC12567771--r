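# Internal numerical helpers: seeded RNG scoping, separable convolution,
# grid resampling primitives shared by the forward models and preprocessing.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# 1-D Gaussian kernel truncated at +/- 4 sigma, normalized to unit sum.
gaussian_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# Replicate-padded 1-D convolution along rows then columns (separable).
# `kernel` must have odd length.
convolve_sep <- function(mat, kernel) {
  if (length(kernel) == 1L) return(mat * kernel)
  conv1 <- function(m, k) {
    r <- (length(k) - 1L) %/% 2L
    n <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      out <- out + k[j] * m[idx(seq_len(n) + off), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat, kernel)), kernel))
}

gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  convolve_sep(mat, gaussian_kernel(sigma_px))
}

# Bilinear sampling of `mat` on the tensor grid (ys, xs), positions in
# (fractional) pixel units with (1, 1) the first pixel centre. Positions
# are clamped to the valid range (replicate boundary).
bilinear_sample <- function(mat, ys, xs) {
  nr <- nrow(mat); nc <- ncol(mat)
  ys <- pmin(pmax(ys, 1), nr)
  xs <- pmin(pmax(xs, 1), nc)
  y0 <- pmin(floor(ys), nr - 1L); y0[nr == 1L] <- 1L
  x0 <- pmin(floor(xs), nc - 1L); x0[nc == 1L] <- 1L
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1L, nr); x1 <- pmin(x0 + 1L, nc)
  m00 <- mat[y0, x0, drop = FALSE]; m01 <- mat[y0, x1, drop = FALSE]
  m10 <- mat[y1, x0, drop = FALSE]; m11 <- mat[y1, x1, drop = FALSE]
  wy <- matrix(fy, length(ys), length(xs))
  wx <- matrix(fx, length(ys), length(xs), byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

# Nearest-neighbour sampling on the same grid convention (for label maps).
nearest_sample <- function(mat, ys, xs) {
  nr <- nrow(mat); nc <- ncol(mat)
  yi <- pmin(pmax(round(ys), 1), nr)
  xi <- pmin(pmax(round(xs), 1), nc)
  mat[yi, xi, drop = FALSE]
}

# Exact area-weighted box resampling via an interpolated integral image.
# Each output pixel is the mean of `mat` over an axis-aligned box of
# `pitch_out / pitch_in` input pixels; exact for piecewise-constant input.
box_resample <- function(mat, pitch_in, pitch_out) {
  if (isTRUE(all.equal(pitch_in, pitch_out))) return(mat)
  f <- pitch_out / pitch_in
  nr <- nrow(mat); nc <- ncol(mat)
  n_out_r <- max(1L, floor(nr / f))
  n_out_c <- max(1L, floor(nc / f))
  # integral image with a zero border; S[i+1, j+1] = sum mat[1:i, 1:j]
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(mat, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  S[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  # linear interpolation of S at fractional (continuous) coordinates
  interp_S <- function(ys, xs) bilinear_sample(S, ys + 1, xs + 1)
  r0 <- (seq_len(n_out_r) - 1L) * f; r1 <- seq_len(n_out_r) * f
  c0 <- (seq_len(n_out_c) - 1L) * f; c1 <- seq_len(n_out_c) * f
  area <- f * f
  (interp_S(r1, c1) - interp_S(r1, c0) - interp_S(r0, c1) +
      interp_S(r0, c0)) / area
}

# Keys cubic-convolution kernel (a = -0.5), the classic "bicubic" weight.
keys_weights <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Separable bicubic (Keys) interpolation of `mat` at tensor grid (ys, xs),
# clamped replicate boundaries.
bicubic_sample <- function(mat, ys, xs) {
  interp_axis <- function(m, pos) {
    # interpolate along rows of m at positions `pos` -> length(pos) rows
    n <- nrow(m)
    p <- pmin(pmax(pos, 1), n)
    base <- floor(p)
    frac <- p - base
    out <- matrix(0, length(pos), ncol(m))
    for (j in -1:2) {
      idx <- pmin(pmax(base + j, 1L), n)
      w <- keys_weights(frac - j)
      out <- out + w * m[idx, , drop = FALSE]
    }
    out
  }
  t(interp_axis(t(interp_axis(mat, ys)), xs))
}

# Integer translation of a matrix with NA fill; value(r, c) = mat(r-dy, c-dx).
shift_matrix <- function(mat, dy, dx) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(NA_real_, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- mat[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Raster sample positions in input pixel units for a scan step of
# `step_px` input pixels, origin at the first pixel centre.
raster_positions <- function(n, step_px, origin_px = 0) {
  k <- floor((n - 1 - origin_px) / step_px)
  stopifnot(k >= 0)
  1 + origin_px + step_px * (0:k)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
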