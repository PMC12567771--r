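# Shared fixtures and independent oracles, all built in code at test time.

# small phantom for fast tests
small_phantom <- function(seed = 1, n = 128, cv = 0.1) {
  generate_brain_phantom(phantom_config(width = n, height = n, seed = seed),
                         tissue_classes(cv = cv))
}

# hand-built phantom: uniform gray matter with one vertical stripe of
# white-matter composition, zero texture; used for resolution contrast
# tests where the geometry must be exactly known
stripe_phantom <- function(stripe_um = 5, n = 200, pitch = 2) {
  classes <- tissue_classes(cv = 0)
  h <- n; w <- n
  labels <- matrix(2L, h, w)
  x_um <- (seq_len(w) - 0.5) * pitch
  mid <- w * pitch / 2
  stripe <- abs(x_um - mid) < stripe_um / 2
  labels[, stripe] <- 3L
  lut <- function(col) {
    v <- numeric(5); v[classes$class_id + 1L] <- classes[[col]]
    matrix(v[labels + 1L], h, w)
  }
  chem <- lapply(stats::setNames(paste0("chem_", c("lipid", "protein",
                                                   "water")),
                                 c("lipid", "protein", "water")), lut)
  fluor <- lapply(stats::setNames(
    paste0("fluor_", c("collagen_elastin", "flavin", "lipopigment")),
    c("collagen_elastin", "flavin", "lipopigment")), lut)
  structure(list(labels = labels, chem = chem, fluor = fluor,
                 scatter = matrix(0.3, h, w), pitch = pitch,
                 thickness = 10, classes = classes,
                 config = phantom_config(width = w, height = h,
                                         grid_pitch = pitch, seed = 0)),
            class = "miraf_phantom")
}

# independent ARI oracle: explicit O(n^2) pair counting, no contingency
# table; uses the pair-count identity
# ARI = 2 (n11 n00 - n10 n01) /
#       ((n11 + n10)(n10 + n00) + (n11 + n01)(n01 + n00))
ari_pair_oracle <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# sub-pixel translation via a Fourier phase ramp (exact for band-limited
# periodic fields); independent of the registration implementation
fourier_shift <- function(x, dy, dx) {
  nr <- nrow(x); nc <- ncol(x)
  ky <- 0:(nr - 1); ky[ky > nr / 2] <- ky[ky > nr / 2] - nr
  kx <- 0:(nc - 1); kx[kx > nc / 2] <- kx[kx > nc / 2] - nc
  ph <- exp(-2i * pi * (outer(ky, rep(1, nc)) * dy / nr +
                          outer(rep(1, nr), kx) * dx / nc))
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE)) / (nr * nc)
}

# smooth random test image
smooth_field <- function(n = 96, seed = 1, sigma = 2) {
  set.seed(seed)
  miraf:::gaussian_blur(matrix(rnorm(n * n), n), sigma)
}

af_layer_list <- function(af) {
  lapply(stats::setNames(names(af$images), names(af$images)),
         function(nm) img2d(af$images[[nm]], af$pitch, nm))
}
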