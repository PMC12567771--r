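# Quantitative evaluation: contingency tables, adjusted Rand index,
# Davies-Bouldin index, cross-resolution segmentation comparison, and
# line-grating contrast/resolution analysis.

#' Label-overlap contingency table
#'
#' @param a,b Label vectors, matrices or `miraf_seg` objects of identical
#'   length/shape.
#' @return Integer matrix of co-occurrence counts (rows: labels of `a`,
#'   columns: labels of `b`).
#' @export
contingency_table <- function(a, b) {
  va <- if (inherits(a, "miraf_seg")) as.vector(a$labels) else as.vector(a)
  vb <- if (inherits(b, "miraf_seg")) as.vector(b$labels) else as.vector(b)
  if (length(va) != length(vb)) {
    stop("label fields must share shape", call. = FALSE)
  }
  as.matrix(table(va, vb))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement,
#' `ARI = (sum_ij C(n_ij, 2) - E) / (0.5 [sum_i C(a_i, 2) +
#' sum_j C(b_j, 2)] - E)` with
#' `E = sum_i C(a_i, 2) sum_j C(b_j, 2) / C(n, 2)`. Equals 1 for identical
#' partitions, is ~0 for independent ones, and is invariant to label
#' permutation of either argument.
#'
#' @param a,b Label vectors, matrices or `miraf_seg` objects of identical
#'   shape with at least two elements.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  va <- if (inherits(a, "miraf_seg")) as.vector(a$labels) else as.vector(a)
  vb <- if (inherits(b, "miraf_seg")) as.vector(b$labels) else as.vector(b)
  if (length(va) != length(vb)) {
    stop("label fields must share shape", call. = FALSE)
  }
  n <- length(va)
  if (n < 2) stop("need at least two elements", call. = FALSE)
  tab <- table(va, vb)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  e <- sum_a * sum_b / comb2(n)
  denom <- (sum_a + sum_b) / 2 - e
  if (abs(denom) < .Machine$double.eps) {
    # both partitions trivial (all-one-cluster or all-singletons):
    # identical by construction
    return(1)
  }
  (sum_ij - e) / denom
}

#' Davies-Bouldin index of a clustering
#'
#' `DBI = (1/k) sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the
#' mean Euclidean distance of cluster i's points to their centroid and
#' `M_ij` the centroid distance. Lower is better; scale-invariant.
#'
#' @param points Numeric matrix (n x d) of feature vectors.
#' @param labels Cluster label per row; at least two non-empty clusters.
#' @return DBI value (>= 0).
#' @export
davies_bouldin <- function(points, labels) {
  X <- as.matrix(points)
  labels <- as.vector(labels)
  stopifnot(nrow(X) == length(labels))
  lv <- sort(unique(labels))
  k <- length(lv)
  if (k < 2) stop("need at least two clusters", call. = FALSE)
  C <- matrix(unlist(lapply(lv, function(l) {
    colMeans(X[labels == l, , drop = FALSE])
  })), nrow = k, ncol = ncol(X), byrow = TRUE)
  S <- vapply(seq_len(k), function(i) {
    Xi <- X[labels == lv[i], , drop = FALSE]
    mean(sqrt(rowSums((Xi - matrix(C[i, ], nrow(Xi), ncol(X),
                                   byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(C))
  if (any(M[upper.tri(M)] == 0)) {
    stop("coincident centroids: Davies-Bouldin undefined", call. = FALSE)
  }
  R <- outer(S, S, `+`) / M
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Compare two segmentations across resolutions
#'
#' Mirrors the cross-modality comparison protocol: the coarser label map is
#' resampled to the finer pitch by nearest neighbour (labels are never
#' interpolated), the maps are registered by translation, cropped to the
#' common field of view, and scored with the adjusted Rand index.
#'
#' @param seg_a,seg_b `miraf_seg` objects (pitches may differ).
#' @return A one-row tibble: `pitch_a`, `pitch_b`, `shift_dy`, `shift_dx`,
#'   `rows`, `cols`, `ari`.
#' @export
compare_segmentations <- function(seg_a, seg_b) {
  stopifnot(inherits(seg_a, "miraf_seg"), inherits(seg_b, "miraf_seg"))
  fine_pitch <- min(seg_a$pitch, seg_b$pitch)
  upsample_nn <- function(seg) {
    if (isTRUE(all.equal(seg$pitch, fine_pitch))) return(seg$labels)
    r <- fine_pitch / seg$pitch
    n_out_r <- floor(nrow(seg$labels) / r)
    n_out_c <- floor(ncol(seg$labels) / r)
    ys <- (seq_len(n_out_r) - 0.5) * r + 0.5
    xs <- (seq_len(n_out_c) - 0.5) * r + 0.5
    nearest_sample(seg$labels, ys, xs)
  }
  la <- upsample_nn(seg_a)
  lb <- upsample_nn(seg_b)
  nr <- min(nrow(la), nrow(lb)); nc <- min(ncol(la), ncol(lb))
  if (nr < 2 || nc < 2) stop("empty intersection", call. = FALSE)
  la <- la[seq_len(nr), seq_len(nc), drop = FALSE]
  lb <- lb[seq_len(nr), seq_len(nc), drop = FALSE]
  # register on label-boundary maps so the estimate does not depend on the
  # (arbitrary) numeric label values
  sh <- tryCatch(register_translation(gradient_magnitude(lb + 0) > 0,
                                      gradient_magnitude(la + 0) > 0),
                 error = function(e) list(dy = 0, dx = 0))
  ody <- round(sh$dy); odx <- round(sh$dx)
  # reject implausible estimates (the maps share a field of view, so any
  # true offset is small compared to the extent)
  if (abs(ody) > nr / 4 || abs(odx) > nc / 4) { ody <- 0; odx <- 0 }
  if (ody != 0 || odx != 0) {
    lbs <- shift_matrix(lb + 0, -ody, -odx)
    keep_r <- max(1L, 1L - ody):min(nr, nr - ody)
    keep_c <- max(1L, 1L - odx):min(nc, nc - odx)
    if (length(keep_r) < 2L || length(keep_c) < 2L) {
      stop("empty intersection", call. = FALSE)
    }
    la <- la[keep_r, keep_c, drop = FALSE]
    lb <- lbs[keep_r, keep_c, drop = FALSE]
  }
  tibble::tibble(pitch_a = seg_a$pitch, pitch_b = seg_b$pitch,
                 shift_dy = ody, shift_dx = odx,
                 rows = nrow(la), cols = ncol(la),
                 ari = adjusted_rand_index(la, lb))
}

#' Default grating frequency ladder
#'
#' Eighteen spatial frequencies from 1.25 to 250 line pairs per mm, the
#' span of the physical resolution target.
#'
#' @return Numeric vector of frequencies (lp/mm), strictly increasing.
#' @export
default_ladder <- function() {
  c(1.25, 2.5, 5, 10, 12.5, 16, 20, 25, 31.5, 40, 50, 63, 80, 100, 125,
    160, 200, 250)
}

#' Contrast transfer curve of the simulated scanner
#'
#' For each ladder frequency a binary 50%-duty grating is rendered on a
#' fine grid, scanned noiselessly through the Gaussian spot and raster
#' comb, and the modulation is estimated phase-insensitively as twice the
#' magnitude of the Fourier coefficient at the grating frequency divided by
#' the profile mean, normalized so an unblurred square wave scores 1
#' (i.e. divided by its fundamental 4/pi). Frequencies above the raster's
#' Nyquist limit are recorded as contrast 0 with an aliasing flag.
#'
#' @param spot A [spot_profile()].
#' @param grid A [raster_grid()].
#' @param ladder Frequencies in lp/mm, in (0, 250] (default
#'   [default_ladder()]).
#' @param pitch Fine rendering pitch in micrometres (default 1).
#' @param n_periods Grating periods per measurement (default 32).
#' @return A tibble of class `miraf_contrast`: `frequency`, `contrast`,
#'   `aliased`.
#' @export
contrast_curve <- function(spot = spot_profile(), grid = raster_grid(5),
                           ladder = default_ladder(), pitch = 1,
                           n_periods = 32) {
  stopifnot(all(ladder > 0), all(ladder <= 250),
            !is.unsorted(ladder, strictly = TRUE))
  nyquist <- 500 / grid$step              # lp/mm at the raster step
  rows <- lapply(ladder, function(f) {
    if (f > nyquist) {
      return(tibble::tibble(frequency = f, contrast = 0, aliased = TRUE))
    }
    period <- 1000 / f
    # span an (approximately) integer number of periods in raster steps
    m_steps <- max(8L, round(n_periods * period / grid$step))
    margin <- 4 * spot$sigma
    extent_x <- m_steps * grid$step + 2 * margin + grid$step
    g <- generate_grating_field(
      grating_spec(f, duty = 0.5, extent = c(extent_x, pitch)),
      pitch = pitch
    )
    profile <- spot_sample(g, spot, grid)[1, ]
    xs_um <- (seq_along(profile) - 1) * grid$step
    # drop the blur margins, keep m_steps samples
    i0 <- ceiling(margin / grid$step) + 1L
    idx <- i0:min(i0 + m_steps - 1L, length(profile))
    s <- profile[idx]; xs <- xs_um[idx]
    f_um <- f / 1000
    coef <- sum((s - mean(s)) * exp(-2i * pi * f_um * xs)) / length(s)
    modulation <- 2 * Mod(coef) / mean(s)
    tibble::tibble(frequency = f, contrast = modulation / (4 / pi),
                   aliased = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("miraf_contrast", class(out))
  out
}

#' Resolution limit from a contrast curve
#'
#' The highest ladder frequency whose modulation contrast reaches the
#' resolvability threshold (default 0.2); 0 if none does.
#'
#' @param curve A [contrast_curve()] result.
#' @param threshold Modulation threshold in `[0, 1]`.
#' @return Frequency in lp/mm.
#' @export
resolution_limit <- function(curve, threshold = 0.2) {
  stopifnot(nrow(curve) > 0)
  ok <- curve$frequency[curve$contrast >= threshold]
  if (!length(ok)) 0 else max(ok)
}
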