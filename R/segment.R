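# K-means segmentation of data cubes: k-means++ initialization,
# multi-restart Lloyd iterations, Davies-Bouldin guided choice of k, and
# label harmonization between segmentations.

# k-means++ seeding: first centre uniform, then each next centre drawn
# with probability proportional to the squared distance to the nearest
# chosen centre. Expects the caller to have fixed the RNG state.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i1 <- sample.int(n, 1L)
  centers[1L, ] <- X[i1, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      # all remaining points coincide with a centre; fall back to uniform
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Fit a K-means model to a data cube
#'
#' Lloyd iterations from k-means++ starts; the best (lowest inertia) of
#' `n_init` independent restarts is kept. `init_method = "candidates"`
#' implements the alternative reading of "10 iterations of the enhanced
#' center initialization": a single Lloyd run started from the best of
#' `n_init` k-means++ candidate draws. Deterministic under `seed`.
#'
#' @param cube A [datacube()] or a pixels-by-layers numeric matrix.
#' @param k Number of clusters (default 5: background, ventricle, gray
#'   matter, white matter and a fine-structure/outlier class).
#' @param n_init Number of restarts (or candidate draws), default 10.
#' @param seed Integer seed.
#' @param tol Convergence tolerance on relative inertia change (Lloyd runs
#'   are iterated to full assignment stability, which is at least as
#'   strict; recorded in the model).
#' @param max_iter Iteration cap per restart.
#' @param init_method `"restarts"` (default) or `"candidates"`.
#' @return An object of class `miraf_kmeans` with elements `k`,
#'   `centroids` (k x layers), `inertia`, `n_init`, `seed`, `iter`,
#'   `sizes`, `layers`, `restart_inertias`.
#' @export
fit_kmeans <- function(cube, k = 5, n_init = 10, seed = 1, tol = 1e-4,
                       max_iter = 300, init_method = c("restarts",
                                                       "candidates")) {
  init_method <- match.arg(init_method)
  X <- if (inherits(cube, "miraf_cube")) cube_matrix(cube) else as.matrix(cube)
  stopifnot(k >= 1, n_init >= 1)
  if (nrow(unique(X)) < k) {
    stop("fewer distinct pixel vectors than clusters", call. = FALSE)
  }
  run_lloyd <- function(centers) {
    suppressWarnings(stats::kmeans(X, centers = centers,
                                   iter.max = max_iter,
                                   algorithm = "Lloyd"))
  }
  fits <- list()
  with_seed(seed, {
    if (init_method == "restarts") {
      for (r in seq_len(n_init)) {
        fits[[r]] <- tryCatch(run_lloyd(kmeanspp_centers(X, k)),
                              error = function(e) NULL)
      }
    } else {
      cands <- lapply(seq_len(n_init), function(r) kmeanspp_centers(X, k))
      init_inertia <- vapply(cands, function(C) {
        D <- pairwise_sqdist(X, C)
        sum(apply(D, 1L, min))
      }, numeric(1))
      fits[[1L]] <- run_lloyd(cands[[which.min(init_inertia)]])
    }
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all K-means restarts failed", call. = FALSE)
  inertias <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  best <- fits[[which.min(inertias)]]
  centroids <- unname(best$centers)
  colnames(centroids) <- colnames(X)
  structure(list(k = as.integer(k), centroids = centroids,
                 inertia = best$tot.withinss, n_init = n_init,
                 seed = seed, tol = tol, max_iter = max_iter,
                 iter = best$iter, sizes = best$size,
                 layers = colnames(X), init_method = init_method,
                 restart_inertias = inertias),
            class = "miraf_kmeans")
}

#' @export
print.miraf_kmeans <- function(x, ...) {
  cat(sprintf("<K-means model: k = %d, inertia = %.4g, best of %d %s>\n",
              x$k, x$inertia, x$n_init,
              if (x$init_method == "restarts") "restarts"
              else "k-means++ candidates"))
  invisible(x)
}

# squared Euclidean distances between rows of X (n x d) and C (k x d)
pairwise_sqdist <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, `+`) - 2 * X %*% t(C)
}

#' Segment a data cube with a fitted model
#'
#' Each pixel is assigned to the nearest centroid in Euclidean distance;
#' exact ties go to the lowest centroid index (documented for
#' reproducibility). Labels are 0-based, in `[0, k)`.
#'
#' @param cube A [datacube()].
#' @param model A `miraf_kmeans` model whose layer dimension matches.
#' @return An object of class `miraf_seg`: integer `labels` matrix,
#'   `pitch`, and the `model`.
#' @export
segment_cube <- function(cube, model) {
  stopifnot(inherits(cube, "miraf_cube"), inherits(model, "miraf_kmeans"))
  X <- cube_matrix(cube)
  if (ncol(X) != ncol(model$centroids)) {
    stop("cube layer dimension does not match the model", call. = FALSE)
  }
  D <- pairwise_sqdist(X, model$centroids)
  lab <- max.col(-D, ties.method = "first") - 1L
  d <- dim(cube$layers[[1]])
  structure(list(labels = matrix(as.integer(lab), d[1], d[2]),
                 pitch = cube$pitch, model = model),
            class = "miraf_seg")
}

#' @export
print.miraf_seg <- function(x, ...) {
  cat(sprintf("<segmentation %dx%d px @ %g um, k = %d>\n",
              nrow(x$labels), ncol(x$labels), x$pitch,
              max(x$labels) + 1L))
  invisible(x)
}

#' Construct a segmentation map from a label matrix
#'
#' Wraps an externally supplied label image (e.g. phantom ground truth)
#' in the segmentation container so it can enter comparisons.
#'
#' @param labels Integer matrix of labels.
#' @param pitch Pixel pitch in micrometres.
#' @return A `miraf_seg`.
#' @export
as_segmentation <- function(labels, pitch) {
  stopifnot(is.matrix(labels))
  structure(list(labels = matrix(as.integer(labels), nrow(labels),
                                 ncol(labels)),
                 pitch = pitch, model = NULL),
            class = "miraf_seg")
}

#' Sweep the cluster count and score with the Davies-Bouldin index
#'
#' Fits one model per candidate k and scores each segmentation with the
#' Davies-Bouldin index; the best k is the argmin (most compact,
#' best-separated clustering). With the sweep disabled the pipeline uses
#' k = 5.
#'
#' @param cube A [datacube()].
#' @param k_range Candidate cluster counts (default 2:8).
#' @param seed Integer seed.
#' @param ... Passed to [fit_kmeans()].
#' @return A list with `best_k` and `scores`, a tibble of `k`,
#'   `davies_bouldin` and `inertia`.
#' @export
sweep_k <- function(cube, k_range = 2:8, seed = 1, ...) {
  stopifnot(all(k_range >= 2))
  X <- cube_matrix(cube)
  rows <- lapply(k_range, function(k) {
    fit <- fit_kmeans(cube, k = k, seed = seed, ...)
    seg <- segment_cube(cube, fit)
    tibble::tibble(k = k,
                   davies_bouldin = davies_bouldin(X, as.vector(seg$labels)),
                   inertia = fit$inertia)
  })
  scores <- dplyr::bind_rows(rows)
  list(best_k = scores$k[which.min(scores$davies_bouldin)],
       scores = scores)
}

# all permutations of seq_len(n) as a list (n <= 8 in practice)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (i in seq_len(n)) {
    for (s in sub) {
      v <- integer(n)
      v[1L] <- i
      v[-1L] <- setdiff(seq_len(n), i)[s]
      out[[idx]] <- v
      idx <- idx + 1L
    }
  }
  out
}

#' Harmonize the labels of one segmentation onto another
#'
#' Permutes the labels of `seg_b` by the maximum-weight one-to-one
#' assignment on the label-overlap contingency table against `seg_a`
#' (exact search over permutations for up to 8 labels, greedy beyond), so
#' that matching structures receive matching ids. Labels of `seg_b` without
#' a partner keep fresh ids. The adjusted Rand index is invariant under
#' this relabeling.
#'
#' @param seg_a,seg_b `miraf_seg` objects of identical shape.
#' @return `seg_b` with permuted labels.
#' @export
harmonize_labels <- function(seg_a, seg_b) {
  stopifnot(inherits(seg_a, "miraf_seg"), inherits(seg_b, "miraf_seg"))
  if (!all(dim(seg_a$labels) == dim(seg_b$labels))) {
    stop("segmentations must share shape", call. = FALSE)
  }
  la <- sort(unique(as.vector(seg_a$labels)))
  lb <- sort(unique(as.vector(seg_b$labels)))
  tab <- table(factor(seg_a$labels, levels = la),
               factor(seg_b$labels, levels = lb))
  m <- max(length(la), length(lb))
  W <- matrix(0, m, m)  # rows: a labels (padded), cols: b labels (padded)
  W[seq_along(la), seq_along(lb)] <- as.matrix(tab)
  if (m <= 8L) {
    best <- NULL; best_w <- -Inf
    for (p in all_perms(m)) {
      w <- sum(W[cbind(p, seq_len(m))])
      if (w > best_w) { best_w <- w; best <- p }
    }
    assign_a_of_b <- best      # column j (b label) -> row (a label)
  } else {
    assign_a_of_b <- rep(NA_integer_, m)
    Wg <- W
    for (step in seq_len(m)) {
      ij <- which(Wg == max(Wg), arr.ind = TRUE)[1, ]
      assign_a_of_b[ij[2]] <- ij[1]
      Wg[ij[1], ] <- -Inf; Wg[, ij[2]] <- -Inf
    }
  }
  # build the replacement map for b's actual labels
  fresh <- if (length(la)) max(la) + 1L else 0L
  new_of_b <- integer(length(lb))
  for (j in seq_along(lb)) {
    i <- assign_a_of_b[j]
    if (!is.na(i) && i <= length(la)) {
      new_of_b[j] <- la[i]
    } else {
      new_of_b[j] <- fresh
      fresh <- fresh + 1L
    }
  }
  relabeled <- matrix(new_of_b[match(as.vector(seg_b$labels), lb)],
                      nrow(seg_b$labels), ncol(seg_b$labels))
  out <- seg_b
  out$labels <- relabeled
  out
}
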