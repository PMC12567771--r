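# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted K-means model
#'
#' One row per cluster and layer: the centroid coordinate in z-scored
#' layer units, plus the cluster size.
#'
#' @param x A `miraf_kmeans` model.
#' @param ... Unused.
#' @return A tibble with columns `cluster`, `layer`, `center`, `size`.
#' @export
tidy.miraf_kmeans <- function(x, ...) {
  k <- x$k
  layers <- x$layers %||% paste0("layer", seq_len(ncol(x$centroids)))
  tibble::tibble(
    cluster = rep(seq_len(k) - 1L, each = length(layers)),
    layer = rep(layers, times = k),
    center = as.vector(t(x$centroids)),
    size = rep(x$sizes, each = length(layers))
  )
}

#' Glance at a fitted K-means model
#'
#' @param x A `miraf_kmeans` model.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `inertia`, `n_init`, `iter`,
#'   `best_restart_gap` (relative inertia gap between the best and worst
#'   restart).
#' @export
glance.miraf_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, inertia = x$inertia, n_init = x$n_init, iter = x$iter,
    best_restart_gap = (max(x$restart_inertias) -
                          min(x$restart_inertias)) /
      max(min(x$restart_inertias), .Machine$double.eps)
  )
}

#' Tidy an experiment report
#'
#' @param x A `miraf_report`.
#' @param ... Unused.
#' @return The per-modality summary tibble (modality, pitch, k,
#'   Davies-Bouldin index, ARI against ground truth).
#' @export
tidy.miraf_report <- function(x, ...) x$summary

#' Glance at an experiment report
#'
#' @param x A `miraf_report`.
#' @param ... Unused.
#' @return One-row tibble: number of modalities, seed, k, best modality by
#'   ARI against truth.
#' @export
glance.miraf_report <- function(x, ...) {
  tibble::tibble(
    n_modalities = nrow(x$summary),
    seed = x$config$seed,
    k = x$config$k,
    best_modality = x$summary$modality[which.max(x$summary$ari_truth)],
    best_ari_truth = max(x$summary$ari_truth)
  )
}
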