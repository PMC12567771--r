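#' Single-channel image with physical pixel pitch
#'
#' Light-weight container for a 2-D image field: a numeric matrix plus the
#' physical pixel pitch in micrometres and an optional channel name. All
#' simulated and processed images in the package are carried in this form.
#'
#' @param values Numeric matrix of pixel values (finite).
#' @param pitch Pixel pitch in micrometres (> 0).
#' @param channel Channel name, e.g. a laser id or an autofluorescence
#'   channel label.
#' @return An object of class `miraf_img2d`: a list with elements `values`,
#'   `pitch` and `channel`.
#' @export
img2d <- function(values, pitch, channel = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("image values must be finite", call. = FALSE)
  }
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0) {
    stop("`pitch` must be a single positive number (um)", call. = FALSE)
  }
  structure(list(values = values, pitch = pitch,
                 channel = as.character(channel)),
            class = "miraf_img2d")
}

#' @export
print.miraf_img2d <- function(x, ...) {
  cat(sprintf("<image %dx%d px @ %g um> channel '%s', range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pitch, x$channel,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.miraf_img2d <- function(x) dim(x$values)

as_img2d <- function(x, pitch = NULL, channel = "") {
  if (inherits(x, "miraf_img2d")) return(x)
  img2d(x, pitch = pitch, channel = channel)
}

#' Co-registered multi-channel data cube
#'
#' A stack of images on one common pixel grid: the input to K-means
#' segmentation. Layers are named matrices of identical dimensions sharing
#' one pixel pitch; `provenance` records where each layer came from (a MIR
#' laser, an autofluorescence channel, or an FTIR band).
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param pitch Common pixel pitch in micrometres.
#' @param provenance Character vector, one entry per layer (defaults to the
#'   layer names).
#' @return An object of class `miraf_cube`.
#' @export
datacube <- function(layers, pitch, provenance = NULL) {
  if (!is.list(layers) || length(layers) == 0L) {
    stop("`layers` must be a non-empty list of matrices", call. = FALSE)
  }
  if (is.null(names(layers)) || anyDuplicated(names(layers)) ||
      any(names(layers) == "")) {
    stop("layers must have unique, non-empty names", call. = FALSE)
  }
  dims <- vapply(layers, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1])) {
    stop("all layers must share the same dimensions", call. = FALSE)
  }
  provenance <- provenance %||% names(layers)
  stopifnot(length(provenance) == length(layers))
  structure(list(layers = layers, pitch = pitch,
                 provenance = as.character(provenance)),
            class = "miraf_cube")
}

#' @export
print.miraf_cube <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<datacube %dx%d px @ %g um, %d layer(s)>\n",
              d[1], d[2], x$pitch, length(x$layers)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.miraf_cube <- function(x) c(dim(x$layers[[1]]), length(x$layers))

#' Flatten a data cube into a pixels-by-layers matrix
#'
#' @param cube A [datacube()].
#' @return A numeric matrix with one row per pixel (column-major order) and
#'   one column per layer.
#' @export
cube_matrix <- function(cube) {
  stopifnot(inherits(cube, "miraf_cube"))
  X <- matrix(unlist(lapply(cube$layers, as.numeric), use.names = FALSE),
              ncol = length(cube$layers))
  colnames(X) <- names(cube$layers)
  X
}
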