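# Persistence: images as TIFF (16-bit counts / 32-bit float fields, 8-bit
# labels) with JSON sidecars carrying the acquisition metadata.

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# TIFF pages hold values in [0, 1]; float fields are stored min/max
# rescaled at 32-bit depth with the ranges kept in the JSON sidecar.
write_float_tiff <- function(mats, path) {
  ranges <- lapply(mats, function(m) {
    lo <- min(m); hi <- max(m)
    if (hi == lo) hi <- lo + 1
    c(lo, hi)
  })
  scaled <- Map(function(m, r) (m - r[1]) / (r[2] - r[1]), mats, ranges)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  ranges
}

read_float_tiff <- function(path, ranges) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.matrix(ranges)) ranges <- asplit(ranges, 1L)  # from JSON
  Map(function(m, r) m * (r[2] - r[1]) + r[1], pages,
      lapply(ranges, as.numeric))
}

#' Write / read a phantom
#'
#' The concentration fields and the scattering baseline go to one
#' multi-page 32-bit float TIFF, the label map to a 16-bit TIFF, and the
#' class table, pitch, thickness and seed to a JSON sidecar.
#'
#' @param phantom A `miraf_phantom`.
#' @param dir Output directory (created if needed).
#' @return `write_phantom` returns `dir` invisibly; `read_phantom` returns
#'   the reconstructed `miraf_phantom`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "miraf_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields <- c(phantom$chem, phantom$fluor, list(scatter = phantom$scatter))
  ranges <- write_float_tiff(fields, file.path(dir, "fields.tiff"))
  tiff::writeTIFF(phantom$labels / 65535, file.path(dir, "labels.tiff"),
                  bits.per.sample = 16)
  meta <- list(field_names = names(fields), field_ranges = ranges,
               pitch = phantom$pitch,
               thickness = phantom$thickness,
               seed = phantom$config$seed,
               config = unclass(phantom$config),
               classes = phantom$classes)
  write_json_sidecar(meta, file.path(dir, "phantom.json"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  fields <- read_float_tiff(file.path(dir, "fields.tiff"),
                            meta$field_ranges)
  names(fields) <- meta$field_names
  labels <- round(tiff::readTIFF(file.path(dir, "labels.tiff")) * 65535)
  chem <- fields[intersect(names(fields), CHEM_SPECIES)]
  fluor <- fields[intersect(names(fields), FLUOR_SPECIES)]
  classes <- tibble::as_tibble(meta$classes)
  config <- do.call(phantom_config, meta$config)
  structure(list(labels = matrix(as.integer(labels), nrow(labels),
                                 ncol(labels)),
                 chem = chem, fluor = fluor, scatter = fields$scatter,
                 pitch = meta$pitch, thickness = meta$thickness,
                 classes = classes, config = config),
            class = "miraf_phantom")
}

#' Write / read a scan set
#'
#' MIR count images are written as one 16-bit grayscale TIFF per laser;
#' FTIR absorbance images as a multi-page 32-bit float TIFF. Wavenumbers,
#' pitch, reference level and seed go to a JSON sidecar.
#'
#' @param scan A `miraf_scanset`.
#' @param dir Output directory.
#' @return `write_scanset` returns `dir` invisibly; `read_scanset` the
#'   reconstructed set (metadata objects such as the spot profile are
#'   restored from the sidecar).
#' @export
write_scanset <- function(scan, dir) {
  stopifnot(inherits(scan, "miraf_scanset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (scan$kind == "mir") {
    for (nm in names(scan$images)) {
      tiff::writeTIFF(round(scan$images[[nm]]) / 65535,
                      file.path(dir, paste0(nm, ".tiff")),
                      bits.per.sample = 16)
    }
    ranges <- NULL
  } else {
    ranges <- write_float_tiff(scan$images,
                               file.path(dir, "absorbance.tiff"))
  }
  meta <- list(kind = scan$kind, band_ids = names(scan$images),
               band_ranges = ranges,
               bands = scan$bands, pitch = scan$pitch, i_ref = scan$i_ref,
               noise_sd = scan$noise_sd, seed = scan$seed,
               b0 = scan$b0, b1 = scan$b1,
               spot_diameter_1e2 = scan$spot$diameter_1e2,
               raster_step = scan$grid$step)
  write_json_sidecar(meta, file.path(dir, "scanset.json"))
  invisible(dir)
}

#' @rdname write_scanset
#' @export
read_scanset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scanset.json"),
                              simplifyVector = TRUE)
  if (meta$kind == "mir") {
    images <- lapply(meta$band_ids, function(nm) {
      round(tiff::readTIFF(file.path(dir, paste0(nm, ".tiff"))) * 65535)
    })
  } else {
    images <- read_float_tiff(file.path(dir, "absorbance.tiff"),
                              meta$band_ranges)
  }
  names(images) <- meta$band_ids
  structure(list(images = images, pitch = meta$pitch, i_ref = meta$i_ref,
                 bands = tibble::as_tibble(meta$bands),
                 spot = if (length(meta$spot_diameter_1e2) == 1L &&
                            !is.na(meta$spot_diameter_1e2))
                   spot_profile(meta$spot_diameter_1e2),
                 grid = if (length(meta$raster_step) == 1L &&
                            !is.na(meta$raster_step))
                   raster_grid(meta$raster_step),
                 noise_sd = meta$noise_sd, seed = meta$seed,
                 b0 = meta$b0, b1 = meta$b1, kind = meta$kind),
            class = "miraf_scanset")
}

#' Write / read a data cube
#'
#' Multi-page 32-bit float TIFF plus a JSON sidecar with layer names,
#' pitch and provenance.
#'
#' @param cube A [datacube()].
#' @param dir Output directory.
#' @return `write_cube` returns `dir` invisibly; `read_cube` the cube.
#' @export
write_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "miraf_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ranges <- write_float_tiff(cube$layers, file.path(dir, "cube.tiff"))
  shifts <- attr(cube, "shifts")
  meta <- list(layer_names = names(cube$layers), layer_ranges = ranges,
               pitch = cube$pitch,
               provenance = cube$provenance, shifts = shifts)
  write_json_sidecar(meta, file.path(dir, "cube.json"))
  invisible(dir)
}

#' @rdname write_cube
#' @export
read_cube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cube.json"),
                              simplifyVector = TRUE)
  layers <- read_float_tiff(file.path(dir, "cube.tiff"),
                            meta$layer_ranges)
  names(layers) <- meta$layer_names
  cube <- datacube(layers, pitch = meta$pitch,
                   provenance = meta$provenance)
  if (!is.null(meta$shifts)) attr(cube, "shifts") <- meta$shifts
  cube
}

#' Write / read a segmentation map
#'
#' Labels as an 8-bit indexed TIFF plus a JSON sidecar with pitch and, when
#' available, the fitted centroids, inertia and seed.
#'
#' @param seg A `miraf_seg`.
#' @param dir Output directory.
#' @return `write_segmentation` returns `dir` invisibly;
#'   `read_segmentation` the map (without the fitted model object).
#' @export
write_segmentation <- function(seg, dir) {
  stopifnot(inherits(seg, "miraf_seg"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (max(seg$labels) > 255) stop("more than 256 labels", call. = FALSE)
  tiff::writeTIFF(seg$labels / 255, file.path(dir, "labels.tiff"),
                  bits.per.sample = 8)
  meta <- list(pitch = seg$pitch,
               k = if (!is.null(seg$model)) seg$model$k
                   else max(seg$labels) + 1L,
               centroids = if (!is.null(seg$model)) seg$model$centroids,
               inertia = if (!is.null(seg$model)) seg$model$inertia,
               seed = if (!is.null(seg$model)) seg$model$seed)
  write_json_sidecar(meta, file.path(dir, "segmentation.json"))
  invisible(dir)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "segmentation.json"),
                              simplifyVector = TRUE)
  labels <- round(tiff::readTIFF(file.path(dir, "labels.tiff")) * 255)
  as_segmentation(matrix(as.integer(labels), nrow(labels), ncol(labels)),
                  pitch = meta$pitch)
}

#' Write an experiment report to disk
#'
#' Writes the summary and pairwise ARI tables as CSV, the full report as
#' JSON, each segmentation as TIFF+JSON, and a copy of the run
#' configuration.
#'
#' @param report A `miraf_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "miraf_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$pairwise),
                   file.path(dir, "pairwise_ari.csv"))
  write_json_sidecar(list(summary = report$summary,
                          pairwise = report$pairwise,
                          timestamp = attr(report, "timestamp")),
                     file.path(dir, "report.json"))
  for (nm in names(report$segmentations)) {
    write_segmentation(report$segmentations[[nm]],
                       file.path(dir, paste0("seg_", nm)))
  }
  write_run_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
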