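# Synthetic tissue phantoms with known ground truth.
#
# The phantom emulates a thin coronal brain section mounted on a reflective
# slide: a gray-matter bulk carrying curved lipid-rich white-matter bands,
# a ventricle, a reticular web of protein-rich fine structures, and a bare
# background margin. Each class carries mean concentrations of three
# chemical species (lipid, protein, water) and three endogenous fluorophores
# (collagen/elastin, flavin, lipopigment) plus a scattering baseline level.

CHEM_SPECIES <- c("lipid", "protein", "water")
FLUOR_SPECIES <- c("collagen_elastin", "flavin", "lipopigment")

#' Default tissue class table
#'
#' Compositional priors for the five phantom classes. The contrasts follow
#' the standard neurochemical picture: white matter is lipid-rich (compact
#' myelin) and shows stronger flavin (FAD) and collagen/elastin
#' autofluorescence, while gray matter is protein-rich and carries stronger
#' lipopigment (lipofuscin-like) autofluorescence; the fine-structure class
#' models protein-rich reticular elements (fiber bundles) inside gray
#' matter. Absolute values are arbitrary units chosen once for clear class
#' separability; the background (bare slide) is chemically empty.
#'
#' @param cv Within-class coefficient of variation applied to every chemical
#'   and fluorophore field (default 0.1; 0 gives piecewise-constant
#'   phantoms).
#' @return A tibble with one row per class: `class_id` (0-based, matching
#'   segmentation labels), `name`, `chem_*` and `fluor_*` mean
#'   concentrations, `cv` and `scatter_mean`.
#' @export
tissue_classes <- function(cv = 0.1) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0, cv <= 1)
  tibble::tibble(
    class_id = 0:4,
    name = c("background", "ventricle", "gray_matter", "white_matter",
             "fine_structure"),
    chem_lipid   = c(0, 0.05, 0.30, 1.10, 0.45),
    chem_protein = c(0, 0.10, 0.90, 0.40, 1.60),
    chem_water   = c(0, 0.40, 0.10, 0.10, 0.10),
    fluor_collagen_elastin = c(0, 0.05, 0.25, 0.75, 0.35),
    fluor_flavin           = c(0, 0.05, 0.35, 0.90, 0.50),
    fluor_lipopigment      = c(0, 0.05, 0.85, 0.25, 1.15),
    cv = cv,
    scatter_mean = c(0.02, 0.15, 0.30, 0.40, 0.30)
  )
}

validate_classes <- function(classes) {
  need <- c("class_id", "name", paste0("chem_", CHEM_SPECIES),
            paste0("fluor_", FLUOR_SPECIES), "cv", "scatter_mean")
  miss <- setdiff(need, names(classes))
  if (length(miss)) {
    stop("class table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(classes$class_id)) {
    stop("class ids must be unique", call. = FALSE)
  }
  conc <- as.matrix(classes[, c(paste0("chem_", CHEM_SPECIES),
                                paste0("fluor_", FLUOR_SPECIES))])
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(classes$cv < 0 | classes$cv > 1)) {
    stop("cv must lie in [0, 1]", call. = FALSE)
  }
  invisible(classes)
}

#' Phantom generation configuration
#'
#' @param width,height Ground-truth grid size in pixels.
#' @param grid_pitch Ground-truth pixel pitch in micrometres (default 2,
#'   fine enough that the 4 um camera grid and the 5 um raster comb sample
#'   the truth without aliasing).
#' @param seed Integer seed; fully determines the phantom.
#' @param min_structure_width,max_structure_width Width range of the curved
#'   white-matter bands, micrometres.
#' @param section_thickness Tissue section thickness l in micrometres
#'   (path length of the Beer-Lambert model; default 10).
#' @return A list of class `miraf_phantom_config`.
#' @export
phantom_config <- function(width = 512, height = 512, grid_pitch = 2,
                           seed = 1, min_structure_width = 5,
                           max_structure_width = 100,
                           section_thickness = 10) {
  if (grid_pitch > min_structure_width / 2) {
    stop("grid too coarse: grid_pitch must be <= min_structure_width / 2",
         call. = FALSE)
  }
  stopifnot(width >= 32, height >= 32, section_thickness > 0,
            max_structure_width >= min_structure_width)
  structure(list(width = as.integer(width), height = as.integer(height),
                 grid_pitch = grid_pitch, seed = as.integer(seed),
                 min_structure_width = min_structure_width,
                 max_structure_width = max_structure_width,
                 section_thickness = section_thickness),
            class = "miraf_phantom_config")
}

#' Generate a synthetic brain-section phantom
#'
#' Builds the ground-truth label map and per-species concentration fields.
#' The geometry is seeded and fully deterministic: an elliptical tissue
#' boundary with a background margin, a central ventricle, two to three
#' curved white-matter bands whose widths span the configured structure
#' range, and a reticular fine-structure web (5-20 um elements) inside gray
#' matter obtained by thresholding band-pass filtered noise. Concentration
#' fields are class means modulated by log-normal within-class texture; the
#' scattering baseline is a smooth, strictly positive seeded field
#' (correlation length >= 50 um) scaled by the class scatter level.
#'
#' @param config A [phantom_config()].
#' @param classes A class table as from [tissue_classes()].
#' @return An object of class `miraf_phantom`: list with `labels` (integer
#'   matrix of class ids), `chem` and `fluor` (named lists of concentration
#'   matrices), `scatter`, `pitch`, `thickness`, `classes`, `config`.
#' @export
generate_brain_phantom <- function(config = phantom_config(),
                                   classes = tissue_classes()) {
  stopifnot(inherits(config, "miraf_phantom_config"))
  validate_classes(classes)
  h <- config$height; w <- config$width; p <- config$grid_pitch
  with_seed(config$seed, {
    # physical coordinates of pixel centres (um)
    xs <- (seq_len(w) - 0.5) * p
    ys <- (seq_len(h) - 0.5) * p
    X <- matrix(xs, h, w, byrow = TRUE)
    Y <- matrix(ys, h, w)
    cx <- w * p / 2 + stats::runif(1, -0.02, 0.02) * w * p
    cy <- h * p / 2 + stats::runif(1, -0.02, 0.02) * h * p
    a <- 0.42 * w * p
    b <- 0.42 * h * p
    th <- stats::runif(1, -0.2, 0.2)
    Xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    Yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    tissue <- (Xr / a)^2 + (Yr / b)^2 <= 1

    labels <- matrix(0L, h, w)                    # background
    labels[tissue] <- 2L                          # gray matter bulk

    # curved white-matter bands in polar coordinates: wavy annuli whose
    # widths sweep the configured structure range
    r <- sqrt(Xr^2 + (Yr * a / b)^2)
    theta <- atan2(Yr * a / b, Xr)
    wmin <- config$min_structure_width
    wmax <- config$max_structure_width
    band_r0 <- c(0.56, 0.76, 0.32) * a
    band_wlo <- c(0.35 * wmax, wmin + 0.1 * (wmax - wmin), wmin)
    band_whi <- c(wmax, 0.45 * wmax, min(4 * wmin, wmax))
    for (i in seq_along(band_r0)) {
      ph1 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      m <- sample(2:4, 1)
      r0 <- band_r0[i] * (1 + 0.08 * sin(m * theta + ph1))
      wb <- band_wlo[i] + (band_whi[i] - band_wlo[i]) *
        (0.5 + 0.5 * sin(2 * theta + ph2))
      band <- tissue & abs(r - r0) < wb / 2
      labels[band] <- 3L
    }

    # ventricle: elongated rotated ellipse near the centre
    va <- 0.22 * a; vb <- 0.09 * b
    vth <- stats::runif(1, 0, pi)
    Xv <- Xr * cos(vth) + Yr * sin(vth)
    Yv <- -Xr * sin(vth) + Yr * cos(vth)
    vent <- (Xv / va)^2 + (Yv / vb)^2 <= 1
    labels[vent & tissue] <- 1L

    # reticular fine structure inside gray matter: band-pass noise web
    noise <- matrix(stats::rnorm(h * w), h, w)
    bp <- gaussian_blur(noise, 3 / p) - gaussian_blur(noise, 9 / p)
    thr <- stats::quantile(bp[labels == 2L], 0.90)
    labels[labels == 2L & bp > thr] <- 4L

    # per-class lookup of field means
    lut <- function(col) {
      v <- numeric(max(classes$class_id) + 1L)
      v[classes$class_id + 1L] <- classes[[col]]
      matrix(v[labels + 1L], h, w)
    }
    cvmap <- lut("cv")
    s2map <- log(1 + cvmap^2)
    texture_field <- function(mean_map) {
      # log-normal texture with unit mean and per-pixel cv from the class
      # map, clipped to 1 +/- 5 cv; cv = 0 classes keep exactly their mean
      z <- matrix(stats::rnorm(h * w), h, w)
      tex <- exp(z * sqrt(s2map) - s2map / 2)
      tex <- pmin(pmax(tex, pmax(0, 1 - 5 * cvmap)), 1 + 5 * cvmap)
      mean_map * tex
    }
    chem <- lapply(stats::setNames(paste0("chem_", CHEM_SPECIES),
                                   CHEM_SPECIES), function(col) {
      texture_field(lut(col))
    })
    fluor <- lapply(stats::setNames(paste0("fluor_", FLUOR_SPECIES),
                                    FLUOR_SPECIES), function(col) {
      texture_field(lut(col))
    })

    # smooth strictly positive scattering baseline, correlation length
    # >= 50 um, modulated by the class scatter level
    sm <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), 35 / p)
    sm <- 1 + 0.25 * sm / stats::sd(sm)
    sm <- pmax(sm, 0.05)
    scatter <- pmax(lut("scatter_mean") * sm, 1e-6)

    structure(list(labels = labels, chem = chem, fluor = fluor,
                   scatter = scatter, pitch = p,
                   thickness = config$section_thickness,
                   classes = classes, config = config),
              class = "miraf_phantom")
  })
}

#' @export
print.miraf_phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d px @ %g um, thickness %g um>\n",
              nrow(x$labels), ncol(x$labels), x$pitch, x$thickness))
  tab <- table(factor(x$labels, levels = x$classes$class_id,
                      labels = x$classes$name))
  print(round(tab / length(x$labels), 3))
  invisible(x)
}

#' Line-grating target specification
#'
#' A binary bar pattern used to probe the resolving power of the simulated
#' flying-spot scanner, mirroring a chrome-on-glass resolution target.
#'
#' @param frequency Spatial frequency in line pairs per mm (> 0).
#' @param duty Bar duty cycle (fraction of the period that is bright).
#' @param extent Physical size `c(width, height)` in micrometres; must hold
#'   at least 8 full periods along the modulation axis.
#' @param orientation Bar orientation in degrees (0 = vertical bars,
#'   modulation along x).
#' @return A list of class `miraf_grating_spec`.
#' @export
grating_spec <- function(frequency, duty = 0.5,
                         extent = c(16e3 / frequency, 100),
                         orientation = 0) {
  stopifnot(frequency > 0, duty >= 0, duty <= 1)
  period <- 1000 / frequency
  extent <- rep(extent, length.out = 2L)
  if (extent[1] < 8 * period) {
    stop("extent must hold at least 8 full periods", call. = FALSE)
  }
  structure(list(frequency = frequency, duty = duty, extent = extent,
                 orientation = orientation, period = period),
            class = "miraf_grating_spec")
}

#' Render a line-grating reflectance field
#'
#' @param spec A [grating_spec()].
#' @param pitch Rendering pixel pitch in micrometres; must satisfy
#'   `pitch <= period / 4` (otherwise the bars are undersampled).
#' @return A [img2d()] reflectance field with values in \{0, 1\}.
#' @export
generate_grating_field <- function(spec, pitch = 1) {
  stopifnot(inherits(spec, "miraf_grating_spec"))
  if (pitch > spec$period / 4) {
    stop("undersampled period: pitch must be <= period / 4", call. = FALSE)
  }
  nc <- max(4L, round(spec$extent[1] / pitch))
  nr <- max(1L, round(spec$extent[2] / pitch))
  th <- spec$orientation * pi / 180
  xs <- (seq_len(nc) - 0.5) * pitch
  ys <- (seq_len(nr) - 0.5) * pitch
  U <- matrix(xs, nr, nc, byrow = TRUE) * cos(th) +
    matrix(ys, nr, nc) * sin(th)
  # area sampling: each pixel carries the exact fraction of its footprint
  # covered by a bar, so the field mean equals the duty cycle at every
  # frequency (interior pixels stay binary)
  T <- spec$period; d <- spec$duty
  Fbar <- function(x) floor(x / T) * d * T + pmin(x %% T, d * T)
  cov <- (Fbar(U + pitch / 2) - Fbar(U - pitch / 2)) / pitch
  img2d(matrix(pmin(pmax(cov, 0), 1), nr, nc), pitch = pitch,
        channel = sprintf("grating_%g_lpmm", spec$frequency))
}
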