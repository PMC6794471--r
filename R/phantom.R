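# Synthetic multi-contrast phantom: shared anatomy with per-structure,
# per-contrast intensities, a smooth polynomial global phase producing
# wraps, thin bright tubes emulating vessels, and complex Gaussian noise
# (hence Rician magnitudes).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default phantom structures
#'
#' A central parenchyma box, two spherical nuclei with distinct intensity
#' profiles, and a radius-1.5-voxel tube crossing the box (a vessel:
#' brighter in the later contrasts). Intensities decay across contrasts
#' for tissue (echo-train-like), so contrasts share anatomy but differ in
#' level.
#'
#' @param n_contrasts number of contrasts M_c.
#' @return list of structure descriptions for [phantom_spec()].
#' @export
default_phantom_structures <- function(n_contrasts = 5L) {
  cidx <- seq_len(n_contrasts) - 1L
  list(
    list(name = "tissue", type = "box",
         center = c(0.5, 0.5, 0.5), half_width = c(0.4, 0.4, 0.4),
         intensities = 100 * exp(-0.15 * cidx)),
    list(name = "nucleus_bright", type = "sphere",
         center = c(0.35, 0.4, 0.45), radius = 0.13,
         intensities = 150 * exp(-0.25 * cidx)),
    list(name = "nucleus_dark", type = "sphere",
         center = c(0.68, 0.62, 0.55), radius = 0.1,
         intensities = 55 * exp(-0.05 * cidx)),
    list(name = "vessel", type = "tube",
         p0 = c(0.15, 0.32, 0.62), p1 = c(0.85, 0.45, 0.55),
         radius_voxels = 1.5,
         intensities = 140 + 12 * cidx)
  )
}

default_phase_coefficients <- function(n_contrasts = 5L) {
  lapply(seq_len(n_contrasts), function(c) {
    c(const = 0.3 * c, x = 3 + 0.5 * c, y = 2 - 0.3 * c,
      z = 1.5 + 0.2 * c, xx = 1.0, yy = -0.8, zz = 0.4, xy = 0.5)
  })
}

#' Specification of a synthetic multi-contrast phantom
#'
#' @param shape 3 ints, grid size in voxels.
#' @param n_contrasts number of contrasts M_c.
#' @param structures list of structure descriptions (see
#'   [default_phantom_structures()]); geometric coordinates are fractions
#'   of the grid except `radius_voxels` for tubes.
#' @param noise_sigma Gaussian noise std per real/imaginary channel
#'   (signal units). The default 10, against a tissue intensity of 100,
#'   gives tissue SNR 10.
#' @param phase_coefficients list (one per contrast) of named low-order
#'   polynomial coefficients (radians) over coordinates normalised to
#'   `[-1, 1]`: names among const, x, y, z, xx, yy, zz, xy, xz, yz. The
#'   defaults span several 2*pi wraps across the volume.
#' @param seed integer RNG seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), n_contrasts = 5L,
                         structures = default_phantom_structures(n_contrasts),
                         noise_sigma = 10,
                         phase_coefficients =
                           default_phase_coefficients(n_contrasts),
                         seed = 20260101L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), n_contrasts >= 1L,
            noise_sigma >= 0)
  for (s in structures) {
    if (length(s$intensities) != n_contrasts) {
      stop("each structure needs one intensity per contrast", call. = FALSE)
    }
    if (any(s$intensities < 0)) stop("intensities must be >= 0",
                                     call. = FALSE)
    if (identical(s$type, "tube") && s$radius_voxels < 1) {
      stop("tube radius must be >= 1 voxel", call. = FALSE)
    }
  }
  structure(list(shape = shape, n_contrasts = as.integer(n_contrasts),
                 structures = structures, noise_sigma = noise_sigma,
                 phase_coefficients = phase_coefficients,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

eval_phase_poly <- function(coeffs, shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  u <- function(n) if (n > 1) seq(-1, 1, length.out = n) else 0
  x <- array(u(nx), shape)
  y <- aperm(array(u(ny), c(ny, nx, nz)), c(2, 1, 3))
  z <- aperm(array(u(nz), c(nz, nx, ny)), c(2, 3, 1))
  g <- function(nm) if (!is.null(coeffs[nm]) && !is.na(coeffs[nm]))
    unname(coeffs[nm]) else 0
  out <- array(g("const"), shape)
  out + g("x") * x + g("y") * y + g("z") * z +
    g("xx") * x^2 + g("yy") * y^2 + g("zz") * z^2 +
    g("xy") * x * y + g("xz") * x * z + g("yz") * y * z
}

structure_mask <- function(s, shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xf <- array(seq_len(nx) / nx, shape)
  yf <- aperm(array(seq_len(ny) / ny, c(ny, nx, nz)), c(2, 1, 3))
  zf <- aperm(array(seq_len(nz) / nz, c(nz, nx, ny)), c(2, 3, 1))
  if (s$type == "box") {
    abs(xf - s$center[1]) <= s$half_width[1] &
      abs(yf - s$center[2]) <= s$half_width[2] &
      abs(zf - s$center[3]) <= s$half_width[3]
  } else if (s$type == "sphere") {
    (xf - s$center[1])^2 + (yf - s$center[2])^2 +
      (zf - s$center[3])^2 <= s$radius^2
  } else if (s$type == "tube") {
    # distance from the segment p0-p1, in voxel units
    p0 <- s$p0 * shape; p1 <- s$p1 * shape
    v <- p1 - p0
    vv <- sum(v^2)
    px <- xf * nx - p0[1]; py <- yf * ny - p0[2]; pz <- zf * nz - p0[3]
    t <- pmin(1, pmax(0, (px * v[1] + py * v[2] + pz * v[3]) / vv))
    d2 <- (px - t * v[1])^2 + (py - t * v[2])^2 + (pz - t * v[3])^2
    d2 <= s$radius_voxels^2
  } else {
    stop("unknown structure type: ", s$type, call. = FALSE)
  }
}

#' Generate a synthetic multi-contrast phantom with known truth
#'
#' Builds piecewise-constant truth magnitudes (per-structure, per-contrast
#' intensities over a zero background), a smooth polynomial global phase
#' per contrast (wrapped), and a noisy copy obtained by adding independent
#' Gaussian noise of std `noise_sigma` to the real and imaginary parts of
#' the complex signal — so noisy magnitudes are Rician (Rayleigh over the
#' empty background). Overlapping structures resolve last-wins.
#'
#' @param spec a [phantom_spec()].
#' @return list with `truth` and `noisy` (both [complex_image_set()]),
#'   `structure_masks` (3D integer label volume, 0 = background, i = i-th
#'   structure), `structure_names`, and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  mc <- spec$n_contrasts
  labels <- array(0L, shape)
  for (i in seq_along(spec$structures)) {
    m <- structure_mask(spec$structures[[i]], shape)
    if (any(labels[m] != 0L)) {
      message(sprintf("structure %d overlaps earlier structures; last wins",
                      i))
    }
    labels[m] <- i
  }
  truth_mag <- vector("list", mc)
  truth_phs <- vector("list", mc)
  for (c in seq_len(mc)) {
    intens <- c(0, vapply(spec$structures,
                          function(s) s$intensities[c], numeric(1)))
    truth_mag[[c]] <- array(intens[labels + 1L], shape)
    truth_phs[[c]] <- rewrap(eval_phase_poly(spec$phase_coefficients[[c]],
                                             shape))
  }
  hdr <- volume_header(shape)
  truth <- complex_image_set(truth_mag, truth_phs, hdr)
  noisy_mag <- vector("list", mc)
  noisy_phs <- vector("list", mc)
  if (spec$noise_sigma == 0) {
    noisy_mag <- truth_mag
    noisy_phs <- truth_phs
  } else {
    with_seed(spec$seed, {
      for (c in seq_len(mc)) {
        re <- truth_mag[[c]] * cos(truth_phs[[c]]) +
          spec$noise_sigma * array(stats::rnorm(prod(shape)), shape)
        im <- truth_mag[[c]] * sin(truth_phs[[c]]) +
          spec$noise_sigma * array(stats::rnorm(prod(shape)), shape)
        noisy_mag[[c]] <- sqrt(re^2 + im^2)
        noisy_phs[[c]] <- rewrap(atan2(im, re))
      }
    })
  }
  noisy <- complex_image_set(noisy_mag, noisy_phs, hdr)
  list(truth = truth, noisy = noisy, structure_masks = labels,
       structure_names = vapply(spec$structures,
                                function(s) s$name %||% s$type,
                                character(1)),
       spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom to disk
#'
#' NIfTI pairs for the noisy and truth sets, a label volume, and a JSON
#' manifest describing the generating specification.
#'
#' @param phantom result of [generate_phantom()].
#' @param output_dir directory (created if absent).
#' @return character vector of files written.
#' @export
write_phantom <- function(phantom, output_dir) {
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  hdr <- phantom$truth$header
  paths <- character(0)
  for (role in c("truth", "noisy")) {
    set <- phantom[[role]]
    for (c in seq_len(set$n_contrasts)) {
      pm <- file.path(output_dir, sprintf("%s_mag%d.nii.gz", role, c))
      pp <- file.path(output_dir, sprintf("%s_phs%d.nii.gz", role, c))
      write_volume(set$magnitudes[[c]], hdr, pm)
      write_volume(set$phases[[c]], hdr, pp)
      paths <- c(paths, pm, pp)
    }
  }
  pl <- file.path(output_dir, "labels.nii.gz")
  write_volume(phantom$structure_masks, hdr, pl)
  manifest <- file.path(output_dir, "phantom.json")
  spec <- phantom$spec
  jsonlite::write_json(
    list(shape = spec$shape, n_contrasts = spec$n_contrasts,
         noise_sigma = spec$noise_sigma, seed = spec$seed,
         structure_names = phantom$structure_names,
         structures = spec$structures,
         phase_coefficients = spec$phase_coefficients),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(paths, pl, manifest)
}
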