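#' Volume geometry header
#'
#' Minimal geometric description of a 3D volume: grid shape in voxels,
#' voxel size in mm, and the 4x4 voxel-to-world affine transform. All
#' volumes in a [complex_image_set()] share one header.
#'
#' @param shape integer vector of length 3, grid dimensions (voxels).
#' @param voxel_size numeric vector of length 3, voxel edge lengths (mm).
#' @param affine 4x4 numeric voxel-to-world transform; last row must be
#'   `(0, 0, 0, 1)`. Defaults to a scaling by `voxel_size`.
#' @return An object of class `volume_header`.
#' @export
volume_header <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive reals (mm)", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (max(abs(affine[4L, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("affine last row must be (0, 0, 0, 1)", call. = FALSE)
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_header")
}

#' @export
print.volume_header <- function(x, ...) {
  cat(sprintf("<volume_header> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

header_from_nifti <- function(img) {
  dm <- dim(img)
  if (length(dm) != 3L) {
    stop("expected a 3D volume, got ", length(dm), " dimensions", call. = FALSE)
  }
  pix <- RNifti::pixdim(img)[seq_len(3L)]
  affine <- tryCatch(unclass(RNifti::xform(img)),
                     error = function(e) diag(c(pix, 1)))
  volume_header(dm, pix, affine)
}

headers_equal <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

#' Multi-contrast complex image set
#'
#' Container for M_c co-registered MR contrasts given as paired magnitude
#' and phase 3D volumes on one grid, e.g. the five images of a
#' multi-echo MP2RAGE acquisition (first inversion plus four second-inversion
#' echoes). Magnitudes are non-negative in arbitrary signal units; phases
#' are radians wrapped to `[-pi, pi)`.
#'
#' @param magnitudes list of 3D arrays, all the same shape, values >= 0.
#' @param phases list of 3D arrays (radians in `[-pi, pi)`), same shapes.
#' @param header a [volume_header()]; defaults to unit voxels.
#' @return An object of class `complex_image_set` with elements
#'   `magnitudes`, `phases`, `header` and `n_contrasts`.
#' @export
complex_image_set <- function(magnitudes, phases, header = NULL) {
  if (!is.list(magnitudes)) magnitudes <- list(magnitudes)
  if (!is.list(phases)) phases <- list(phases)
  m <- length(magnitudes)
  if (m < 1L || length(phases) != m) {
    stop("need equal numbers (>= 1) of magnitude and phase volumes",
         call. = FALSE)
  }
  shp <- dim(magnitudes[[1]])
  if (length(shp) != 3L) stop("volumes must be 3D arrays", call. = FALSE)
  for (i in seq_len(m)) {
    if (!identical(dim(magnitudes[[i]]), shp) ||
        !identical(dim(phases[[i]]), shp)) {
      stop(sprintf("grid mismatch: contrast %d does not match contrast 1", i),
           call. = FALSE)
    }
    if (any(magnitudes[[i]] < 0)) {
      stop(sprintf("magnitude volume %d has negative values", i),
           call. = FALSE)
    }
    rng <- range(phases[[i]])
    if (rng[1] < -pi - 1e-6 || rng[2] >= pi + 1e-6) {
      stop(sprintf("phase volume %d outside [-pi, pi): range [%.4g, %.4g]",
                   i, rng[1], rng[2]), call. = FALSE)
    }
  }
  if (is.null(header)) header <- volume_header(shp)
  if (!identical(header$shape, as.integer(shp))) {
    stop("header shape does not match volume shape", call. = FALSE)
  }
  magnitudes <- lapply(magnitudes, function(v) array(as.numeric(v), shp))
  phases <- lapply(phases, function(v) array(as.numeric(v), shp))
  structure(list(magnitudes = magnitudes, phases = phases,
                 header = header, n_contrasts = m),
            class = "complex_image_set")
}

#' @export
print.complex_image_set <- function(x, ...) {
  cat(sprintf("<complex_image_set> %d contrast(s), grid %d x %d x %d\n",
              x$n_contrasts, x$header$shape[1], x$header$shape[2],
              x$header$shape[3]))
  invisible(x)
}

#' Wrap phase values into [-pi, pi)
#'
#' @param phi numeric array or vector of phase values (radians).
#' @return `phi` reduced modulo 2*pi into `[-pi, pi)`.
#' @export
rewrap <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # %% can return 2*pi for inputs just below a wrap boundary (float round-off)
  out[out >= pi] <- -pi
  out
}
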