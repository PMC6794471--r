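#' Unwrap a 3D phase volume
#'
#' Quality-guided region-growing unwrapping: voxels are visited in
#' decreasing order of the quality map (typically the magnitude image) and
#' each is unwrapped against the already-unwrapped neighbour that reached
#' it, adding the multiple of 2*pi that minimises the step. The result is
#' deterministic, differs from the input by integer multiples of 2*pi
#' voxelwise, and is anchored so the median added multiple is zero.
#'
#' @param phase 3D array, wrapped phase in `[-pi, pi)`.
#' @param quality optional 3D non-negative array on the same grid guiding
#'   the growth order (higher first). `NULL` or an all-zero map gives
#'   unweighted (uniform-quality) unwrapping.
#' @return 3D array of unwrapped phase; `rewrap(out)` equals `phase`.
#' @export
unwrap_phase <- function(phase, quality = NULL) {
  d <- dim(phase)
  if (length(d) != 3L) stop("`phase` must be a 3D array", call. = FALSE)
  rng <- range(phase)
  if (rng[1] < -pi - 1e-6 || rng[2] >= pi + 1e-6) {
    stop("`phase` must be wrapped to [-pi, pi)", call. = FALSE)
  }
  if (is.null(quality)) {
    quality <- array(1, d)
  } else {
    if (!identical(dim(quality), d)) {
      stop("`quality` grid does not match `phase`", call. = FALSE)
    }
    if (any(quality < 0)) stop("`quality` must be non-negative",
                               call. = FALSE)
    if (all(quality == 0)) {
      warning("all-zero quality map; unwrapping unweighted")
      quality <- array(1, d)
    }
  }
  out <- unwrap_phase_cpp(as.numeric(phase), as.numeric(quality),
                          as.integer(d))
  out <- array(out, d)
  k <- round((out - phase) / (2 * pi))
  out - 2 * pi * round(stats::median(k))
}

#' Total-variation (ROF) smoothing of a 3D volume
#'
#' Minimises `0.5 * ||u - f||^2 + weight * TV(u)` by Chambolle's dual
#' projection iteration with step 1/12 (safe for the 3D discrete
#' divergence-gradient operator). Forward differences with Neumann boundary
#' conditions.
#'
#' @param f 3D array, finite.
#' @param weight positive regularisation weight (radians x voxels here).
#' @param max_iter iteration cap.
#' @param tol stop when the max change in `u`, relative to the dynamic
#'   range of `f`, falls below this.
#' @return smoothed 3D array `u`.
#' @export
tv_smooth <- function(f, weight, max_iter = 500L, tol = 1e-5) {
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    stop("`weight` must be a positive real", call. = FALSE)
  }
  if (any(!is.finite(f))) stop("`f` must be finite", call. = FALSE)
  d <- dim(f)
  if (length(d) != 3L) stop("`f` must be a 3D array", call. = FALSE)
  u <- chambolle_tv_cpp(as.numeric(f), weight, as.integer(max_iter),
                        tol, as.integer(d))
  array(u, d)
}

#' Split unwrapped phase into global and residual components
#'
#' The global phase (slowly varying field from air cavities, B0
#' inhomogeneity, coil combination) is estimated as the total-variation
#' smoothing of the unwrapped phase; the residual local phase is the
#' remainder and carries anatomy and noise. The decomposition is exactly
#' additive: `unwrapped == global_phase + residual_phase`.
#'
#' @param unwrapped 3D array of unwrapped phase (radians), finite.
#' @param tv_weight positive TV regularisation weight. The default keeps
#'   phase structure at wavelengths of ~20 voxels and above in the global
#'   component while features of ~4 voxels and below pass to the residual.
#' @param max_iter,tol passed to [tv_smooth()].
#' @param mask optional logical/0-1 array: voxels with undefined phase
#'   (zero magnitude). There the residual is forced to 0 and the global
#'   phase absorbs the full unwrapped value.
#' @return object of class `phase_decomposition`: list with `unwrapped`,
#'   `global_phase`, `residual_phase`.
#' @export
split_global_phase <- function(unwrapped, tv_weight = 0.5, max_iter = 500L,
                               tol = 1e-5, mask = NULL) {
  if (!is.numeric(tv_weight) || length(tv_weight) != 1L || tv_weight <= 0) {
    stop("`tv_weight` must be a positive real", call. = FALSE)
  }
  if (any(!is.finite(unwrapped))) {
    stop("`unwrapped` must be finite", call. = FALSE)
  }
  global <- tv_smooth(unwrapped, tv_weight, max_iter = max_iter, tol = tol)
  residual <- unwrapped - global
  if (!is.null(mask)) {
    undef <- as.logical(mask)
    residual[undef] <- 0
    global[undef] <- unwrapped[undef]
  }
  structure(list(unwrapped = unwrapped, global_phase = global,
                 residual_phase = residual),
            class = "phase_decomposition")
}

#' Multi-channel contrast stack
#'
#' 4D real array (X x Y x Z x M) feeding the patch PCA, with one channel
#' label per slice of the fourth dimension.
#'
#' @param data 4D numeric array, finite.
#' @param channel_labels character vector of length M.
#' @param header a [volume_header()] for the spatial grid.
#' @return object of class `contrast_stack`.
#' @export
contrast_stack <- function(data, channel_labels = NULL, header = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("`data` must be a 4D array", call. = FALSE)
  if (any(!is.finite(data))) stop("`data` must be finite", call. = FALSE)
  m <- d[4]
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%d", seq_len(m))
  if (length(channel_labels) != m) {
    stop("need one channel label per channel", call. = FALSE)
  }
  if (is.null(header)) header <- volume_header(d[1:3])
  structure(list(data = data, channel_labels = as.character(channel_labels),
                 header = header),
            class = "contrast_stack")
}

#' @export
print.contrast_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<contrast_stack> %d x %d x %d voxels, %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Build the real/imaginary channel stack from magnitudes and residual phase
#'
#' For each contrast c, `real_c = magnitude_c * cos(residual_c)` and
#' `imag_c = magnitude_c * sin(residual_c)`; channels are ordered
#' `[real_1, imag_1, ..., real_Mc, imag_Mc]`, so M = 2 * M_c. Both channels
#' of a contrast inherit the complex Gaussian noise statistics of the raw
#' signal, which is what makes them suitable for a joint real-valued PCA.
#'
#' @param set a [complex_image_set()].
#' @param residuals list of M_c residual-phase volumes (radians), one per
#'   contrast, on the set's grid.
#' @return a [contrast_stack()] with 2 * M_c channels.
#' @export
build_complex_stack <- function(set, residuals) {
  stopifnot(inherits(set, "complex_image_set"))
  mc <- set$n_contrasts
  if (!is.list(residuals)) residuals <- list(residuals)
  if (length(residuals) != mc) {
    stop("need one residual-phase volume per contrast", call. = FALSE)
  }
  shp <- set$header$shape
  data <- array(0, c(shp, 2L * mc))
  labels <- character(2L * mc)
  for (c in seq_len(mc)) {
    if (!identical(dim(residuals[[c]]), as.integer(shp)) &&
        !identical(dim(residuals[[c]]), dim(set$magnitudes[[c]]))) {
      stop(sprintf("residual %d grid does not match the set", c),
           call. = FALSE)
    }
    data[, , , 2L * c - 1L] <- set$magnitudes[[c]] * cos(residuals[[c]])
    data[, , , 2L * c] <- set$magnitudes[[c]] * sin(residuals[[c]])
    labels[2L * c - 1L] <- sprintf("contrast%d_real", c)
    labels[2L * c] <- sprintf("contrast%d_imag", c)
  }
  contrast_stack(data, labels, set$header)
}

#' Rebuild magnitude/phase contrasts from a denoised stack
#'
#' Inverts [build_complex_stack()]: per contrast, magnitude is the modulus
#' of the (real, imag) pair and phase is its argument plus the reintroduced
#' global phase, wrapped back to `[-pi, pi)`.
#'
#' @param denoised a [contrast_stack()] with 2 * M_c channels in
#'   [build_complex_stack()] order.
#' @param global_phases list of M_c global-phase volumes (radians).
#' @return a [complex_image_set()].
#' @export
restore_outputs <- function(denoised, global_phases) {
  stopifnot(inherits(denoised, "contrast_stack"))
  m <- dim(denoised$data)[4]
  if (m %% 2L != 0L) {
    stop("stack has an odd channel count; expected real/imag pairs",
         call. = FALSE)
  }
  mc <- m %/% 2L
  if (!is.list(global_phases)) global_phases <- list(global_phases)
  if (length(global_phases) != mc) {
    stop("need one global-phase volume per contrast", call. = FALSE)
  }
  mags <- vector("list", mc)
  phas <- vector("list", mc)
  for (c in seq_len(mc)) {
    re <- denoised$data[, , , 2L * c - 1L]
    im <- denoised$data[, , , 2L * c]
    mags[[c]] <- sqrt(re^2 + im^2)
    phas[[c]] <- rewrap(atan2(im, re) + global_phases[[c]])
  }
  complex_image_set(mags, phas, denoised$header)
}

#' Full phase preprocessing of a complex image set
#'
#' Runs, independently for each contrast (echoes carry different global
#' fields): magnitude-guided phase unwrapping, TV split into global and
#' residual phase, and complex-stack construction.
#'
#' @param set a [complex_image_set()].
#' @param tv_weight,max_iter,tol passed to [split_global_phase()].
#' @return list with `stack` (a [contrast_stack()]), `global_phases`
#'   (list of M_c volumes) and `decompositions` (list of
#'   `phase_decomposition`).
#' @export
preprocess_complex_set <- function(set, tv_weight = 0.5, max_iter = 500L,
                                   tol = 1e-5) {
  stopifnot(inherits(set, "complex_image_set"))
  mc <- set$n_contrasts
  decs <- vector("list", mc)
  for (c in seq_len(mc)) {
    mag <- set$magnitudes[[c]]
    uw <- unwrap_phase(set$phases[[c]], quality = mag)
    decs[[c]] <- split_global_phase(uw, tv_weight = tv_weight,
                                    max_iter = max_iter, tol = tol,
                                    mask = mag == 0)
  }
  stack <- build_complex_stack(set, lapply(decs, `[[`, "residual_phase"))
  list(stack = stack,
       global_phases = lapply(decs, `[[`, "global_phase"),
       decompositions = decs)
}
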