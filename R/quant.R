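#' Multi-echo magnitude series
#'
#' @param echo_times numeric vector of E echo times (ms), strictly
#'   increasing, positive, E >= 2.
#' @param magnitudes list of E 3D magnitude volumes on one grid, or a 4D
#'   array with echoes in the 4th dimension.
#' @return object of class `echo_series`.
#' @export
echo_series <- function(echo_times, magnitudes) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 2L || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    stop("`echo_times` must be >= 2 strictly increasing positive values",
         call. = FALSE)
  }
  if (is.array(magnitudes) && length(dim(magnitudes)) == 4L) {
    magnitudes <- lapply(seq_len(dim(magnitudes)[4]),
                         function(e) magnitudes[, , , e])
  }
  if (length(magnitudes) != length(echo_times)) {
    stop("need one magnitude volume per echo time", call. = FALSE)
  }
  shp <- dim(magnitudes[[1]])
  if (length(shp) != 3L) stop("magnitudes must be 3D volumes",
                              call. = FALSE)
  for (e in seq_along(magnitudes)) {
    if (!identical(dim(magnitudes[[e]]), shp)) {
      stop(sprintf("echo %d grid mismatch", e), call. = FALSE)
    }
  }
  structure(list(echo_times = echo_times, magnitudes = magnitudes),
            class = "echo_series")
}

#' Log-domain T2* relaxometry fit
#'
#' Per-voxel ordinary least squares of `log(magnitude)` on echo time:
#' the slope is `-R2*` (in 1/ms, since echo times are in ms) and the
#' intercept is `log(S0)`. The regression is unweighted — a simple
#' log-domain fit. Voxels where any echo magnitude is non-positive (the
#' log is undefined) or outside the mask are flagged invalid and set NA in
#' all maps.
#'
#' @param series an [echo_series()].
#' @param mask optional logical 3D array restricting the fit.
#' @return object of class `relaxometry_maps`: `r2star` (1/ms), `t2star`
#'   (ms; NA where `r2star <= 0`), `s0` (signal units), `valid` (logical
#'   3D array).
#' @export
fit_t2star <- function(series, mask = NULL) {
  stopifnot(inherits(series, "echo_series"))
  te <- series$echo_times
  e <- length(te)
  shp <- dim(series$magnitudes[[1]])
  nvox <- prod(shp)
  y <- matrix(NA_real_, nvox, e)
  for (i in seq_len(e)) y[, i] <- as.vector(series$magnitudes[[i]])
  valid <- rowSums(y > 0) == e
  if (!is.null(mask)) {
    if (!identical(dim(mask), shp)) stop("mask grid mismatch",
                                         call. = FALSE)
    valid <- valid & as.vector(as.logical(mask))
  }
  if (!any(valid)) {
    stop(sprintf("no valid voxels to fit (%d candidates)", nvox),
         call. = FALSE)
  }
  ly <- log(y[valid, , drop = FALSE])
  tc <- te - mean(te)
  sxx <- sum(tc^2)
  slope <- as.vector(ly %*% tc) / sxx
  intercept <- rowMeans(ly) - slope * mean(te)
  r2star_v <- rep(NA_real_, nvox)
  s0_v <- rep(NA_real_, nvox)
  r2star_v[valid] <- -slope
  s0_v[valid] <- exp(intercept)
  t2star_v <- ifelse(!is.na(r2star_v) & r2star_v > 0, 1 / r2star_v,
                     NA_real_)
  structure(list(r2star = array(r2star_v, shp),
                 t2star = array(t2star_v, shp),
                 s0 = array(s0_v, shp),
                 valid = array(valid, shp)),
            class = "relaxometry_maps")
}

#' Region signal-to-noise statistics
#'
#' Per labelled structure: mean signal, standard deviation (population
#' denominator n) and their ratio, the region SNR. A region with zero
#' spread gets `snr = NA` (undefined) rather than infinity; labels with
#' fewer than 2 voxels are skipped with a warning. Label 0 is treated as
#' background and ignored.
#'
#' @param volume 3D numeric array.
#' @param mask 3D integer label array on the same grid.
#' @param label_names optional character vector naming labels 1, 2, ...
#' @return tibble with columns `label`, `n_voxels`, `mean`, `std`, `snr`.
#' @export
region_snr <- function(volume, mask, label_names = NULL) {
  if (!identical(dim(volume), dim(mask))) {
    stop("volume and mask grids differ", call. = FALSE)
  }
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs != 0]
  rows <- lapply(labs, function(l) {
    v <- volume[mask == l]
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      warning(sprintf("label %s has < 2 voxels; skipped", l))
      return(NULL)
    }
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    nm <- if (!is.null(label_names) && l <= length(label_names))
      label_names[l] else as.character(l)
    tibble::tibble(label = nm, n_voxels = length(v), mean = mu,
                   std = sd_pop,
                   snr = if (sd_pop > 0) mu / sd_pop else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no label has >= 2 voxels", call. = FALSE)
  }
  out
}

#' Per-region SNR improvement from denoising
#'
#' The difference in region SNR (mean over population std within each
#' labelled structure) between the denoised and original volumes;
#' positive values mean the denoised image is cleaner.
#'
#' @param original,denoised 3D arrays on one grid.
#' @param mask 3D integer label array.
#' @param label_names optional names for labels 1, 2, ...
#' @return tibble with `label`, `snr_original`, `snr_denoised`,
#'   `improvement` (NA where either SNR is undefined).
#' @export
snr_improvement <- function(original, denoised, mask, label_names = NULL) {
  if (!identical(dim(original), dim(denoised))) {
    stop("original and denoised grids differ", call. = FALSE)
  }
  so <- region_snr(original, mask, label_names)
  sd_ <- region_snr(denoised, mask, label_names)
  merged <- merge(as.data.frame(so[, c("label", "snr")]),
                  as.data.frame(sd_[, c("label", "snr")]),
                  by = "label", suffixes = c("_original", "_denoised"),
                  sort = FALSE)
  tibble::tibble(label = merged$label,
                 snr_original = merged$snr_original,
                 snr_denoised = merged$snr_denoised,
                 improvement = merged$snr_denoised - merged$snr_original)
}
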