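#' Read a multi-contrast magnitude/phase set from NIfTI files
#'
#' Reads paired magnitude and phase volumes (NIfTI-1, plain or gzipped),
#' validates that all volumes share one grid, and normalises phase units to
#' radians in `[-pi, pi)`. Scanner exports store phase on several
#' conventions; when a phase volume's range is inconsistent with radians a
#' documented list of linear rescalings is attempted (see
#' [normalise_phase_units()]) and the applied mapping is recorded in the
#' returned set's `phase_scaling` attribute.
#'
#' @param magnitude_paths character vector of magnitude NIfTI paths.
#' @param phase_paths character vector of phase NIfTI paths, same length.
#' @return A [complex_image_set()]; attribute `phase_scaling` holds one
#'   scaling label per contrast.
#' @export
read_complex_set <- function(magnitude_paths, phase_paths) {
  if (length(magnitude_paths) < 1L ||
      length(magnitude_paths) != length(phase_paths)) {
    stop("need equal numbers (>= 1) of magnitude and phase paths",
         call. = FALSE)
  }
  paths <- c(magnitude_paths, phase_paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("file not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mags <- lapply(magnitude_paths, RNifti::readNifti)
  phas <- lapply(phase_paths, RNifti::readNifti)
  hdr <- header_from_nifti(mags[[1]])
  check_grid <- function(img, path) {
    h <- header_from_nifti(img)
    if (!identical(h$shape, hdr$shape)) {
      stop(sprintf("grid mismatch: %s has shape %s, expected %s",
                   path, paste(h$shape, collapse = "x"),
                   paste(hdr$shape, collapse = "x")), call. = FALSE)
    }
  }
  for (i in seq_along(mags)) {
    check_grid(mags[[i]], magnitude_paths[i])
    check_grid(phas[[i]], phase_paths[i])
  }
  scalings <- character(length(phas))
  for (i in seq_along(phas)) {
    norm <- normalise_phase_units(as.array(phas[[i]]))
    phas[[i]] <- norm$phase
    scalings[i] <- norm$scaling
    if (norm$scaling != "radians") {
      message(sprintf("phase volume %d (%s): applied rescaling '%s'",
                      i, basename(phase_paths[i]), norm$scaling))
    }
  }
  set <- complex_image_set(lapply(mags, as.array), phas, hdr)
  attr(set, "phase_scaling") <- scalings
  set
}

#' Normalise a phase volume to radians in [-pi, pi)
#'
#' Known storage conventions, tried in order when the raw range exceeds
#' `[-pi - 0.01, pi + 0.01]`:
#' \describe{
#'   \item{`radians`}{already in `[-pi, pi)` (or `(-pi, pi]`, re-wrapped).}
#'   \item{`radians_0_2pi`}{radians in `[0, 2*pi)`; re-wrapped.}
#'   \item{`integer_0_4096`}{scanner integers in `[0, 4096)`; mapped
#'     linearly onto `[-pi, pi)` as `x / 4096 * 2*pi - pi`.}
#'   \item{`integer_pm4096`}{integers in `[-4096, 4096)`; mapped as
#'     `x / 4096 * pi`.}
#'   \item{`degrees`}{values in `[-180, 180]`; mapped as `x * pi / 180`.}
#'   \item{`milliradians`}{values in `[-1000*pi, 1000*pi]`; divided by 1000.}
#' }
#' Anything else fails loudly rather than silently corrupting the complex
#' reconstruction.
#'
#' @param phase 3D numeric array of raw phase values.
#' @return list with `phase` (radians in `[-pi, pi)`) and `scaling` (label).
#' @export
normalise_phase_units <- function(phase) {
  rng <- range(phase)
  tol <- 0.01
  if (rng[1] >= -pi - tol && rng[2] <= pi + tol) {
    return(list(phase = rewrap(phase), scaling = "radians"))
  }
  if (rng[1] >= -tol && rng[2] <= 2 * pi + tol) {
    return(list(phase = rewrap(phase), scaling = "radians_0_2pi"))
  }
  if (rng[1] >= -tol && rng[2] < 4096) {
    return(list(phase = rewrap(phase / 4096 * 2 * pi - pi),
                scaling = "integer_0_4096"))
  }
  if (rng[1] >= -4096 && rng[2] < 4096) {
    return(list(phase = rewrap(phase / 4096 * pi),
                scaling = "integer_pm4096"))
  }
  if (rng[1] >= -180 - tol && rng[2] <= 180 + tol) {
    return(list(phase = rewrap(phase * pi / 180), scaling = "degrees"))
  }
  if (rng[1] >= -1000 * pi - tol && rng[2] <= 1000 * pi + tol) {
    return(list(phase = rewrap(phase / 1000), scaling = "milliradians"))
  }
  stop(sprintf(paste0("phase range [%.4g, %.4g] inconsistent with radians ",
                      "after known rescalings"), rng[1], rng[2]),
       call. = FALSE)
}

write_volume <- function(vol, header, path) {
  img <- RNifti::asNifti(array(vol, header$shape))
  RNifti::pixdim(img) <- header$voxel_size
  RNifti::qform(img) <- structure(header$affine, code = 1L)
  RNifti::sform(img) <- structure(header$affine, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a denoising result to NIfTI files
#'
#' Writes one magnitude and one phase volume per contrast, plus the two
#' quality-control maps: the patch-weighted local dimension map (number of
#' retained spectral components) and the R-squared map of the noise-line
#' fit. Filenames are deterministic: `<prefix>_den-mag<i>.nii.gz`,
#' `<prefix>_den-phs<i>.nii.gz`, `<prefix>_den-dim.nii.gz`,
#' `<prefix>_den-r2.nii.gz`. Headers are copied from the input set.
#'
#' @param result list from [lcpca_denoise()] with elements `denoised`
#'   (a [complex_image_set()]), `dimension_map`, `fit_map`.
#' @param output_dir directory to write into (created if absent).
#' @param prefix filename stem, default "lcpca".
#' @return character vector of file paths written (2 per contrast + 2).
#' @export
write_denoise_result <- function(result, output_dir, prefix = "lcpca") {
  set <- result$denoised
  if (!inherits(set, "complex_image_set")) {
    stop("`result$denoised` must be a complex_image_set", call. = FALSE)
  }
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir,
                  call. = FALSE)
  }
  hdr <- set$header
  paths <- character(0)
  for (i in seq_len(set$n_contrasts)) {
    pm <- file.path(output_dir, sprintf("%s_den-mag%d.nii.gz", prefix, i))
    pp <- file.path(output_dir, sprintf("%s_den-phs%d.nii.gz", prefix, i))
    write_volume(set$magnitudes[[i]], hdr, pm)
    write_volume(set$phases[[i]], hdr, pp)
    paths <- c(paths, pm, pp)
  }
  pd <- file.path(output_dir, sprintf("%s_den-dim.nii.gz", prefix))
  pr <- file.path(output_dir, sprintf("%s_den-r2.nii.gz", prefix))
  write_volume(result$dimension_map, hdr, pd)
  write_volume(result$fit_map, hdr, pr)
  c(paths, pd, pr)
}

#' Write a JSON run log sidecar
#'
#' Records the fully resolved parameter set and per-stage timings of a run
#' so that any output can be reproduced from its sidecar alone.
#'
#' @param path output JSON path.
#' @param params named list of resolved parameters.
#' @param timings named numeric vector/list of per-stage elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, params, timings = NULL) {
  log <- list(tool = "lcpca",
              version = as.character(utils::packageVersion("lcpca")),
              parameters = params,
              timings_sec = as.list(timings))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
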