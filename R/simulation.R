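#' Specification of the patch-level threshold simulation
#'
#' One experimental condition for the noise-threshold study: low-rank
#' signal patches of `n^3` voxels by `m` channels with added Gaussian
#' noise, optionally resampled by trilinear interpolation to induce
#' spatial noise correlations.
#'
#' @param n patch edge in voxels (default 4).
#' @param m number of channels (default 10, as for 5 complex contrasts).
#' @param rank number of non-zero signal components, in `[0, m]`
#'   (default 3).
#' @param snr signal-to-noise ratio: RMS signal entry amplitude divided by
#'   the per-entry noise std.
#' @param interpolation one of `"none"`, `"single"` (one random
#'   half-voxel trilinear shift applied identically to all channels) or
#'   `"per_dimension"` (an independent shift per channel).
#' @param reps number of simulated patches.
#' @param seed RNG seed.
#' @return object of class `patch_sim_spec`.
#' @export
patch_sim_spec <- function(n = 4L, m = 10L, rank = 3L, snr = 20,
                           interpolation = c("none", "single",
                                             "per_dimension"),
                           reps = 10000L, seed = 20260101L) {
  interpolation <- match.arg(interpolation)
  n <- as.integer(n); m <- as.integer(m); rank <- as.integer(rank)
  if (rank < 0L || rank > m) stop("`rank` must be in [0, m]", call. = FALSE)
  if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
  if (reps < 1L) stop("`reps` must be >= 1", call. = FALSE)
  structure(list(n = n, m = m, rank = rank, snr = snr,
                 interpolation = interpolation, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "patch_sim_spec")
}

random_orthonormal <- function(nrow, ncol) {
  q <- qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))
  q[, seq_len(ncol), drop = FALSE]
}

# Trilinear resampling of a 3D array at grid positions shifted by `off`
# (per-axis offsets in voxels); only the `interior` index range is
# returned, so the 1-voxel pad of the simulation support is never
# extrapolated.
shift_trilinear <- function(a, off, interior) {
  ni <- length(interior)
  x <- interior + off[1]; y <- interior + off[2]; z <- interior + off[3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  wx <- x - x0; wy <- y - y0; wz <- z - z0
  out <- array(0, c(ni, ni, ni))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- outer(outer(if (cx) wx else 1 - wx,
                     if (cy) wy else 1 - wy), if (cz) wz else 1 - wz)
    dim(w) <- c(ni, ni, ni)
    out <- out + w * a[x0 + cx, y0 + cy, z0 + cz]
  }
  out
}

#' Simulate one low-rank-plus-noise patch
#'
#' The signal is a sum of `rank` components, each an outer product of a
#' random orthonormal spatial pattern and a random orthonormal channel
#' weight vector, all with equal amplitude. I.i.d. Gaussian noise is added
#' entrywise with std = RMS(signal entries) / snr (for `rank = 0` the
#' noise std is 1). Interpolated modes simulate on an (n+2)^3 support,
#' shift signal+noise jointly by a random offset uniform in
#' `[-0.5, 0.5]` voxels per axis (one shift for all channels, or one per
#' channel), and crop the interior n^3 voxels.
#'
#' @param spec a [patch_sim_spec()].
#' @param rep_seed optional seed for this single patch; by default the
#'   current RNG stream is used (as [run_threshold_experiment()] does).
#' @return n^3 x m numeric matrix with attributes `rank` and `sigma`.
#' @export
simulate_patch <- function(spec, rep_seed = NULL) {
  stopifnot(inherits(spec, "patch_sim_spec"))
  if (!is.null(rep_seed)) set.seed(rep_seed)
  n <- spec$n; m <- spec$m
  pad <- if (spec$interpolation == "none") 0L else 1L
  ns <- n + 2L * pad
  nvox <- ns^3
  signal <- matrix(0, nvox, m)
  if (spec$rank > 0L) {
    u <- random_orthonormal(nvox, spec$rank)
    v <- random_orthonormal(m, spec$rank)
    amp <- spec$snr * sqrt(nvox * m / spec$rank)  # unit-sigma RMS target
    signal <- amp * u %*% t(v)
  }
  sigma <- 1
  composed <- signal + matrix(stats::rnorm(nvox * m, sd = sigma), nvox, m)
  if (spec$interpolation == "none") {
    out <- composed
  } else {
    interior <- (pad + 1L):(pad + n)
    out <- matrix(0, n^3, m)
    off <- stats::runif(3, -0.5, 0.5)
    for (j in seq_len(m)) {
      if (spec$interpolation == "per_dimension" && j > 1L) {
        off <- stats::runif(3, -0.5, 0.5)
      }
      vol <- array(composed[, j], c(ns, ns, ns))
      out[, j] <- shift_trilinear(vol, off, interior)
    }
  }
  attr(out, "rank") <- spec$rank
  attr(out, "sigma") <- sigma
  out
}

#' Run the patch-level noise-threshold experiment
#'
#' For each repetition: simulate a patch, column-center and SVD it, and
#' apply each threshold method — the linear fit to the `floor(m/2)` lowest
#' singular values with margin `alpha`, and/or the Marchenko-Pastur
#' random-matrix threshold — recording the number of retained components.
#' Fully reproducible from the spec (including its seed).
#'
#' @param spec a [patch_sim_spec()].
#' @param methods subset of `c("linear_fit", "rmt")`.
#' @param alpha linear-fit margin (default 0.05).
#' @param fit_count number of lowest singular values fitted; default
#'   `floor(m/2)`.
#' @return object of class `threshold_experiment`: list with `spec`,
#'   `kept` (tibble: method, rep, kept) and `summary` (tibble: method,
#'   median_kept, mean_kept, plus one `kept_<k>` histogram column per
#'   possible count 0..m).
#' @export
run_threshold_experiment <- function(spec,
                                     methods = c("linear_fit", "rmt"),
                                     alpha = 0.05, fit_count = NULL) {
  stopifnot(inherits(spec, "patch_sim_spec"))
  methods <- match.arg(methods, c("linear_fit", "rmt"),
                       several.ok = TRUE)
  m <- spec$m
  if (is.null(fit_count)) fit_count <- max(2L, m %/% 2L)
  n3 <- spec$n^3
  kept <- matrix(NA_integer_, spec$reps, length(methods),
                 dimnames = list(NULL, methods))
  with_seed(spec$seed, {
    for (r in seq_len(spec$reps)) {
      x <- simulate_patch(spec)
      xc <- sweep(x, 2L, colMeans(x), "-")
      d <- svd(xc, nu = 0, nv = 0)$d
      if ("linear_fit" %in% methods) {
        line <- fit_noise_line(d, fit_count)
        kept[r, "linear_fit"] <- threshold_spectrum(d, line, alpha)
      }
      if ("rmt" %in% methods) {
        kept[r, "rmt"] <- rmt_threshold(d^2 / n3, n3)
      }
    }
  })
  long <- tibble::tibble(
    method = rep(methods, each = spec$reps),
    rep = rep(seq_len(spec$reps), times = length(methods)),
    kept = as.integer(as.vector(kept[, methods, drop = FALSE])))
  summ <- do.call(rbind, lapply(methods, function(meth) {
    k <- kept[, meth]
    hist <- tabulate(k + 1L, nbins = m + 1L)
    row <- tibble::tibble(method = meth,
                          median_kept = stats::median(k),
                          mean_kept = mean(k))
    hist_df <- as.data.frame(as.list(hist))
    names(hist_df) <- sprintf("kept_%d", 0:m)
    cbind(row, hist_df)
  }))
  structure(list(spec = spec, kept = long,
                 summary = tibble::as_tibble(summ)),
            class = "threshold_experiment")
}

#' @export
print.threshold_experiment <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<threshold_experiment> n=%d m=%d rank=%d snr=%g ",
                     "interp=%s reps=%d\n"),
              s$n, s$m, s$rank, s$snr, s$interpolation, s$reps))
  print(x$summary[, c("method", "median_kept", "mean_kept")])
  invisible(x)
}

#' Histogram of retained-component counts per method
#'
#' @param x a `threshold_experiment`.
#' @param ... unused.
#' @return a ggplot object: count histograms by method, with the true
#'   signal rank marked by a dashed line.
#' @export
plot_threshold_experiment <- function(x, ...) {
  stopifnot(inherits(x, "threshold_experiment"))
  ggplot2::ggplot(x$kept, ggplot2::aes(x = .data$kept)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = x$spec$rank, linetype = "dashed") +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_x_continuous(breaks = 0:x$spec$m,
                                limits = c(-0.5, x$spec$m + 0.5)) +
    ggplot2::labs(x = "retained components", y = "patches",
                  title = sprintf("rank %d, SNR %g, interpolation: %s",
                                  x$spec$rank, x$spec$snr,
                                  x$spec$interpolation))
}
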