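#' Parameters of the local complex PCA
#'
#' @param patch_size patch edge N in voxels (default 4).
#' @param alpha multiplicative margin over the fitted noise line: a
#'   singular value is retained when it exceeds `(1 + alpha)` times the
#'   line. Default 0.05 (5 percent).
#' @param stride offset between neighbouring patch origins, in voxels;
#'   `patch_size / 2` by default (8-fold interior coverage), down to 1 for
#'   a fully overcomplete sweep.
#' @param fit_count number of lowest singular values used for the noise
#'   line; `NULL` resolves to `floor(M / 2)` for an M-channel stack.
#' @return object of class `lcpca_params`.
#' @export
lcpca_params <- function(patch_size = 4L, alpha = 0.05, stride = NULL,
                         fit_count = NULL) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 2L) stop("`patch_size` must be >= 2", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive real", call. = FALSE)
  }
  if (is.null(stride)) stride <- max(1L, patch_size %/% 2L)
  stride <- as.integer(stride)
  if (stride < 1L || stride > patch_size) {
    stop("`stride` must be in [1, patch_size]", call. = FALSE)
  }
  if (!is.null(fit_count)) {
    fit_count <- as.integer(fit_count)
    if (fit_count < 2L) stop("`fit_count` must be >= 2", call. = FALSE)
  }
  structure(list(patch_size = patch_size, alpha = alpha, stride = stride,
                 fit_count = fit_count),
            class = "lcpca_params")
}

# Stride-spaced 1D origin grid, clamped so the last patch ends at the
# volume face; every voxel is covered by at least one patch.
patch_origins_1d <- function(size, n, stride) {
  if (size < n) stop("volume dimension smaller than patch size",
                     call. = FALSE)
  last <- size - n + 1L
  og <- seq.int(1L, last, by = stride)
  if (og[length(og)] != last) og <- c(og, last)
  og
}

#' Enumerate overlapping patches of a contrast stack
#'
#' Origins lie on a stride-spaced grid; near the far faces the final origin
#' is clamped inside the volume rather than zero-padding, so every voxel is
#' covered by at least one patch and the PCA never sees artificial
#' boundaries. Order is deterministic (x fastest, then y, then z).
#'
#' @param stack a [contrast_stack()].
#' @param params an [lcpca_params()].
#' @return list of patches; each has `values` (N^3 x M matrix, x fastest),
#'   `origin` (3 ints, 1-based), `N`, and `means` (per-channel patch mean).
#' @export
sweep_patches <- function(stack, params = lcpca_params()) {
  stopifnot(inherits(stack, "contrast_stack"))
  d <- dim(stack$data)
  n <- params$patch_size
  og <- lapply(d[1:3], patch_origins_1d, n = n, stride = params$stride)
  out <- vector("list", length(og[[1]]) * length(og[[2]]) * length(og[[3]]))
  i <- 0L
  for (oz in og[[3]]) for (oy in og[[2]]) for (ox in og[[1]]) {
    vals <- stack$data[ox:(ox + n - 1L), oy:(oy + n - 1L),
                       oz:(oz + n - 1L), , drop = FALSE]
    dim(vals) <- c(n^3, d[4])
    i <- i + 1L
    out[[i]] <- list(values = vals, origin = c(ox, oy, oz), N = n,
                     means = colMeans(vals))
  }
  out
}

#' Singular value decomposition of a patch
#'
#' Column-centers the N^3 x M patch matrix (per-channel mean removed) and
#' decomposes it by SVD. The squared singular values divided by (N^3 - 1)
#' are the eigenvalues of the patch covariance across channels; the right
#' singular vectors are the corresponding eigenvectors (the channel-space
#' basis used for denoising).
#'
#' @param patch a patch from [sweep_patches()] (list with `values`,
#'   `means`), or a bare N^3 x M matrix.
#' @return object of class `patch_spectrum`: `singular_values`
#'   (non-increasing), `basis` (M x M orthonormal columns), `means`, plus
#'   `noise_line` and `kept` slots filled by [fit_noise_line()] /
#'   [threshold_spectrum()].
#' @export
decompose_patch <- function(patch) {
  if (is.matrix(patch)) patch <- list(values = patch,
                                      means = colMeans(patch))
  x <- patch$values
  if (any(!is.finite(x))) stop("patch contains non-finite values",
                               call. = FALSE)
  xc <- sweep(x, 2L, patch$means, "-")
  sv <- svd(xc, nu = 0, nv = ncol(xc))
  structure(list(singular_values = sv$d, basis = sv$v,
                 means = patch$means, n_samples = nrow(x),
                 noise_line = NULL, kept = NA_integer_),
            class = "patch_spectrum")
}

#' Least-squares line through the lowest singular values
#'
#' Gaussian-noise singular values of a small patch decomposition are well
#' approximated by a straight line in rank order; fitting the `fit_count`
#' smallest values gives a local estimate of the noise floor. The abscissa
#' is the rank index in the descending-sorted spectrum (1 = largest), so
#' the line can be evaluated at any rank.
#'
#' @param singular_values numeric vector, non-increasing.
#' @param fit_count how many of the smallest values to fit (>= 2);
#'   default `floor(M / 2)`.
#' @return list with `slope`, `intercept`, `r_squared`. A perfectly
#'   constant (and exactly fitted) segment has `r_squared = 1`.
#' @export
fit_noise_line <- function(singular_values,
                           fit_count = length(singular_values) %/% 2L) {
  m <- length(singular_values)
  fit_count <- as.integer(fit_count)
  if (fit_count < 2L || fit_count > m) {
    stop("`fit_count` must be in [2, length(singular_values)]",
         call. = FALSE)
  }
  idx <- (m - fit_count + 1L):m
  y <- singular_values[idx]
  x <- as.numeric(idx)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - (intercept + slope * x)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - yb)^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else
    as.numeric(ss_res <= .Machine$double.eps * max(1, yb^2) * fit_count)
  list(slope = slope, intercept = intercept,
       r_squared = max(0, min(1, r_squared)))
}

#' Threshold a singular-value spectrum against its fitted noise line
#'
#' A singular value at rank i is retained when it exceeds
#' `(1 + alpha) * line(i)` with `line(i) = intercept + slope * i` clamped
#' below at zero (singular values are non-negative). Retained components
#' form a prefix of the sorted spectrum: the first rank failing the test
#' truncates, since the denoising projects onto a leading subspace and an
#' isolated exceedance deeper in the spectrum is noise.
#'
#' @param singular_values numeric vector, non-increasing.
#' @param noise_line list with `slope` and `intercept` from
#'   [fit_noise_line()].
#' @param alpha positive multiplicative margin (default 0.05).
#' @return integer, the number of retained components in `[0, M]`.
#' @export
threshold_spectrum <- function(singular_values, noise_line, alpha = 0.05) {
  m <- length(singular_values)
  ranks <- seq_len(m)
  line <- pmax(0, noise_line$intercept + noise_line$slope * ranks)
  ok <- singular_values > (1 + alpha) * line
  first_fail <- which(!ok)
  if (length(first_fail) == 0L) m else first_fail[1L] - 1L
}

#' Marchenko-Pastur (random matrix theory) component count
#'
#' Comparison method: iteratively finds the largest signal dimension p such
#' that the M - p smallest covariance eigenvalues are consistent with a
#' pure-noise Marchenko-Pastur bulk. Consistency test: the empirical spread
#' of the candidate bulk must not exceed the MP bulk width implied by its
#' own mean, `lambda_max - lambda_min <= 4 * sqrt(gamma) * sigma^2` with
#' `gamma = (M - p) / n_samples` and `sigma^2` the bulk mean. Deterministic.
#'
#' @param eigenvalues numeric vector of covariance eigenvalues (>= 0), any
#'   order.
#' @param n_samples number of samples per eigenvalue (N^3 for an N-voxel
#'   patch).
#' @return integer, the estimated number of signal components.
#' @export
rmt_threshold <- function(eigenvalues, n_samples) {
  if (any(eigenvalues < -1e-12 * max(abs(eigenvalues), 1))) {
    stop("`eigenvalues` must be non-negative", call. = FALSE)
  }
  lam <- sort(pmax(eigenvalues, 0), decreasing = TRUE)
  m <- length(lam)
  for (p in 0:(m - 1L)) {
    bulk <- lam[(p + 1L):m]
    gamma <- (m - p) / n_samples
    sigma2 <- mean(bulk)
    if ((bulk[1L] - bulk[length(bulk)]) <= 4 * sqrt(gamma) * sigma2) {
      return(p)
    }
  }
  m
}

#' Project a patch onto its retained components
#'
#' The centered patch matrix is projected onto the first `kept` right
#' singular vectors and the per-channel means are added back. `kept = M`
#' reproduces the input exactly; `kept = 0` returns each channel constant
#' at its patch mean.
#'
#' @param patch patch (list with `values`) or bare N^3 x M matrix.
#' @param spectrum a `patch_spectrum` for this patch with its `kept` slot
#'   set, or an integer number of components to keep.
#' @return N^3 x M matrix of denoised values.
#' @export
denoise_patch <- function(patch, spectrum) {
  if (is.matrix(patch)) patch <- list(values = patch,
                                      means = colMeans(patch))
  x <- patch$values
  m <- ncol(x)
  if (is.numeric(spectrum) && length(spectrum) == 1L) {
    k <- as.integer(spectrum)
    spectrum <- decompose_patch(patch)
    spectrum$kept <- k
  }
  kept <- spectrum$kept
  if (is.na(kept) || kept < 0L || kept > m) {
    stop("spectrum `kept` must be set and in [0, M]", call. = FALSE)
  }
  if (kept == m) return(x)
  mu <- patch$means
  if (kept == 0L) {
    return(matrix(mu, nrow = nrow(x), ncol = m, byrow = TRUE))
  }
  xc <- sweep(x, 2L, mu, "-")
  v <- spectrum$basis[, seq_len(kept), drop = FALSE]
  sweep(xc %*% v %*% t(v), 2L, mu, "+")
}

#' Recombine overlapping denoised patches into volumes
#'
#' Each patch contributes with weight `W = 1 / (1 + kept)`, so patches that
#' retained fewer components (flatter, more aggressively denoised) weigh
#' more; voxel values are the W-weighted average of all covering patches.
#' The same weighted average of the per-patch constants `kept` and
#' `r_squared` yields the two quality-control maps.
#'
#' @param patches list; each element has `values` (N^3 x M denoised
#'   matrix), `origin`, `N`, `kept`, `r_squared`.
#' @param shape 3 ints, spatial grid.
#' @param n_channels M.
#' @return list with `data` (4D array), `dimension_map`, `fit_map`,
#'   `weight_sum`.
#' @export
recombine <- function(patches, shape, n_channels) {
  shape <- as.integer(shape)
  num <- array(0, c(shape, n_channels))
  den <- array(0, shape)
  dsum <- array(0, shape)
  fsum <- array(0, shape)
  for (p in patches) {
    n <- p$N
    xs <- p$origin[1]:(p$origin[1] + n - 1L)
    ys <- p$origin[2]:(p$origin[2] + n - 1L)
    zs <- p$origin[3]:(p$origin[3] + n - 1L)
    w <- 1 / (1 + p$kept)
    num[xs, ys, zs, ] <- num[xs, ys, zs, , drop = FALSE] +
      w * array(p$values, c(n, n, n, n_channels))
    den[xs, ys, zs] <- den[xs, ys, zs] + w
    dsum[xs, ys, zs] <- dsum[xs, ys, zs] + w * p$kept
    fsum[xs, ys, zs] <- fsum[xs, ys, zs] + w * p$r_squared
  }
  if (any(den == 0)) {
    stop(sprintf("%d voxel(s) not covered by any patch", sum(den == 0)),
         call. = FALSE)
  }
  data <- num / as.vector(den)  # den recycles over the channel dimension
  list(data = data, dimension_map = dsum / den, fit_map = fsum / den,
       weight_sum = den)
}

#' Denoise a contrast stack by local complex PCA
#'
#' The full patch pipeline: sweep overlapping N^3 patches, SVD each, fit
#' the noise line to the lowest singular values, threshold at
#' `(1 + alpha)` times the line, project onto the retained subspace, and
#' recombine with weights `1 / (1 + kept)`. Deterministic for fixed input.
#'
#' @param stack a [contrast_stack()] (typically from
#'   [build_complex_stack()]).
#' @param params an [lcpca_params()].
#' @return object of class `denoise_result`: `denoised` (a
#'   [contrast_stack()]), `dimension_map` (weighted mean retained
#'   dimension, in `[0, M]`), `fit_map` (weighted mean noise-line
#'   R-squared, in `[0, 1]`).
#' @export
denoise_stack <- function(stack, params = lcpca_params()) {
  stopifnot(inherits(stack, "contrast_stack"))
  d <- dim(stack$data)
  n <- params$patch_size
  m <- d[4]
  if (any(d[1:3] < n)) {
    stop("every spatial dimension must be >= patch_size", call. = FALSE)
  }
  fit_count <- if (is.null(params$fit_count)) max(2L, m %/% 2L) else
    params$fit_count
  if (fit_count > m) stop("`fit_count` exceeds channel count",
                          call. = FALSE)
  og <- lapply(d[1:3], patch_origins_1d, n = n, stride = params$stride)
  n3 <- n^3
  num <- array(0, d)
  den <- array(0, d[1:3])
  dsum <- den
  fsum <- den
  for (oz in og[[3]]) for (oy in og[[2]]) for (ox in og[[1]]) {
    xs <- ox:(ox + n - 1L); ys <- oy:(oy + n - 1L); zs <- oz:(oz + n - 1L)
    vals <- stack$data[xs, ys, zs, , drop = FALSE]
    dim(vals) <- c(n3, m)
    mu <- colMeans(vals)
    xc <- vals - rep(mu, each = n3)
    sv <- La.svd(xc, nu = 0L, nv = m)
    line <- fit_noise_line(sv$d, fit_count)
    kept <- threshold_spectrum(sv$d, line, params$alpha)
    if (kept == m) {
      rec <- vals
    } else if (kept == 0L) {
      rec <- matrix(mu, nrow = n3, ncol = m, byrow = TRUE)
    } else {
      vt <- sv$vt[seq_len(kept), , drop = FALSE]
      rec <- (xc %*% t(vt)) %*% vt + rep(mu, each = n3)
    }
    w <- 1 / (1 + kept)
    num[xs, ys, zs, ] <- num[xs, ys, zs, , drop = FALSE] +
      w * array(rec, c(n, n, n, m))
    den[xs, ys, zs] <- den[xs, ys, zs] + w
    dsum[xs, ys, zs] <- dsum[xs, ys, zs] + w * kept
    fsum[xs, ys, zs] <- fsum[xs, ys, zs] + w * line$r_squared
  }
  out <- contrast_stack(num / as.vector(den), stack$channel_labels,
                        stack$header)
  structure(list(denoised = out, dimension_map = dsum / den,
                 fit_map = fsum / den),
            class = "denoise_result")
}
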