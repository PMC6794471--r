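test_that("patch sweep covers the volume on a clamped stride grid", {
  params <- lcpca_params(patch_size = 4, stride = 2)

  st1 <- contrast_stack(array(rnorm(4^3 * 2), c(4, 4, 4, 2)))
  expect_length(sweep_patches(st1, params), 1L)

  st2 <- contrast_stack(array(rnorm(8^3 * 2), c(8, 8, 8, 2)))
  patches <- sweep_patches(st2, params)
  expect_length(patches, 27L)
  cover <- array(0L, c(8, 8, 8))
  for (p in patches) {
    idx <- lapply(p$origin, function(o) o:(o + 3L))
    cover[idx[[1]], idx[[2]], idx[[3]]] <-
      cover[idx[[1]], idx[[2]], idx[[3]]] + 1L
  }
  expect_true(all(cover >= 1L))
  expect_true(all(cover <= 8L))

  st3 <- contrast_stack(array(rnorm(5 * 4 * 4 * 2), c(5, 4, 4, 2)))
  p3 <- sweep_patches(st3, params)
  expect_length(p3, 2L)
  expect_identical(sort(vapply(p3, function(p) p$origin[1], integer(1))),
                   c(1L, 2L))

  st_small <- contrast_stack(array(0, c(3, 4, 4, 2)))
  expect_error(sweep_patches(st_small, params), "smaller than patch")
})

test_that("patch decomposition matches its covariance eigenstructure", {
  # constant patch: all singular values zero
  const <- matrix(5, 64, 10)
  expect_lt(max(decompose_patch(const)$singular_values), 1e-10)

  # rank-1 patch: one nonzero singular value equal to the Frobenius norm
  set.seed(31)
  u <- rnorm(64); u <- u - mean(u)
  v <- rnorm(10)
  x <- u %*% t(v)
  sp <- decompose_patch(x)
  expect_equal(sp$singular_values[1], sqrt(sum(x^2)), tolerance = 1e-10)
  expect_lt(sp$singular_values[2] / sp$singular_values[1], 1e-10)

  # oracle: sqrt of covariance eigenvalues * (n-1), on random matrices
  for (i in 1:50) {
    x <- matrix(rnorm(64 * 10), 64, 10)
    sp <- decompose_patch(x)
    ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sp$singular_values, sqrt(pmax(ev, 0) * 63),
                 tolerance = 1e-8)
    gram <- crossprod(sp$basis)
    expect_lt(max(abs(gram - diag(10))), 1e-8)
  }
})

test_that("the noise line fit is exact least squares with sane degenerate cases", {
  s <- 10 - (1:10)  # exact line, slope -1, intercept 10
  fit <- fit_noise_line(s, 5)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  flat <- rep(2, 10)
  fit2 <- fit_noise_line(flat, 5)
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$intercept, 2)
  expect_equal(fit2$r_squared, 1)

  # brute-force normal equations oracle
  set.seed(32)
  for (i in 1:20) {
    s <- sort(abs(rnorm(10, 5)), decreasing = TRUE)
    fit <- fit_noise_line(s, 5)
    xs <- 6:10
    X <- cbind(1, xs)
    beta <- solve(t(X) %*% X, t(X) %*% s[6:10])
    expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
    expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  }

  expect_error(fit_noise_line(s, 1), "fit_count")
})

test_that("spectrum thresholding keeps a prefix above (1+alpha) times the line", {
  line <- list(slope = -1, intercept = 10)
  on_line <- 10 - (1:10)
  expect_identical(threshold_spectrum(on_line, line, 0.05), 0L)

  one_up <- on_line
  one_up[1] <- 10 * (10 - 1)  # 10x the line prediction at rank 1
  expect_identical(threshold_spectrum(one_up, line, 0.05), 1L)

  # prefix truncation: an isolated exceedance below a failing rank is ignored
  s <- c(100, 8.4, 7.9, 7, 6, 5, 4, 3, 2, 1)  # rank 2 fails, rank 3 close
  line2 <- list(slope = -1, intercept = 10)
  k <- threshold_spectrum(s, line2, 0.05)
  expect_identical(k, 1L)

  # negative line values clamp to zero, so positive values are kept
  line3 <- list(slope = -2, intercept = 4)
  s3 <- c(5, 1, 0.5, 0.1)
  expect_identical(threshold_spectrum(s3, line3, 0.05), 4L)
})

test_that("increasing alpha never increases the kept count", {
  set.seed(33)
  for (i in 1:25) {
    s <- sort(abs(rnorm(10, 8, 3)), decreasing = TRUE)
    fit <- fit_noise_line(s, 5)
    alphas <- c(0.01, 0.05, 0.2, 1, 10, 1e6)
    kept <- vapply(alphas, function(a) threshold_spectrum(s, fit, a),
                   integer(1))
    expect_true(all(diff(kept) <= 0))
    if (fit$intercept + fit$slope * 1 > 0) {
      expect_identical(kept[length(kept)], 0L)
    }
  }
})

test_that("the random-matrix threshold flags a pure bulk as noise", {
  expect_identical(rmt_threshold(rep(3, 10), 64), 0L)
  expect_identical(rmt_threshold(rep(0, 10), 64), 0L)
  # three strong components over a noise bulk
  set.seed(34)
  x <- matrix(rnorm(64 * 10), 64, 10)
  x[, 1:3] <- x[, 1:3] + 50 * matrix(rnorm(64 * 3), 64, 3)
  ev <- svd(scale(x, scale = FALSE))$d^2 / 64
  expect_identical(rmt_threshold(ev, 64), 3L)
})

test_that("patch denoising projects onto the retained subspace", {
  set.seed(35)
  x <- matrix(rnorm(64 * 10, 10), 64, 10)
  sp <- decompose_patch(x)

  sp$kept <- 10L
  expect_lt(max(abs(denoise_patch(x, sp) - x)), 1e-10)

  sp$kept <- 0L
  out0 <- denoise_patch(x, sp)
  expect_equal(out0, matrix(colMeans(x), 64, 10, byrow = TRUE),
               tolerance = 1e-12)

  # noiseless rank-2 patch: projecting on its own 2D subspace is lossless
  u <- matrix(rnorm(64 * 2), 64, 2)
  v <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  x2 <- u %*% t(v)
  out2 <- denoise_patch(x2, 2L)
  expect_lt(max(abs(out2 - x2)), 1e-8)
})

test_that("recombination is the 1/(1+kept)-weighted convex average", {
  # two overlapping 2x2x2 patches along x with kept 0 and 1
  set.seed(36)
  a <- matrix(rnorm(8, 10), 8, 1)
  b <- matrix(rnorm(8, 20), 8, 1)
  patches <- list(
    list(values = a, origin = c(1L, 1L, 1L), N = 2L, kept = 0L,
         r_squared = 1),
    list(values = b, origin = c(2L, 1L, 1L), N = 2L, kept = 1L,
         r_squared = 0.5))
  res <- recombine(patches, c(3L, 2L, 2L), 1L)
  av <- array(a, c(2, 2, 2)); bv <- array(b, c(2, 2, 2))
  # overlap voxels x=2: weights 1 and 0.5
  expect_equal(res$data[2, , , 1],
               (1 * av[2, , ] + 0.5 * bv[1, , ]) / 1.5, tolerance = 1e-12)
  expect_equal(res$data[1, , , 1], av[1, , ], tolerance = 1e-12)
  expect_equal(res$data[3, , , 1], bv[2, , ], tolerance = 1e-12)
  expect_equal(res$dimension_map[2, 1, 1], (1 * 0 + 0.5 * 1) / 1.5,
               tolerance = 1e-12)
  expect_equal(res$fit_map[2, 1, 1], (1 * 1 + 0.5 * 0.5) / 1.5,
               tolerance = 1e-12)

  # convexity: every voxel between min and max of its contributors
  lo <- pmin(av[2, , ], bv[1, , ]); hi <- pmax(av[2, , ], bv[1, , ])
  expect_true(all(res$data[2, , , 1] >= lo - 1e-12 &
                    res$data[2, , , 1] <= hi + 1e-12))

  # identical constant patches recombine to that constant
  cpatches <- list(
    list(values = matrix(7, 8, 1), origin = c(1L, 1L, 1L), N = 2L,
         kept = 2L, r_squared = 1),
    list(values = matrix(7, 8, 1), origin = c(2L, 1L, 1L), N = 2L,
         kept = 0L, r_squared = 1))
  resc <- recombine(cpatches, c(3L, 2L, 2L), 1L)
  expect_equal(max(abs(resc$data - 7)), 0)

  # a gap in coverage is an error
  expect_error(recombine(patches[1], c(3L, 2L, 2L), 1L), "not covered")
})

test_that("denoise_stack is near-lossless on a noiseless low-rank stack and deterministic", {
  st <- make_rank_stack(c(12L, 12L, 12L), m = 10L, rank = 3L)
  res <- denoise_stack(st)
  rng <- diff(range(st$data))
  expect_lt(max(abs(res$denoised$data - st$data)), 1e-6 * rng)
  expect_true(all(res$dimension_map >= 0 & res$dimension_map <= 10))
  expect_true(all(res$fit_map >= 0 & res$fit_map <= 1))

  res2 <- denoise_stack(st)
  expect_identical(res$denoised$data, res2$denoised$data)

  expect_error(
    denoise_stack(contrast_stack(array(0, c(3, 8, 8, 2)))),
    "patch_size")
})

test_that("denoising reduces MSE to truth in every structure at SNR 10", {
  ph <- tiny_phantom(shape = c(20L, 20L, 20L), n_contrasts = 3L,
                     noise_sigma = 10, seed = 5L)
  pre <- preprocess_complex_set(ph$noisy)
  res <- denoise_stack(pre$stack)
  out <- restore_outputs(res$denoised, pre$global_phases)
  for (l in 1:2) {
    m <- ph$structure_masks == l
    for (c in 1:3) {
      mse_noisy <- mean((ph$noisy$magnitudes[[c]][m] -
                           ph$truth$magnitudes[[c]][m])^2)
      mse_den <- mean((out$magnitudes[[c]][m] -
                         ph$truth$magnitudes[[c]][m])^2)
      expect_lt(mse_den, mse_noisy)
    }
  }
})

test_that("lcpca_params validates its arguments", {
  expect_error(lcpca_params(alpha = 0), "alpha")
  expect_error(lcpca_params(patch_size = 4, stride = 5), "stride")
  expect_error(lcpca_params(fit_count = 1), "fit_count")
  p <- lcpca_params()
  expect_identical(p$patch_size, 4L)
  expect_equal(p$alpha, 0.05)
  expect_identical(p$stride, 2L)
})
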