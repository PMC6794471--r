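test_that("constant phase is unchanged by unwrapping", {
  ph <- array(0.3, c(6, 6, 6))
  expect_equal(unwrap_phase(ph), ph, tolerance = 1e-12)
})

test_that("a wrapped 6*pi ramp is recovered exactly up to the anchoring constant", {
  shape <- c(32L, 8L, 8L)
  truth <- ramp_phase(shape, total = 6 * pi)
  wrapped <- rewrap(truth)
  uw <- unwrap_phase(wrapped)
  err <- uw - truth
  err <- err - 2 * pi * round(median(err) / (2 * pi))
  expect_lt(max(abs(err)), 1e-6)
  # mod-2*pi consistency at every voxel
  expect_lt(max(abs(rewrap(uw) - wrapped)), 1e-9)
})

test_that("unwrapping a noisy ramp at SNR 10 leaves < 1% wrap errors", {
  set.seed(11)
  shape <- c(24L, 24L, 24L)
  truth <- ramp_phase(shape, total = 6 * pi)
  sigma <- 1 / 10
  re <- cos(truth) + sigma * rnorm(prod(shape))
  im <- sin(truth) + sigma * rnorm(prod(shape))
  mag <- array(sqrt(re^2 + im^2), shape)
  noisy <- array(rewrap(atan2(im, re)), shape)
  uw <- unwrap_phase(noisy, quality = mag)
  err <- uw - truth
  err <- err - 2 * pi * round(median(err) / (2 * pi))
  expect_lt(mean(abs(err) >= pi), 0.01)
})

test_that("an all-zero quality map falls back to unweighted unwrapping with a warning", {
  ph <- array(0.2, c(4, 4, 4))
  expect_warning(out <- unwrap_phase(ph, quality = array(0, c(4, 4, 4))),
                 "all-zero")
  expect_equal(out, ph, tolerance = 1e-12)
})

test_that("TV smoothing matches a brute-force ROF minimiser on a small grid", {
  set.seed(21)
  shape <- c(5L, 4L, 4L)
  f <- array(rnorm(prod(shape)), shape)
  w <- 0.3
  u <- tv_smooth(f, w, max_iter = 3000L, tol = 1e-9)
  u_bf <- brute_force_rof(f, w)
  # both minimise the same convex objective; compare objective values and
  # the minimisers themselves
  expect_lt(rof_objective(u, f, w),
            rof_objective(u_bf, f, w) + 1e-4)
  expect_lt(max(abs(u - u_bf)), 0.02)
})

test_that("splitting a constant volume returns it unchanged with zero residual", {
  f <- array(1.7, c(6, 6, 6))
  dec <- split_global_phase(f, tv_weight = 1)
  expect_equal(dec$global_phase, f, tolerance = 1e-6)
  expect_lt(max(abs(dec$residual_phase)), 1e-6)
})

test_that("a low-frequency ramp survives into the global phase under strong TV", {
  shape <- c(24L, 8L, 8L)
  f <- ramp_phase(shape, total = 2 * pi)  # smooth, ~1 cycle over 24 voxels
  dec <- split_global_phase(f, tv_weight = 0.5)
  interior <- dec$residual_phase[3:22, 3:6, 3:6]
  expect_lt(max(abs(interior)), 0.05)
})

test_that("a sharp localized phase bump concentrates in the residual", {
  shape <- c(24L, 16L, 16L)
  ramp <- ramp_phase(shape, total = pi / 16)  # gentle smooth background
  # a 3-voxel-cube bump below the TV flattening threshold
  # (weight * surface / volume = 0.5 * 2 = 1 rad) is rejected from the
  # smooth global phase; a steeper background ramp would couple into the
  # bump's x-faces and keep part of it global
  bump <- array(0, shape)
  bump[11:13, 7:9, 7:9] <- 0.5
  dec <- split_global_phase(ramp + bump, tv_weight = 0.5)
  bump_res <- dec$residual_phase[11:13, 7:9, 7:9]
  # >= 90% of the bump's energy must appear in the residual over its support
  expect_gt(sum(bump_res^2) / sum(bump^2), 0.9)
})

test_that("the phase decomposition is exactly additive", {
  set.seed(22)
  f <- array(rnorm(6^3), c(6, 6, 6))
  dec <- split_global_phase(f, tv_weight = 0.7)
  expect_equal(dec$global_phase + dec$residual_phase, dec$unwrapped,
               tolerance = 1e-12)
  expect_identical(dec$unwrapped, f)
})

test_that("build_complex_stack preserves magnitude and orders channels real/imag", {
  set.seed(23)
  shape <- c(6L, 6L, 6L)
  mags <- list(array(abs(rnorm(216, 100, 20)), shape),
               array(abs(rnorm(216, 80, 10)), shape))
  phs <- list(array(runif(216, -pi, pi - 0.01), shape),
              array(runif(216, -pi, pi - 0.01), shape))
  set <- complex_image_set(mags, phs)
  res <- lapply(1:2, function(c) array(rnorm(216, sd = 0.3), shape))
  st <- build_complex_stack(set, res)
  expect_identical(dim(st$data)[4], 4L)
  expect_identical(st$channel_labels,
                   c("contrast1_real", "contrast1_imag",
                     "contrast2_real", "contrast2_imag"))
  for (c in 1:2) {
    mod <- sqrt(st$data[, , , 2 * c - 1]^2 + st$data[, , , 2 * c]^2)
    expect_lt(max(abs(mod - mags[[c]]) / mags[[c]]), 1e-12)
  }
  # zero residual: real channel equals magnitude, imaginary is zero
  st0 <- build_complex_stack(set, lapply(1:2, function(c) array(0, shape)))
  expect_equal(st0$data[, , , 1], mags[[1]], tolerance = 1e-12)
  expect_equal(max(abs(st0$data[, , , 2])), 0)
})

test_that("preprocess -> restore with no denoising is the identity", {
  ph <- tiny_phantom(shape = c(12L, 12L, 12L), noise_sigma = 5)
  set <- ph$noisy
  pre <- preprocess_complex_set(set)
  out <- restore_outputs(pre$stack, pre$global_phases)
  nonzero <- set$magnitudes[[1]] > 0
  for (c in 1:set$n_contrasts) {
    expect_lt(max(abs(out$magnitudes[[c]] - set$magnitudes[[c]])), 1e-10)
    dphi <- rewrap(out$phases[[c]] - set$phases[[c]])
    expect_lt(max(abs(dphi[set$magnitudes[[c]] > 0])), 1e-10)
  }
})

test_that("restore_outputs rejects an odd channel count and recovers global phase when imag is zeroed", {
  shape <- c(4L, 4L, 4L)
  st_odd <- contrast_stack(array(1, c(shape, 3L)))
  expect_error(restore_outputs(st_odd, list(array(0, shape))), "odd")
  dat <- array(0, c(shape, 2L))
  dat[, , , 1] <- 2  # positive real channel, zero imaginary
  st <- contrast_stack(dat)
  gp <- array(0.8, shape)
  out <- restore_outputs(st, list(gp))
  expect_equal(out$phases[[1]], rewrap(gp), tolerance = 1e-12)
})

test_that("complex-route channels carry Gaussian noise of the input sigma", {
  # flat truth + complex Gaussian noise: once the global phase is removed,
  # the real and imaginary channels are Gaussian with the input sigma —
  # this is what makes the complex route statistically simple, in contrast
  # to the Rician magnitude
  set.seed(77)
  sigma <- 5
  a <- 100
  shape <- c(12L, 12L, 12L)
  nvox <- prod(shape)
  global <- ramp_phase(shape, total = 4 * pi)
  re <- a * cos(global) + sigma * rnorm(nvox)
  im <- a * sin(global) + sigma * rnorm(nvox)
  mag <- array(sqrt(re^2 + im^2), shape)
  phs <- array(rewrap(atan2(im, re)), shape)
  set <- complex_image_set(list(mag), list(phs))
  residual <- rewrap(phs - global)
  st <- build_complex_stack(set, list(residual))
  # real channel = a + rotated noise; imag channel = rotated noise
  for (chan in c(1L, 2L)) {
    vals <- as.vector(st$data[, , , chan])
    expect_lt(abs(sd(vals) - sigma) / sigma, 0.10)
    samp <- sample(vals, 500)
    expect_gt(shapiro.test(samp - mean(samp))$p.value, 0.01)
  }
  expect_lt(abs(mean(st$data[, , , 1]) - a), 0.5)
  expect_lt(abs(mean(st$data[, , , 2])), 0.5)
})
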