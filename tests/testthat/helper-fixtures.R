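# Fixtures are generated in code; nothing is stored on disk.

# Small phantom for fast end-to-end tests: 2 contrasts on a 16^3 grid.
tiny_phantom <- function(shape = c(16L, 16L, 16L), n_contrasts = 2L,
                         noise_sigma = 5, seed = 42L) {
  generate_phantom(phantom_spec(
    shape = shape, n_contrasts = n_contrasts,
    structures = list(
      list(name = "tissue", type = "box", center = c(0.5, 0.5, 0.5),
           half_width = c(0.38, 0.38, 0.38),
           intensities = rep(100, n_contrasts)),
      list(name = "core", type = "sphere", center = c(0.5, 0.5, 0.5),
           radius = 0.15, intensities = rep(150, n_contrasts))),
    noise_sigma = noise_sigma, seed = seed))
}

# Noiseless rank-r stack: r spatial patterns times channel weights, plus a
# constant offset per channel (removed by patch centering).
make_rank_stack <- function(shape, m, rank, seed = 7L, amplitude = 100) {
  set.seed(seed)
  nvox <- prod(shape)
  u <- qr.Q(qr(matrix(rnorm(nvox * rank), nvox, rank)))
  v <- qr.Q(qr(matrix(rnorm(m * rank), m, rank)))
  data <- amplitude * u %*% t(v)
  contrast_stack(array(data, c(shape, m)))
}

# Independent ROF oracle: direct minimisation of the discrete objective
# 0.5*sum((u-f)^2) + w*sum(|grad u|) with forward differences (the same
# discretisation tv_smooth targets), via BFGS on an epsilon-smoothed TV.
brute_force_rof <- function(f, weight, eps = 1e-9) {
  d <- dim(f)
  grad_terms <- function(u) {
    u <- array(u, d)
    gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
    n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
    if (n1 > 1) gx[1:(n1 - 1), , ] <- u[2:n1, , ] - u[1:(n1 - 1), , ]
    if (n2 > 1) gy[, 1:(n2 - 1), ] <- u[, 2:n2, ] - u[, 1:(n2 - 1), ]
    if (n3 > 1) gz[, , 1:(n3 - 1)] <- u[, , 2:n3] - u[, , 1:(n3 - 1)]
    list(gx = gx, gy = gy, gz = gz)
  }
  obj <- function(u) {
    g <- grad_terms(u)
    sum((u - as.vector(f))^2) / 2 +
      weight * sum(sqrt(g$gx^2 + g$gy^2 + g$gz^2 + eps))
  }
  fit <- optim(as.vector(f), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  array(fit$par, d)
}

rof_objective <- function(u, f, weight) {
  d <- dim(f)
  u <- array(u, d)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  if (n1 > 1) gx[1:(n1 - 1), , ] <- u[2:n1, , ] - u[1:(n1 - 1), , ]
  if (n2 > 1) gy[, 1:(n2 - 1), ] <- u[, 2:n2, ] - u[, 1:(n2 - 1), ]
  if (n3 > 1) gz[, , 1:(n3 - 1)] <- u[, , 2:n3] - u[, , 1:(n3 - 1)]
  sum((u - f)^2) / 2 + weight * sum(sqrt(gx^2 + gy^2 + gz^2))
}

# x-ramp phase volume covering `total` radians across the first axis.
ramp_phase <- function(shape, total = 6 * pi) {
  nx <- shape[1]
  x <- array(rep(seq(0, 1, length.out = nx), times = prod(shape[2:3])),
             shape)
  x * total
}
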