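test_that("transition points follow the competitor-over-weight rule", {
  # W_dh = 2 with best competitor product 4 -> P = 2
  W <- cbind(c(2), c(1))
  expect_equal(transition_points(y = 5, s = c(0, 4), W, h = 1), 2)
  # all competitors silent: P = 0 (the background is the competitor)
  expect_equal(transition_points(y = 5, s = c(0, 0), W, h = 1), 0)
  # unreachable pixel: P = +Inf
  W2 <- cbind(c(0, 1), c(1, 1))
  expect_equal(transition_points(c(1, 1), c(0, 2), W2, h = 1), c(Inf, 2))
  # negative competitor values are floored at the background
  expect_equal(transition_points(y = 5, s = c(0, -3), W, h = 1), 0)
})

test_that("piecewise structure: D reachable pixels give D+1 segments, continuous at boundaries", {
  set.seed(1)
  p <- model_params(matrix(c(1.5), 1, 1), sigma = 1, pi = 0.5, mu_pr = 1,
                    sigma_pr = 1, normalize = FALSE)
  pp <- build_segments(y = 2, s = 0, h = 1, p)
  expect_length(pp$boundaries, 1)  # D = 1: exactly 2 segments
  expect_length(pp$A, 2)
  for (i in 1:40) {
    inst <- random_instance()
    pp <- build_segments(inst$y, inst$s, inst$h, inst$params)
    expect_equal(length(pp$A), length(pp$boundaries) + 1)
    expect_true(all(diff(pp$boundaries) >= 0))
    expect_true(all(pp$A < 0))  # every segment a proper truncated Gaussian
    # log-density continuity at every interior boundary
    for (j in seq_along(pp$boundaries)) {
      b <- pp$boundaries[j]
      left <- pp$A[j] * b^2 + pp$B[j] * b + pp$C[j]
      right <- pp$A[j + 1] * b^2 + pp$B[j + 1] * b + pp$C[j + 1]
      expect_lt(abs(left - right), 1e-8 * max(1, abs(left)))
    }
  }
})

test_that("assembled conditional matches the brute-force density on a grid", {
  set.seed(2)
  for (i in 1:60) {
    inst <- random_instance()
    pp <- add_spike_and_normalize(
      build_segments(inst$y, inst$s, inst$h, inst$params), inst$pi)
    grid <- seq(inst$mu_pr - 6 * inst$sigma_pr, inst$mu_pr + 8, length.out = 2001)
    ref <- oracle_cond_logdens(grid, inst$y, inst$s, inst$h, inst$W,
                               inst$sigma, inst$pi, inst$mu_pr, inst$sigma_pr)
    got <- piecewise_logdensity(pp, grid)
    dif <- got - ref
    # identical shape up to one additive constant (the omitted per-pixel
    # Gaussian normalizers)
    expect_lt(max(dif) - min(dif), 1e-8)
  }
})

test_that("spike mass and normalization match numeric integration", {
  set.seed(3)
  for (i in 1:100) {
    inst <- random_instance()
    pp <- add_spike_and_normalize(
      build_segments(inst$y, inst$s, inst$h, inst$params), inst$pi)
    total <- exp(pp$spike_log_mass - pp$log_norm) +
      sum(exp(pp$log_masses - pp$log_norm))
    expect_lt(abs(total - 1), 1e-9)
    ref <- oracle_spike_prob(inst$y, inst$s, inst$h, inst$W, inst$sigma,
                             inst$pi, inst$mu_pr, inst$sigma_pr)
    expect_lt(abs(exp(pp$spike_log_mass - pp$log_norm) - ref), 1e-6)
  }
  # flat likelihood (latent reaches no pixel): prior is recovered
  W <- cbind(c(0, 0), c(1, 1))
  p <- model_params(W, 1, pi = 0.3, mu_pr = 1, sigma_pr = 1, normalize = FALSE)
  pp <- add_spike_and_normalize(build_segments(c(1, 2), c(0, 1), 1, p), 0.3)
  expect_equal(exp(pp$spike_log_mass - pp$log_norm), 0.7, tolerance = 1e-12)
})

test_that("inverse transform returns exact zeros in the spike and slab quantiles otherwise", {
  # latent reaching no pixels, pi = 1: pure slab quantile function
  W <- matrix(0, 2, 1)
  p <- model_params(W, 1, pi = 1, mu_pr = 0.5, sigma_pr = 2,
                    normalize = FALSE)
  suppressWarnings(
    pp <- add_spike_and_normalize(build_segments(c(1, 2), 0, 1, p), 1))
  for (u in c(0.01, 0.3, 0.5, 0.9, 0.999))
    expect_equal(inverse_transform_sample(pp, u), qnorm(u, 0.5, 2),
                 tolerance = 1e-9)
  # pi = 0: every draw is the exact zero of the spike
  p0 <- model_params(matrix(1, 2, 1), 1, pi = 0, mu_pr = 1, sigma_pr = 1,
                     normalize = FALSE)
  pp0 <- add_spike_and_normalize(build_segments(c(1, 2), 0, 1, p0), 0)
  expect_identical(inverse_transform_sample(pp0, c(0.1, 0.5, 0.9)),
                   c(0, 0, 0))
  expect_error(inverse_transform_sample(pp0, 1.5))
})

test_that("draws reproduce the numerically integrated CDF (KS)", {
  set.seed(4)
  inst <- random_instance(D = 5, H = 3)
  pp <- add_spike_and_normalize(
    build_segments(inst$y, inst$s, inst$h, inst$params), inst$pi)
  x <- inverse_transform_sample(pp, runif(2e4))
  orc <- oracle_cond_grid(inst$y, inst$s, inst$h, inst$W, inst$sigma,
                          inst$pi, inst$mu_pr, inst$sigma_pr)
  Femp <- ecdf(x)
  ks <- max(abs(Femp(orc$grid) - orc$cdf))
  expect_lt(ks, 0.015)
  expect_equal(mean(x == 0), orc$p_spike, tolerance = 0.02)
})

test_that("Gibbs chain marginals match grid posteriors on small problems", {
  set.seed(5)
  # single-latent problem: chain marginal vs numerically integrated posterior
  inst <- random_instance(D = 4, H = 1)
  inst$s <- 0
  p <- inst$params
  sw <- gibbs_sweep(inst$y, selected = 1, p, n_samples = 6000, seed = 6)
  x <- sw$samples[-sw$burn_in, 1]
  orc <- oracle_cond_grid(inst$y, rep(0, 1), 1, inst$W, inst$sigma, inst$pi,
                          inst$mu_pr, inst$sigma_pr)
  ks <- max(abs(ecdf(x)(orc$grid) - orc$cdf))
  expect_lt(ks, 0.02)

  # D = 4, H = 2 joint: pooled post-burn-in marginals vs 2-D grid
  inst2 <- random_instance(D = 4, H = 2, allow_zero_w = FALSE)
  p2 <- inst2$params
  sw2 <- gibbs_sweep(inst2$y, selected = 1:2, p2, n_samples = 15000, seed = 7)
  smp <- sw2$samples[-sw2$burn_in, ]
  gr <- seq(p2$mu_pr - 8 * p2$sigma_pr, p2$mu_pr + 8 * p2$sigma_pr,
            length.out = 241)
  joint_at <- function(v1, v2) {
    s <- c(v1, v2)
    exp(oracle_loglik_y(inst2$y, s, p2$W, p2$sigma)) *
      prod(ifelse(s == 0, 1 - p2$pi,
                  p2$pi * dnorm(s, p2$mu_pr, p2$sigma_pr)))
  }
  dx <- gr[2] - gr[1]
  M <- outer(gr, gr, Vectorize(joint_at)) * dx * dx      # slab-slab
  v1 <- vapply(gr, function(v) joint_at(v, 0), numeric(1)) * dx  # slab-spike
  v2 <- vapply(gr, function(v) joint_at(0, v), numeric(1)) * dx
  p00 <- joint_at(0, 0)
  Z <- sum(M) + sum(v1) + sum(v2) + p00
  for (h in 1:2) {
    marg_slab <- if (h == 1) rowSums(M) + v1 else colSums(M) + v2
    spike_mass <- (if (h == 1) sum(v2) else sum(v1)) + p00
    cdf <- (cumsum(marg_slab) - marg_slab / 2 + spike_mass * (gr >= 0)) / Z
    ks_h <- max(abs(ecdf(smp[, h])(gr) - cdf))
    expect_lt(ks_h, 0.03)
  }
})

test_that("degenerate and invariance properties of the sweep", {
  d <- generate_bars(N = 3, seed = 8)
  p <- model_params(d$W_true, 2, 0.2, 2, 0.5, normalize = FALSE)
  # pi = 0: all samples identically zero
  p0 <- p; p0$pi <- 0
  sw <- gibbs_sweep(d$Y[1, ], 1:10, p0, n_samples = 9, seed = 9)
  expect_true(all(sw$samples == 0))
  # relabeling pixels leaves the sampled trajectory identical
  perm <- sample(25)
  p_perm <- model_params(p$W[perm, ], 2, 0.2, 2, 0.5, normalize = FALSE)
  a <- gibbs_sweep(d$Y[2, ], 1:10, p, n_samples = 15, seed = 10)
  b <- gibbs_sweep(d$Y[2, perm], 1:10, p_perm, n_samples = 15, seed = 10)
  expect_equal(a$samples, b$samples, tolerance = 1e-9)
  expect_error(gibbs_sweep(d$Y[1, ], integer(0), p, n_samples = 5))
})
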