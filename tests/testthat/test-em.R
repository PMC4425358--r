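test_that("M-step updates reproduce their definitional examples", {
  # single event with s = 2, y_d = 6: ratio estimator gives 12/4 = 3
  W <- matrix(1, 1, 1)
  samples <- list(matrix(2, 1, 1))
  st <- accumulate_stats(samples, Y = matrix(6, 1, 1), W)
  expect_equal(st$star_sy[1, 1], 12)
  expect_equal(st$star_ss[1, 1], 4)
  expect_equal(st$star_sy[1, 1] / st$star_ss[1, 1], 3)
  # N = D = K = 1, rendered value 1, y = 3: sigma = |1 - 3| = 2
  st_s <- accumulate_stats(list(matrix(1, 1, 1)), Y = matrix(3, 1, 1), W)
  expect_equal(mstep_sigma(st_s), 2)
  # all-zero samples: no latent events, residual is sum of y^2
  st0 <- accumulate_stats(list(matrix(0, 1, 1)), matrix(c(3, 0), 1, 2),
                          matrix(1, 2, 1))
  expect_equal(sum(st0$star_count), 0)
  expect_equal(st0$star_sq_resid, 9)
  expect_equal(mstep_pi(st0), 1e-4)  # clamp floor at the degenerate zero
  # nonzero values {1, 3}: slab mean 2, sd 1
  stp <- accumulate_stats(list(matrix(c(1, 3), 2, 1)),
                          matrix(0, 1, 1), matrix(1, 1, 1))
  pr <- mstep_prior(stp, 0, 0.1)
  expect_equal(pr$mu_pr, 2)
  expect_equal(pr$sigma_pr, 1)
  # frozen slab: sigma_pr untouched
  prf <- mstep_prior(stp, 0, 0.25, fix_sigma_pr = TRUE)
  expect_equal(prf$sigma_pr, 0.25)
  # every sample has 2 of 10 active: pi = 0.2
  s10 <- matrix(0, 3, 10); s10[, 1:2] <- 1
  stpi <- accumulate_stats(list(s10), matrix(0, 1, 10), matrix(1, 10, 10))
  expect_equal(mstep_pi(stpi), 0.2)
})

test_that("accumulators and M-steps equal naive nested-loop oracles to 1e-12", {
  set.seed(1)
  for (i in 1:20) {
    N <- sample(2:5, 1); D <- sample(2:6, 1); H <- sample(2:4, 1); K <- sample(2:4, 1)
    W <- matrix(runif(D * H, 0, 2), D, H)
    W[runif(D * H) < 0.2] <- 0
    for (h in seq_len(H))                  # keep columns normalizable
      if (all(W[, h] == 0)) W[sample(D, 1), h] <- 1
    Y <- matrix(rnorm(N * D, 2, 1), N, D)
    samples <- lapply(seq_len(N), function(n) {
      m <- matrix(rnorm(K * H, 1, 1), K, H)
      m[runif(K * H) < 0.5] <- 0
      m
    })
    st <- accumulate_stats(samples, Y, W)
    ref <- oracle_stats(samples, Y, W)
    expect_lt(max(abs(st$star_sy - ref$star_sy)), 1e-12)
    expect_lt(max(abs(st$star_ss - ref$star_ss)), 1e-12)
    expect_equal(st$star_count, ref$star_count)
    expect_lt(abs(st$star_sq_resid - ref$star_sq_resid), 1e-10)
    expect_lt(max(abs(st$dstar_sum - ref$dstar_sum)), 1e-12)
    expect_lt(abs(st$active_sum - ref$active_sum), 1e-12)
    # full update chain against the naive implementation
    upd <- oracle_msteps(samples, Y, W)
    expect_equal(mstep_sigma(st), upd$sigma, tolerance = 1e-12)
    expect_equal(suppressWarnings(mstep_W(st, W)), upd$W, tolerance = 1e-12)
    expect_equal(mstep_pi(st), upd$pi, tolerance = 1e-12)
    pr <- mstep_prior(st, 0, 1)
    expect_equal(pr$mu_pr, upd$mu_pr, tolerance = 1e-12)
    expect_equal(pr$sigma_pr, upd$sigma_pr, tolerance = 1e-12)
  }
})

test_that("compiled E-step accumulation agrees with the R accumulator on its own samples", {
  d <- generate_bars(N = 30, seed = 2)
  p <- model_params(d$W_true, 2, 0.2, 2, 0.5, normalize = FALSE)
  st <- estep(d$Y, p, H_prime = 6, n_random = 1, K = 9, seed = 3,
              return_samples = TRUE)
  ref <- accumulate_stats(st$samples, d$Y, p$W)
  expect_lt(max(abs(st$star_sy - ref$star_sy)), 1e-9)
  expect_lt(max(abs(st$star_ss - ref$star_ss)), 1e-9)
  expect_equal(st$star_count, ref$star_count)
  expect_lt(abs(st$star_sq_resid - ref$star_sq_resid), 1e-7)
  expect_lt(max(abs(st$dstar_sum - ref$dstar_sum)), 1e-9)
  expect_lt(abs(st$active_sum - ref$active_sum), 1e-9)
})

test_that("argmax ties credit the lowest latent index", {
  # two identical columns, one sample with both latents at the same value
  W <- matrix(1, 2, 2)
  samples <- list(matrix(c(1.5, 1.5), 1, 2))
  st <- accumulate_stats(samples, matrix(1, 1, 2), W)
  expect_equal(st$star_count[, 1], c(1, 1))
  expect_equal(st$star_count[, 2], c(0, 0))
  ref <- oracle_stats(samples, matrix(1, 1, 2), W)
  expect_equal(st$star_count, ref$star_count)
})

test_that("dictionary update keeps zero-evidence entries and renormalizes", {
  st <- accumulate_stats(list(matrix(c(2, 0), 1, 2)),
                         matrix(6, 1, 1), matrix(c(1, 1), 1, 2))
  W_prev <- matrix(c(1, 1), 1, 2)
  expect_warning(W_new <- mstep_W(st, W_prev))
  expect_equal(dim(W_new), c(1, 2))
  expect_equal(colSums(W_new), c(1, 1), tolerance = 1e-9)
})

test_that("initialization follows the data-moments scheme deterministically", {
  set.seed(4)
  Y <- matrix(rnorm(500, 5, 2), 50, 10)
  p <- initialize_params(Y, H = 4, seed = 5)
  expect_equal(p$mu_pr, mean(Y))
  expect_equal(p$sigma, sd(as.vector(Y)))
  expect_equal(p$sigma_pr, p$sigma)
  expect_equal(colSums(p$W), rep(10, 4), tolerance = 1e-9)
  expect_true(all(p$W >= 0))
  p2 <- initialize_params(Y, H = 4, seed = 5)
  expect_identical(p$W, p2$W)
})

test_that("noise-free single-cause data is fit in one EM step", {
  # one latent, one data point: the ratio estimator lands on the generating
  # column (up to normalization) immediately
  set.seed(6)
  w <- runif(9, 0.5, 2)
  W_true <- matrix(w * 9 / sum(w), 9, 1)
  y <- 2.5 * W_true[, 1]
  p <- model_params(matrix(runif(9, 0.5, 2), 9, 1), sigma = 0.05, pi = 0.9,
                    mu_pr = 2.5, sigma_pr = 0.3)
  st <- estep(matrix(y, 1), p, K = 30, seed = 7)
  W_new <- mstep_W(st, p$W)
  expect_gt(sum(W_new * W_true) / sqrt(sum(W_new^2) * sum(W_true^2)), 0.999)
})

test_that("fits are reproducible and resumable bit-for-bit", {
  d <- generate_bars(N = 60, seed = 8)
  f1 <- fit_ssmca(d, H = 10, H_prime = 5, n_random = 1, K = 6, n_iter = 4,
                  seed = 9)
  f2 <- fit_ssmca(d, H = 10, H_prime = 5, n_random = 1, K = 6, n_iter = 4,
                  seed = 9)
  expect_identical(f1$params$W, f2$params$W)
  expect_identical(f1$trajectory, f2$trajectory)
  # resume: stop after 2 iterations, continue to 4, same endpoint
  fa <- fit_ssmca(d, H = 10, H_prime = 5, n_random = 1, K = 6, n_iter = 2,
                  seed = 9)
  fb <- fit_ssmca(d, H = 10, H_prime = 5, n_random = 1, K = 6, n_iter = 4,
                  seed = 9, init = fa$params, start_iter = 3L)
  expect_equal(fb$params$W, f1$params$W, tolerance = 1e-12)
  expect_equal(fb$params$sigma, f1$params$sigma, tolerance = 1e-12)
})

test_that("ssmca_fix freezes the slab width across iterations", {
  d <- generate_bars(N = 40, seed = 10)
  f <- fit_ssmca(d, H = 10, H_prime = 5, K = 6, n_iter = 3,
                 mode = "ssmca_fix", sigma_pr_fixed = 0.25, seed = 11)
  expect_true(all(f$trajectory$sigma_pr == 0.25))
})
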