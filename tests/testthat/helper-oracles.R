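# Independent brute-force oracles used across the suite.  These never call
# the package's piecewise machinery: densities are evaluated directly from
# the generative model definition.

# floored max-superposition renderer (reference implementation)
oracle_render <- function(s, W) {
  r <- rep(0, nrow(W))
  for (h in seq_along(s)) r <- pmax(r, s[h] * W[, h])
  r
}

# log p(y | s) from per-pixel Gaussian densities
oracle_loglik_y <- function(y, s, W, sigma) {
  sum(dnorm(y, oracle_render(s, W), sigma, log = TRUE))
}

# unnormalized log conditional density of latent h on the slab side
oracle_cond_logdens <- function(v, y, s, h, W, sigma, pi, mu_pr, sigma_pr) {
  vapply(v, function(vi) {
    s2 <- s
    s2[h] <- vi
    oracle_loglik_y(y, s2, W, sigma) +
      dnorm(vi, mu_pr, sigma_pr, log = TRUE) + log(pi)
  }, numeric(1))
}

# spike probability and normalized grid CDF of the conditional, by
# high-resolution numeric integration (Simpson's rule)
oracle_cond_grid <- function(y, s, h, W, sigma, pi, mu_pr, sigma_pr,
                             lo = NULL, hi = NULL, n_grid = 40001) {
  if (is.null(lo)) lo <- mu_pr - 12 * sigma_pr
  if (is.null(hi)) {
    hi <- mu_pr + 12 * sigma_pr
    wh <- W[, h]
    if (any(wh > 0)) hi <- max(hi, max((abs(y) + 8 * sigma)[wh > 0] / wh[wh > 0]))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  ld <- oracle_cond_logdens(grid, y, s, h, W, sigma, pi, mu_pr, sigma_pr)
  off <- max(ld)
  dens <- exp(ld - off)
  dx <- grid[2] - grid[1]
  wts <- rep(c(2, 4), length.out = n_grid); wts[1] <- wts[n_grid] <- 1
  slab_mass <- sum(wts * dens) * dx / 3
  s0 <- s; s0[h] <- 0
  spike <- exp(oracle_loglik_y(y, s0, W, sigma) + log(1 - pi) - off)
  total <- slab_mass + spike
  cdf <- (cumsum(dens) - dens / 2) * dx
  cdf <- (cdf + spike * (grid >= 0)) / total
  list(grid = grid, logdens = ld, p_spike = spike / total, cdf = cdf)
}

# spike probability by adaptive quadrature of the slab side (independent of
# the package's segment algebra)
oracle_spike_prob <- function(y, s, h, W, sigma, pi, mu_pr, sigma_pr) {
  s0 <- s; s0[h] <- 0
  off <- oracle_loglik_y(y, s0, W, sigma)
  f <- function(v)
    exp(oracle_cond_logdens(v, y, s, h, W, sigma, pi, mu_pr, sigma_pr) - off)
  lim <- mu_pr + c(-1, 1) * 15 * sigma_pr
  wh <- W[, h]
  if (any(wh > 0)) lim[2] <- max(lim[2], max((abs(y) + 10 * sigma)[wh > 0] / wh[wh > 0]))
  # localize the slab mass first; integrate() struggles with a narrow peak
  # inside a wide interval
  cg <- seq(lim[1], lim[2], length.out = 4001)
  ld <- oracle_cond_logdens(cg, y, s, h, W, sigma, pi, mu_pr, sigma_pr) - off
  keep <- range(cg[ld > max(ld) - 60])
  pad <- diff(keep) * 0.02 + (cg[2] - cg[1])
  win <- c(max(lim[1], keep[1] - pad), min(lim[2], keep[2] + pad))
  slab <- tryCatch(
    integrate(f, win[1], win[2], rel.tol = 1e-10,
              subdivisions = 2000L)$value,
    error = function(e) {
      g <- seq(win[1], win[2], length.out = 100001)
      w <- rep(c(2, 4), length.out = 100001); w[1] <- w[100001] <- 1
      sum(w * f(g)) * (g[2] - g[1]) / 3
    })
  spike <- 1 - pi
  spike / (spike + slab)
}

# random small model instance for property-style sweeps
random_instance <- function(D = NULL, H = NULL, allow_zero_w = TRUE) {
  if (is.null(D)) D <- sample(1:8, 1)
  if (is.null(H)) H <- sample(1:4, 1)
  W <- matrix(runif(D * H, 0, 3), D, H)
  if (allow_zero_w) W[runif(D * H) < 0.25] <- 0
  sigma <- runif(1, 0.3, 2)
  pi <- runif(1, 0.05, 0.9)
  mu_pr <- runif(1, -0.5, 2.5)
  sigma_pr <- runif(1, 0.2, 1.5)
  s <- ifelse(runif(H) < 0.5, 0, rnorm(H, mu_pr, sigma_pr))
  h <- sample(H, 1)
  y <- abs(rnorm(D, 2, 2))
  list(D = D, H = H, W = W, sigma = sigma, pi = pi, mu_pr = mu_pr,
       sigma_pr = sigma_pr, s = s, h = h, y = y,
       params = model_params(W, sigma, pi, mu_pr, sigma_pr,
                             normalize = FALSE))
}

# naive triple-loop sufficient statistics (reference for the accumulators)
oracle_stats <- function(samples, Y, W) {
  N <- nrow(Y); D <- nrow(W); H <- ncol(W)
  star_sy <- matrix(0, D, H); star_ss <- matrix(0, D, H)
  star_count <- matrix(0, D, H)
  dsum <- numeric(H); dsumsq <- numeric(H); dcount <- numeric(H)
  resid <- 0; active_sum <- 0
  for (n in seq_len(N)) {
    for (k in seq_len(nrow(samples[[n]]))) {
      s <- samples[[n]][k, ]
      for (d in seq_len(D)) {
        best <- 0; bh <- 0
        for (h in seq_len(H)) {
          v <- s[h] * W[d, h]
          if (v > best) { best <- v; bh <- h }
        }
        resid <- resid + (best - Y[n, d])^2
        if (bh > 0) {
          star_sy[d, bh] <- star_sy[d, bh] + s[bh] * Y[n, d]
          star_ss[d, bh] <- star_ss[d, bh] + s[bh]^2
          star_count[d, bh] <- star_count[d, bh] + 1
        }
      }
      nact <- 0
      for (h in seq_len(H)) {
        if (s[h] != 0) {
          nact <- nact + 1
          dsum[h] <- dsum[h] + s[h]
          dsumsq[h] <- dsumsq[h] + s[h]^2
          dcount[h] <- dcount[h] + 1
        }
      }
      active_sum <- active_sum + nact / H
    }
  }
  list(star_sy = star_sy, star_ss = star_ss, star_count = star_count,
       star_sq_resid = resid, dstar_sum = dsum, dstar_sumsq = dsumsq,
       dstar_count = dcount, active_sum = active_sum)
}

# naive M-step updates straight from the update-equation definitions
oracle_msteps <- function(samples, Y, W_prev, floor = 1e-4) {
  st <- oracle_stats(samples, Y, W_prev)
  N <- nrow(Y); D <- nrow(W_prev); H <- ncol(W_prev)
  K <- nrow(samples[[1]])
  sigma <- sqrt(st$star_sq_resid / (N * D * K))
  W <- W_prev
  for (d in seq_len(D)) for (h in seq_len(H))
    if (st$star_count[d, h] > 0)
      W[d, h] <- st$star_sy[d, h] / st$star_ss[d, h]
  W[W < floor] <- floor
  W <- sweep(W, 2, D / colSums(W), "*")
  pi_hat <- st$active_sum / (N * K)
  nz <- unlist(lapply(samples, function(m) m[m != 0]))
  list(sigma = sigma, W = W, pi = pi_hat, mu_pr = mean(nz),
       sigma_pr = sqrt(mean((nz - mean(nz))^2)))
}
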