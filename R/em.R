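#' Accumulate M-step sufficient statistics from posterior samples
#'
#' Implements the two restricted expectations feeding the closed-form
#' updates: the max-restricted sums (a pixel event is credited to the latent
#' attaining the maximum `s_h W_dh` there, ties to the lowest index; pixels
#' whose maximum is the silent background credit no latent but still
#' contribute to the residual) and the nonzero-restricted sums over all
#' active latents. Also tracks the per-sample fraction of active latents
#' (the estimator of the spike probability).
#'
#' @param samples list of `K x H` post-burn-in sample matrices, one per data
#'   point.
#' @param Y `N x D` observations (rows aligned with `samples`).
#' @param W current dictionary.
#' @return object of class `ssmca_stats`.
#' @export
accumulate_stats <- function(samples, Y, W) {
  N <- nrow(Y); D <- nrow(W); H <- ncol(W)
  if (length(samples) != N) stop("one sample matrix per data point required")
  star_sy <- matrix(0, D, H); star_ss <- matrix(0, D, H)
  star_count <- matrix(0, D, H)
  dsum <- numeric(H); dsumsq <- numeric(H); dcount <- numeric(H)
  resid <- 0; active_sum <- 0; k_used <- nrow(samples[[1]])
  for (n in seq_len(N)) {
    smp <- samples[[n]]
    if (nrow(smp) == 0) stop("no post-burn-in samples for data point ", n)
    for (k in seq_len(nrow(smp))) {
      s <- smp[k, ]
      prod <- W * rep(s, each = D)           # D x H products
      r <- pmax(0, do.call(pmax, asplit(prod, 2)))
      amax <- max.col(cbind(0, prod), ties.method = "first") - 1L
      hit <- r > 0
      resid <- resid + sum((r - Y[n, ])^2)
      for (d in which(hit)) {
        hh <- amax[d]
        star_sy[d, hh] <- star_sy[d, hh] + s[hh] * Y[n, d]
        star_ss[d, hh] <- star_ss[d, hh] + s[hh]^2
        star_count[d, hh] <- star_count[d, hh] + 1
      }
      act <- which(s != 0)
      dsum[act] <- dsum[act] + s[act]
      dsumsq[act] <- dsumsq[act] + s[act]^2
      dcount[act] <- dcount[act] + 1
      active_sum <- active_sum + length(act) / H
    }
  }
  structure(list(star_sy = star_sy, star_ss = star_ss,
                 star_count = star_count, star_sq_resid = resid,
                 dstar_sum = dsum, dstar_sumsq = dsumsq,
                 dstar_count = dcount, active_sum = active_sum,
                 n_data = N, n_dim = D, n_latent = H, k_used = k_used,
                 mean_joint_loglik = NA_real_),
            class = "ssmca_stats")
}

#' Noise update: root mean squared reconstruction residual
#'
#' `sigma_hat^2` is the average squared difference between the rendered
#' samples and the data over all data points, pixels and samples.
#'
#' @param stats an `ssmca_stats` object.
#' @return updated sigma (standard deviation).
#' @export
mstep_sigma <- function(stats) {
  denom <- stats$n_data * stats$n_dim * stats$k_used
  if (denom <= 0) stop("empty sufficient statistics")
  sqrt(stats$star_sq_resid / denom)
}

#' Dictionary update: per-entry ratio estimator
#'
#' `W_dh = sum(s_h y_d) / sum(s_h^2)` over the events where latent `h` is
#' the maximal cause at pixel `d`. Entries with no such events keep their
#' previous value; negative estimates are clipped to `floor`; columns are
#' renormalized to sum to `D`.
#'
#' A small positive `floor` matters: an entry at exactly zero is absorbing
#' (a latent with `W_dh = 0` can never attain the maximum at pixel `d`, so
#' it never collects evidence there again), which can permanently lock a
#' dictionary column out of pixels it needs. With a tiny positive value the
#' latent still wins the pixel whenever no other cause covers it, and the
#' entry can regrow.
#'
#' @param stats an `ssmca_stats` object.
#' @param W_prev previous dictionary (source of zero-evidence entries).
#' @param floor smallest representable dictionary entry.
#' @return updated dictionary.
#' @export
mstep_W <- function(stats, W_prev, floor = 1e-4) {
  W <- W_prev
  ev <- stats$star_count > 0
  W[ev] <- stats$star_sy[ev] / stats$star_ss[ev]
  W[W < floor] <- floor
  dead <- colSums(stats$star_count) == 0
  if (any(dead))
    warning(sum(dead), " dictionary column(s) received no evidence this iteration")
  normalize_dictionary(W)
}

#' Spike-probability update: mean fraction of active latents per sample
#'
#' @param stats an `ssmca_stats` object.
#' @return updated pi, clamped away from the degenerate endpoints so the
#'   sampler's spike/slab mixture stays proper.
#' @export
mstep_pi <- function(stats) {
  total <- stats$n_data * stats$k_used
  if (total <= 0) stop("empty sufficient statistics")
  min(max(stats$active_sum / total, 1e-4), 1 - 1e-4)
}

#' Slab update: moments of the pooled nonzero latent values
#'
#' Mean and standard deviation over every nonzero sampled latent value
#' (pooled across data points, samples and latents). In `ssmca_fix` mode
#' the slab width is frozen and only the mean is updated.
#'
#' @param stats an `ssmca_stats` object.
#' @param mu_prev,sigma_prev previous values (returned when no latent was
#'   active in any sample).
#' @param fix_sigma_pr if `TRUE`, return `sigma_prev` unchanged.
#' @return list with `mu_pr` and `sigma_pr`.
#' @export
mstep_prior <- function(stats, mu_prev, sigma_prev, fix_sigma_pr = FALSE) {
  n <- sum(stats$dstar_count)
  if (n == 0) {
    warning("no nonzero latent events; slab parameters unchanged")
    return(list(mu_pr = mu_prev, sigma_pr = sigma_prev))
  }
  mu <- sum(stats$dstar_sum) / n
  if (fix_sigma_pr) return(list(mu_pr = mu, sigma_pr = sigma_prev))
  v <- sum(stats$dstar_sumsq) / n - mu^2
  list(mu_pr = mu, sigma_pr = max(sqrt(max(v, 0)), 1e-6))
}

#' Data-driven parameter initialization
#'
#' Slab and noise sd start at the observed data standard deviation, the slab
#' mean at the data mean, and every dictionary column at the per-pixel data
#' mean plus Gaussian noise of the same sd (clipped to a small positive
#' floor, normalized to sum `D`). The spike probability starts at
#' `1 / H_prime` — one selected cause per patch until the data say
#' otherwise; large starting values (every latent half-on) reliably produce
#' entangled mixture columns on benchmark data.
#'
#' @param Y `N x D` data matrix.
#' @param H number of latents.
#' @param H_prime preselection size used to set the initial pi.
#' @param floor smallest dictionary entry (see [mstep_W()]).
#' @param seed integer seed.
#' @return an [model_params()] object.
#' @export
initialize_params <- function(Y, H, H_prime = H, floor = 1e-4, seed = NULL) {
  if (nrow(Y) < 2) stop("need at least two data points")
  m <- colMeans(Y)
  s <- max(sd(as.vector(Y)), 1e-3)
  with_seed(seed, {
    W <- matrix(m, ncol(Y), H) + matrix(rnorm(ncol(Y) * H, 0, s), ncol(Y), H)
    W[W < floor] <- floor
    model_params(W, sigma = s, pi = 1 / H_prime, mu_pr = mean(Y),
                 sigma_pr = s)
  })
}

#' Fit the nonlinear spike-and-slab model by truncated EM
#'
#' Per iteration and data point: score latents by cosine similarity, select
#' the `H_prime` most relevant (plus `n_random` random extras), run `K`
#' systematic-scan Gibbs sweeps over the exact conditionals (first third
#' burn-in), accumulate the restricted expectations, then apply the
#' closed-form updates in the order noise, dictionary (with column
#' renormalization), spike probability, slab. Every data point uses its own
#' counter-based RNG stream derived from `(seed, iteration, index)`, so
#' results do not depend on execution order and a run can be resumed from a
#' checkpoint bit-for-bit.
#'
#' @param data an `ssmca_databatch` or an `N x D` matrix.
#' @param H number of dictionary elements to learn.
#' @param H_prime preselection size (`H_prime = H` disables truncation).
#' @param n_random random slots among the `H_prime` selected.
#' @param K Gibbs samples per data point per iteration (`>= 3`).
#' @param n_iter EM iterations.
#' @param mode `"ssmca"` learns the slab width; `"ssmca_fix"` freezes it at
#'   `sigma_pr_fixed` (narrow slab approximates a binary prior).
#' @param sigma_pr_fixed frozen slab sd for `ssmca_fix` mode.
#' @param w_floor smallest dictionary entry (see [mstep_W()]).
#' @param seed master seed; also governs initialization.
#' @param init optional `ssmca_params` to start from (overrides the default
#'   initialization; used when resuming).
#' @param start_iter first iteration number (used when resuming).
#' @param verbose print per-iteration parameter values.
#' @return object of class `ssmca_fit`: final `params`, per-iteration
#'   `trajectory` data frame (sigma, pi, pi*H, mu_pr, sigma_pr, mean joint
#'   log-likelihood of the post-burn-in samples), the initialization and the
#'   configuration.
#' @export
fit_ssmca <- function(data, H, H_prime = H, n_random = 0, K = 30,
                      n_iter = 30, mode = c("ssmca", "ssmca_fix"),
                      sigma_pr_fixed = 0.25, w_floor = 1e-4, seed = 1,
                      init = NULL, start_iter = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  Y <- if (inherits(data, "ssmca_databatch")) data$Y else as.matrix(data)
  if (K < 3) stop("K must be at least 3 to leave post-burn-in samples")
  if (n_iter < start_iter - 1) stop("nothing to do")
  params <- if (is.null(init))
    initialize_params(Y, H, H_prime, floor = w_floor,
                      seed = derive_seed(seed, 0))
  else init
  if (mode == "ssmca_fix" && is.null(init))
    params$sigma_pr <- sigma_pr_fixed
  traj <- vector("list", n_iter - start_iter + 1)
  for (it in seq(start_iter, length.out = n_iter - start_iter + 1)) {
    stats <- estep_batch_cpp(Y, params$W, params$sigma, params$pi,
                             params$mu_pr, params$sigma_pr, H_prime, n_random,
                             K, seed, it)
    class(stats) <- "ssmca_stats"
    params$sigma <- max(mstep_sigma(stats), 1e-6)
    params$W <- mstep_W(stats, params$W, floor = w_floor)
    params$pi <- mstep_pi(stats)
    pr <- mstep_prior(stats, params$mu_pr, params$sigma_pr,
                      fix_sigma_pr = (mode == "ssmca_fix"))
    params$mu_pr <- pr$mu_pr
    params$sigma_pr <- pr$sigma_pr
    traj[[it - start_iter + 1]] <- data.frame(
      iter = it, sigma = params$sigma, pi = params$pi,
      pi_H = params$pi * H, mu_pr = params$mu_pr,
      sigma_pr = params$sigma_pr,
      mean_joint_loglik = stats$mean_joint_loglik)
    if (verbose)
      message(sprintf(
        "iter %3d: sigma=%.4f pi*H=%.3f mu_pr=%.3f sigma_pr=%.3f <logp>=%.2f",
        it, params$sigma, params$pi * H, params$mu_pr, params$sigma_pr,
        stats$mean_joint_loglik))
  }
  structure(list(params = params, trajectory = do.call(rbind, traj),
                 config = list(H = H, H_prime = H_prime, n_random = n_random,
                               K = K, n_iter = n_iter, mode = mode,
                               sigma_pr_fixed = sigma_pr_fixed, seed = seed)),
            class = "ssmca_fit")
}

#' @export
print.ssmca_fit <- function(x, ...) {
  cat(sprintf("ssmca fit (%s): %d iterations, H = %d, H' = %d, K = %d\n",
              x$config$mode, nrow(x$trajectory), x$config$H,
              x$config$H_prime, x$config$K))
  print(x$params)
  invisible(x)
}

#' Run one E-step and return samples and statistics
#'
#' Exposes the batched E-step (selection, Gibbs sampling, accumulation) for
#' inspection: with `return_samples = TRUE` the post-burn-in samples and the
#' per-point selections are attached, which is how the accumulation can be
#' cross-checked against [accumulate_stats()].
#'
#' @param Y `N x D` data matrix.
#' @param params an [model_params()] object.
#' @inheritParams fit_ssmca
#' @param iter iteration tag entering the per-point stream seeds.
#' @param return_samples attach post-burn-in samples per data point.
#' @return an `ssmca_stats` object (with `samples` and `selections` when
#'   requested).
#' @export
estep <- function(Y, params, H_prime = ncol(params$W), n_random = 0, K = 30,
                  seed = 1, iter = 1L, return_samples = FALSE) {
  stats <- estep_batch_cpp(as.matrix(Y), params$W, params$sigma, params$pi,
                           params$mu_pr, params$sigma_pr, H_prime, n_random,
                           K, seed, iter, return_samples)
  class(stats) <- "ssmca_stats"
  stats
}
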