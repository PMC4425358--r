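#' Transition points of one latent's conditional likelihood
#'
#' For pixel `d`, the transition point `P_d` is the latent value at which
#' `s_h W_dh` overtakes every competing cause at that pixel (competitors are
#' floored at the silent background 0, so `P_d >= 0` whenever `s` is a valid
#' state). Below `P_d` the pixel's likelihood is constant in `s_h`; above it,
#' Gaussian. Pixels the latent cannot reach (`W_dh = 0`) have `P_d = Inf`.
#'
#' @param y observed patch, length `D`.
#' @param s current latent state, length `H`.
#' @param W dictionary, `D x H`.
#' @param h index of the latent being updated.
#' @return numeric vector of `D` transition points.
#' @export
transition_points <- function(y, s, W, h) {
  if (length(s) != ncol(W)) stop("dimension mismatch")
  comp <- rep(0, nrow(W))
  for (j in seq_along(s)) {
    if (j == h || s[j] == 0) next
    comp <- pmax(comp, s[j] * W[, j])
  }
  ifelse(W[, h] > 0, comp / W[, h], Inf)
}

#' Assemble the piecewise quadratic log-density of one latent
#'
#' Builds the exact conditional `p(s_h | s_-h, y, theta)` up to the spike:
#' each pixel contributes a constant "left" piece below its transition point
#' and a Gaussian "right" piece above it; sorting pixels by transition point
#' and accumulating coefficients yields `D_eff + 1` quadratic segments
#' (`a s^2 + b s + c` with `a < 0`), to which the slab's quadratic is added.
#' Segment masses are not yet computed; see [add_spike_and_normalize()].
#'
#' @inheritParams transition_points
#' @param params an [model_params()] object.
#' @return object of class `ssmca_piecewise` with `boundaries` (sorted
#'   transition points of reachable pixels), coefficient vectors `A`, `B`,
#'   `C`, and `loglik_at_zero` (the assembled pixel terms at `s_h = 0`,
#'   without the slab).
#' @export
build_segments <- function(y, s, h, params) {
  if (length(y) != nrow(params$W) || length(s) != ncol(params$W))
    stop("dimension mismatch")
  out <- build_segments_cpp(y, s, h, params$W, params$sigma, params$mu_pr,
                            params$sigma_pr)
  if (any(!is.finite(out$A)))
    stop("non-finite segment coefficients (check sigma, sigma_pr > 0)")
  structure(out, class = "ssmca_piecewise")
}

#' Add the spike step and normalize the piecewise posterior
#'
#' The point mass at `s_h = 0` gets log-weight `log(1 - pi)` plus the
#' likelihood of the data with this latent silent; slab-side segments are
#' weighted by `log(pi)` and integrated as truncated Gaussians in log space.
#'
#' @param pp result of [build_segments()].
#' @param pi spike probability.
#' @return `ssmca_piecewise` with `log_masses`, `spike_log_mass` and
#'   `log_norm` fields; `exp(spike_log_mass - log_norm)` is the posterior
#'   probability that the latent is exactly zero.
#' @export
add_spike_and_normalize <- function(pp, pi) {
  out <- add_spike_cpp(pp$boundaries, pp$A, pp$B, pp$C, pp$loglik_at_zero, pi)
  structure(out, class = "ssmca_piecewise")
}

#' Inverse-transform sample from a normalized piecewise posterior
#'
#' Locates the segment (or the spike step) containing cumulative mass `u`
#' and inverts the truncated-Gaussian CDF of that segment. Returns exactly
#' `0` when `u` falls inside the spike step.
#'
#' @param pp normalized posterior from [add_spike_and_normalize()].
#' @param u uniform variate(s) in the open interval (0,1).
#' @return sampled value(s) of the latent.
#' @export
inverse_transform_sample <- function(pp, u) {
  if (any(u <= 0 | u >= 1)) stop("u must lie in the open interval (0,1)")
  vapply(u, function(ui)
    draw_piecewise_cpp(pp$boundaries, pp$A, pp$B, pp$C, pp$log_masses,
                       pp$spike_log_mass, pp$log_norm, ui),
    numeric(1))
}

#' Evaluate the piecewise log-density at arbitrary points
#'
#' Slab-side log-density (unnormalized, including `log(pi)` once the spike
#' has been added). Mainly a diagnostic / testing aid.
#'
#' @param pp an `ssmca_piecewise` object.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of log-density values.
#' @export
piecewise_logdensity <- function(pp, x) {
  j <- findInterval(x, pp$boundaries) + 1
  pp$A[j] * x^2 + pp$B[j] * x + pp$C[j]
}

#' Systematic-scan Gibbs sampling of the selected latents
#'
#' Cyclically redraws every selected latent from its exact conditional
#' (piecewise Gaussian plus spike) by inverse-transform sampling; latents
#' outside the selection stay exactly zero. The first `floor(n_samples / 3)`
#' states are flagged as burn-in and excluded from downstream expectations.
#'
#' @param y observed patch, length `D`.
#' @param selected an `ssmca_selection` from [select_latents()], or an
#'   integer vector of latent indices (scan order).
#' @param params an [model_params()] object.
#' @param n_samples number of states to return.
#' @param s_init optional initial state (must be zero outside the selection);
#'   defaults to the all-zero state.
#' @param seed integer seed for the sampler's deterministic stream.
#' @return list with `samples` (`n_samples x H`, one state per row),
#'   `burn_in` (indices of burn-in rows) and `selected`.
#' @export
gibbs_sweep <- function(y, selected, params, n_samples, s_init = NULL,
                        seed = NULL) {
  idx <- if (inherits(selected, "ssmca_selection")) selected$indices
         else as.integer(selected)
  if (length(idx) == 0) stop("empty selection")
  H <- ncol(params$W)
  if (is.null(s_init)) s_init <- rep(0, H)
  if (any(s_init[-idx] != 0) && length(idx) < H)
    stop("s_init must be zero outside the selected latents")
  if (is.null(seed))
    seed <- with_seed(NULL, sample.int(.Machine$integer.max, 1))
  smp <- gibbs_sweep_cpp(y, s_init, idx, params$W, params$sigma, params$pi,
                         params$mu_pr, params$sigma_pr, n_samples, seed)
  nb <- floor(n_samples / 3)
  list(samples = smp, burn_in = seq_len(nb), selected = idx)
}
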