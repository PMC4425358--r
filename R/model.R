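#' Model parameters for nonlinear spike-and-slab sparse coding
#'
#' Bundles the dictionary and the scalar parameters of the generative model
#' \deqn{y_d \sim N(\max(0, \max_h s_h W_{dh}), \sigma^2), \quad
#'       s_h = b_h z_h, \; b_h \sim Bern(\pi), \; z_h \sim N(\mu_{pr}, \sigma_{pr}^2).}
#' The outer `max(0, .)` is the silent background: a pixel with no active
#' cause is rendered at intensity zero. Dictionary columns are constrained
#' nonnegative and normalized so that every column sums to `D` (the number of
#' pixels), which makes the slab mean comparable across patch sizes.
#'
#' @param W nonnegative numeric matrix, `D x H`; one column per latent.
#' @param sigma positive observation noise standard deviation.
#' @param pi spike probability in `[0, 1]` (probability a latent is active).
#' @param mu_pr slab mean.
#' @param sigma_pr positive slab standard deviation.
#' @param normalize if `TRUE` (default), rescale columns of `W` to sum to `D`.
#' @return an object of class `ssmca_params`.
#' @export
model_params <- function(W, sigma, pi, mu_pr, sigma_pr, normalize = TRUE) {
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("W must be finite")
  if (any(W < 0)) stop("W must be nonnegative")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(sigma_pr) || sigma_pr <= 0) stop("sigma_pr must be > 0")
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (normalize) W <- normalize_dictionary(W)
  structure(list(W = W, sigma = sigma, pi = pi, mu_pr = mu_pr,
                 sigma_pr = sigma_pr),
            class = "ssmca_params")
}

#' Rescale dictionary columns to sum to the number of pixels
#'
#' @param W nonnegative `D x H` matrix.
#' @return matrix whose every column sums to `nrow(W)`; all-zero columns are
#'   reset to a uniform positive column (no evidence to preserve) with a
#'   warning.
#' @export
normalize_dictionary <- function(W) {
  D <- nrow(W)
  cs <- colSums(W)
  bad <- cs <= .Machine$double.eps * D
  if (any(bad)) {
    warning(sum(bad), " all-zero dictionary column(s) reset to uniform")
    W[, bad] <- 1
    cs[bad] <- D
  }
  sweep(W, 2, D / cs, "*")
}

#' @export
print.ssmca_params <- function(x, ...) {
  cat(sprintf(
    "ssmca model parameters: D = %d pixels, H = %d latents\n  sigma = %.4g, pi = %.4g (pi*H = %.3g), mu_pr = %.4g, sigma_pr = %.4g\n",
    nrow(x$W), ncol(x$W), x$sigma, x$pi, x$pi * ncol(x$W), x$mu_pr,
    x$sigma_pr))
  invisible(x)
}

#' Draw latent vectors from the spike-and-slab prior
#'
#' Inactive latents are represented by literal `0`, never by small floats.
#'
#' @param params an [model_params()] object.
#' @param n number of independent draws.
#' @param seed optional integer seed (`NULL` uses the ambient RNG stream).
#' @return list with `s` (`n x H` matrix, exact zeros at spikes), and the
#'   underlying `b` (binary) and `z` (slab values) matrices.
#' @export
sample_prior <- function(params, n = 1, seed = NULL) {
  H <- ncol(params$W)
  with_seed(seed, {
    b <- matrix(rbinom(n * H, 1, params$pi), n, H)
    z <- matrix(rnorm(n * H, params$mu_pr, params$sigma_pr), n, H)
    s <- z
    s[b == 0] <- 0
    list(s = s, b = b, z = z)
  })
}

#' Render a latent configuration through the max-superposition
#'
#' `render(s, W)[d] = max(0, max_h s_h W_dh)`: overlapping components occlude
#' (pixelwise maximum) rather than add, and an empty scene renders to zero.
#'
#' @param s numeric latent vector of length `H`, or `N x H` matrix.
#' @param W dictionary, `D x H`.
#' @return length-`D` vector (or `N x D` matrix) of noise-free pixel means.
#' @export
render <- function(s, W) {
  if (is.matrix(s)) {
    if (ncol(s) != ncol(W)) stop("dimension mismatch between s and W")
    return(render_batch_cpp(s, W))
  }
  if (length(s) != ncol(W)) stop("dimension mismatch between s and W")
  drop(render_batch_cpp(matrix(s, 1), W))
}

#' Draw noisy observations given latents
#'
#' @inheritParams render
#' @param sigma observation noise standard deviation.
#' @param seed optional integer seed.
#' @return vector/matrix shaped like `render(s, W)` with iid Gaussian noise.
#' @export
sample_observation <- function(s, W, sigma, seed = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  mu <- render(s, W)
  with_seed(seed, mu + rnorm(length(mu), 0, sigma))
}

#' Joint log density of an observation and a latent configuration
#'
#' Returns `log p(y | s, theta) + log p(s | theta)` where the prior term uses
#' the point mass `1 - pi` for exact zeros and `pi` times the slab density
#' elsewhere.
#'
#' @param y observed patch, length `D`.
#' @param s latent vector, length `H`.
#' @param params an [model_params()] object.
#' @return scalar log joint density.
#' @export
loglikelihood <- function(y, s, params) {
  if (length(y) != nrow(params$W) || length(s) != ncol(params$W))
    stop("dimension mismatch")
  ll <- sum(dnorm(y, render(s, params$W), params$sigma, log = TRUE))
  act <- s != 0
  if (any(act)) {
    if (params$pi == 0) return(-Inf)
    ll <- ll + sum(act) * log(params$pi) +
      sum(dnorm(s[act], params$mu_pr, params$sigma_pr, log = TRUE))
  }
  if (any(!act)) {
    if (params$pi == 1) return(-Inf)
    ll <- ll + sum(!act) * log1p(-params$pi)
  }
  ll
}
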