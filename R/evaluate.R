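#' Reconstruct patches with a trained model
#'
#' Runs preselection and Gibbs sampling on each patch and keeps the
#' post-burn-in sample with the highest joint log density `log p(y, s)`;
#' the reconstruction is that sample rendered through the max. Per-patch
#' MSE is the mean squared pixel error against the observed (noisy) patch;
#' MMSE is its mean over the dataset.
#'
#' @param data an `ssmca_databatch`, a matrix of patches (rows), or a single
#'   patch vector.
#' @param params a trained [model_params()] object.
#' @param H_prime,n_random preselection configuration.
#' @param K Gibbs samples per patch (first third burn-in).
#' @param seed integer seed (reconstruction is deterministic given it).
#' @param keep_yhat,keep_shat attach the reconstructed patches / latent
#'   point estimates.
#' @return object of class `ssmca_reconstruction`: `mse`, `n_active`,
#'   `joint_loglik` per patch, `mmse`, optional `Y_hat`/`S_hat`, and
#'   `k_true` when the input carried ground-truth labels.
#' @export
reconstruct <- function(data, params, H_prime = ncol(params$W), n_random = 0,
                        K = 20, seed = 1, keep_yhat = TRUE,
                        keep_shat = FALSE) {
  k_true <- NULL
  if (inherits(data, "ssmca_databatch")) {
    k_true <- data$k_true
    Y <- data$Y
  } else if (is.matrix(data)) Y <- data
  else Y <- matrix(data, 1)
  res <- reconstruct_batch_cpp(Y, params$W, params$sigma, params$pi,
                               params$mu_pr, params$sigma_pr, H_prime,
                               n_random, K, seed, keep_yhat, keep_shat)
  res$mse <- res$mse / ncol(Y)   # compiled path accumulates the pixel sum
  out <- list(mse = as.vector(res$mse), n_active = as.integer(res$n_active),
              joint_loglik = as.vector(res$joint_loglik),
              mmse = mean(res$mse), k_true = k_true)
  if (keep_yhat) out$Y_hat <- res$Y_hat
  if (keep_shat) out$S_hat <- res$S_hat
  structure(out, class = "ssmca_reconstruction")
}

#' @export
print.ssmca_reconstruction <- function(x, ...) {
  cat(sprintf(
    "ssmca reconstruction: %d patches, MMSE = %.4g, mean active components = %.2f\n",
    length(x$mse), x$mmse, mean(x$n_active)))
  invisible(x)
}

#' Count the components used by a code vector
#'
#' Spike-and-slab codes carry exact zeros, so the default threshold 0 counts
#' exact nonzeros; linear sparse-coding coefficients are only approximately
#' zero and should be counted with a small positive threshold (1e-6 is used
#' by the baseline adapter).
#'
#' @param s numeric code vector.
#' @param threshold magnitude above which a coefficient counts as active.
#' @return integer count.
#' @export
count_active <- function(s, threshold = 0) {
  sum(abs(s) > threshold)
}

#' Sparsity and error versus ground-truth data complexity
#'
#' Groups a reconstruction report by the ground-truth number of components
#' per patch and summarizes how many components the model used and what
#' error it incurred -- the sparsity-follows-complexity analysis.
#'
#' @param report an `ssmca_reconstruction` carrying `k_true` (or pass
#'   `k_true` explicitly).
#' @param k_true optional ground-truth counts overriding the report's.
#' @return data frame with one row per `k`: group size, mean/sd of active
#'   components, mean/sd of MSE.
#' @export
sparsity_vs_complexity <- function(report, k_true = NULL) {
  k <- if (!is.null(k_true)) k_true else report$k_true
  if (is.null(k)) stop("ground-truth component counts (k_true) required")
  if (length(k) != length(report$mse)) stop("k_true length mismatch")
  ks <- sort(unique(k))
  out <- data.frame(
    k = ks,
    n = vapply(ks, function(kk) sum(k == kk), numeric(1)),
    mean_active = vapply(ks, function(kk) mean(report$n_active[k == kk]), numeric(1)),
    sd_active = vapply(ks, function(kk) sd(report$n_active[k == kk]), numeric(1)),
    mean_mse = vapply(ks, function(kk) mean(report$mse[k == kk]), numeric(1)),
    sd_mse = vapply(ks, function(kk) sd(report$mse[k == kk]), numeric(1)))
  out
}

#' Consistency of the prior with the data-averaged posterior
#'
#' For a correct model of the data-generating process, the posterior
#' averaged over data points equals the prior. Pools post-burn-in posterior
#' samples over data points and latents and reports (a) the gap between the
#' empirical activation frequency and the spike probability `pi`, with a
#' Monte-Carlo standard error from the per-data-point means, and (b) a
#' Kolmogorov-Smirnov comparison of the pooled nonzero values against the
#' slab Gaussian.
#'
#' @param params an [model_params()] object (the model whose consistency is
#'   probed).
#' @param data patches as matrix or `ssmca_databatch`.
#' @param H_prime,n_random,K sampler configuration (use `H_prime = H` for an
#'   unbiased check).
#' @param seed integer seed.
#' @return list with `activation_freq`, `pi`, `gap`, `mc_se`, `ks_stat`,
#'   `ks_p`, `n_nonzero`.
#' @export
prior_posterior_consistency <- function(params, data,
                                        H_prime = ncol(params$W),
                                        n_random = 0, K = 30, seed = 1) {
  Y <- if (inherits(data, "ssmca_databatch")) data$Y else as.matrix(data)
  stats <- estep(Y, params, H_prime = H_prime, n_random = n_random, K = K,
                 seed = seed, iter = 1L, return_samples = TRUE)
  H <- ncol(params$W)
  per_point <- vapply(stats$samples,
                      function(m) mean(m != 0), numeric(1))
  freq <- mean(per_point)
  mc_se <- sd(per_point) / sqrt(length(per_point))
  nz <- unlist(lapply(stats$samples, function(m) m[m != 0]), use.names = FALSE)
  ks <- if (length(nz) >= 8)
    suppressWarnings(ks.test(nz, "pnorm", params$mu_pr, params$sigma_pr))
  else list(statistic = NA_real_, p.value = NA_real_)
  list(activation_freq = freq, pi = params$pi, gap = abs(freq - params$pi),
       mc_se = mc_se, ks_stat = unname(ks$statistic),
       ks_p = unname(ks$p.value), n_nonzero = length(nz))
}

#' Linear sparse-coding baseline (online l1 dictionary learning)
#'
#' Thin adapter over scikit-learn's mini-batch dictionary learning (the
#' standard online solver of the lasso-penalized matrix-factorization
#' objective `min 0.5 ||y - W s||^2 + a ||s||_1` with unit-norm atoms),
#' invoked through the `python` interpreter. Produces the same report
#' schema as [reconstruct()], with linear reconstruction `W s` and active
#' counts thresholded at 1e-6. The core package works without this adapter;
#' a clear error is raised when no usable interpreter is found.
#'
#' @param data patches (matrix or `ssmca_databatch`).
#' @param a l1 regularization weight of the objective.
#' @param H number of dictionary atoms.
#' @param n_train patches used to fit the dictionary (sampled without
#'   replacement when the dataset is larger); all patches are encoded.
#' @param max_iter sklearn `max_iter` over minibatches.
#' @param seed integer seed (sklearn `random_state` and training subsample).
#' @param threshold active-coefficient threshold for the report.
#' @param python path to the interpreter (default: `ssmca.python` option,
#'   then `python` on the PATH).
#' @return list with `W` (`D x H`), `codes` (`N x H`), and `report`
#'   (`ssmca_reconstruction`-classed: `mse`, `n_active`, `mmse`, `k_true`).
#' @export
linear_baseline <- function(data, a = 1, H = 100, n_train = 20000,
                            max_iter = 2000, seed = 1, threshold = 1e-6,
                            python = getOption("ssmca.python", "python")) {
  k_true <- NULL
  if (inherits(data, "ssmca_databatch")) {
    k_true <- data$k_true
    Y <- data$Y
  } else Y <- as.matrix(data)
  if (!nzchar(Sys.which(python)))
    stop("linear_baseline requires a python interpreter with scikit-learn; ",
         "none found (set options(ssmca.python = ...))")
  td <- tempfile("linsc")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  data.table::fwrite(data.table::as.data.table(Y),
                     file.path(td, "Y.csv"), col.names = FALSE)
  script <- system.file("python", "linsc_baseline.py", package = "ssmca")
  if (!nzchar(script)) stop("baseline helper script not found")
  status <- system2(python,
                    c(script, shQuote(td), as.character(a), as.character(H),
                      as.character(n_train), as.character(max_iter),
                      as.character(seed)),
                    stdout = file.path(td, "log.txt"),
                    stderr = file.path(td, "log.txt"))
  if (status != 0)
    stop("baseline adapter failed:\n",
         paste(readLines(file.path(td, "log.txt")), collapse = "\n"))
  Wd <- as.matrix(data.table::fread(file.path(td, "dict.csv"), header = FALSE))
  codes <- as.matrix(data.table::fread(file.path(td, "codes.csv"),
                                       header = FALSE))
  rec <- codes %*% Wd                       # rows of Wd are atoms
  mse <- rowMeans((Y - rec)^2)
  n_active <- as.integer(rowSums(abs(codes) > threshold))
  report <- structure(list(mse = mse, n_active = n_active,
                           joint_loglik = NULL, mmse = mean(mse),
                           k_true = k_true),
                      class = "ssmca_reconstruction")
  list(W = t(Wd), codes = codes, report = report)
}
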