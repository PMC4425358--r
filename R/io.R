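#' Write a data batch to a plain-text container
#'
#' A batch is stored as a directory of CSV matrices plus a JSON metadata
#' file, a portable text format that round-trips every field of
#' [databatch()].
#'
#' @param batch an `ssmca_databatch`.
#' @param path directory to create (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_databatch <- function(batch, path) {
  if (!inherits(batch, "ssmca_databatch")) stop("not a data batch")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  wm <- function(M, f) data.table::fwrite(data.table::as.data.table(M),
                                          file.path(path, f),
                                          col.names = FALSE)
  wm(batch$Y, "Y.csv")
  for (f in c("S_true", "W_true", "Y_clean"))
    if (!is.null(batch[[f]])) wm(batch[[f]], paste0(f, ".csv"))
  if (!is.null(batch$k_true))
    wm(matrix(batch$k_true, ncol = 1), "k_true.csv")
  jsonlite::write_json(batch$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a data batch written by [write_databatch()]
#'
#' @param path container directory.
#' @return an `ssmca_databatch`.
#' @export
read_databatch <- function(path) {
  rm_ <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) return(NULL)
    as.matrix(data.table::fread(p, header = FALSE))
  }
  Y <- rm_("Y.csv")
  if (is.null(Y)) stop("no Y.csv under ", path)
  dimnames(Y) <- NULL
  strip <- function(M) { if (!is.null(M)) dimnames(M) <- NULL; M }
  k <- rm_("k_true.csv")
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  databatch(Y, S_true = strip(rm_("S_true.csv")),
            W_true = strip(rm_("W_true.csv")),
            k_true = if (!is.null(k)) as.integer(k[, 1]),
            Y_clean = strip(rm_("Y_clean.csv")), meta = meta)
}

#' Write a fitted model checkpoint
#'
#' Stores the dictionary as CSV and the scalar parameters, configuration and
#' trajectory as JSON/CSV so a fit can be resumed with [fit_ssmca()] (same
#' master seed, `start_iter = iter + 1`).
#'
#' @param fit an `ssmca_fit` (or a bare `ssmca_params`).
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  params <- if (inherits(fit, "ssmca_fit")) fit$params else fit
  if (!inherits(params, "ssmca_params")) stop("not a fit or parameter object")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(params$W),
                     file.path(path, "W.csv"), col.names = FALSE)
  scal <- list(sigma = params$sigma, pi = params$pi, mu_pr = params$mu_pr,
               sigma_pr = params$sigma_pr)
  if (inherits(fit, "ssmca_fit")) {
    scal$config <- fit$config
    scal$iter <- max(fit$trajectory$iter)
    data.table::fwrite(fit$trajectory, file.path(path, "trajectory.csv"))
  }
  jsonlite::write_json(scal, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a checkpoint written by [write_checkpoint()]
#'
#' @param path checkpoint directory.
#' @return list with `params` (`ssmca_params`), and when present `config`,
#'   `iter` and `trajectory`.
#' @export
read_checkpoint <- function(path) {
  pj <- file.path(path, "params.json")
  if (!file.exists(pj)) stop("corrupt checkpoint: missing params.json")
  scal <- jsonlite::read_json(pj, simplifyVector = TRUE)
  W <- as.matrix(data.table::fread(file.path(path, "W.csv"), header = FALSE))
  dimnames(W) <- NULL
  params <- model_params(W, scal$sigma, scal$pi, scal$mu_pr, scal$sigma_pr,
                         normalize = FALSE)
  out <- list(params = params, config = scal$config, iter = scal$iter)
  tp <- file.path(path, "trajectory.csv")
  if (file.exists(tp)) out$trajectory <- as.data.frame(data.table::fread(tp))
  out
}

#' Write a reconstruction report as CSV plus a JSON summary
#'
#' @param report an `ssmca_reconstruction`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(index = seq_along(report$mse),
                   k_true = if (is.null(report$k_true)) NA else report$k_true,
                   mse = report$mse, n_active = report$n_active)
  data.table::fwrite(df, file.path(path, "report.csv"))
  summ <- list(mmse = report$mmse, mean_active = mean(report$n_active),
               n = length(report$mse))
  if (!is.null(report$k_true))
    summ$by_k <- sparsity_vs_complexity(report)
  jsonlite::write_json(summ, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
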