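#' Relevance score of each latent for one observation
#'
#' The cosine-similarity selection function `score_h = <W_h, y> / ||W_h||`
#' (the norm of `y` is constant across latents and does not affect the
#' ranking). All-zero dictionary columns score `-Inf` and are never ranked.
#'
#' @param y observed patch, length `D`.
#' @param W dictionary, `D x H`.
#' @return numeric vector of `H` scores.
#' @export
selection_score <- function(y, W) {
  if (length(y) != nrow(W)) stop("dimension mismatch between y and W")
  nrm <- sqrt(colSums(W^2))
  sc <- as.vector(crossprod(W, y))
  sc <- ifelse(nrm > 0, sc / nrm, -Inf)
  sc
}

#' Restrict inference to the most relevant latents
#'
#' Picks the top `H_prime - n_random` latents by score (ties broken by
#' ascending index) plus `n_random` latents drawn uniformly without
#' replacement from the remainder. Latents outside the selection are clamped
#' to exactly zero for this data point; the truncated posterior only has
#' support on the selected subset. With `H_prime` equal to the total number
#' of latents the selection is exhaustive and inference is exact.
#'
#' @param scores numeric vector from [selection_score()].
#' @param H_prime total number of latents to select.
#' @param n_random how many of the `H_prime` slots are filled at random.
#' @param seed optional integer seed for the random slots.
#' @return list with `indices` (ordered: top scores first, then random
#'   picks), `n_random`, and the input `scores`.
#' @export
select_latents <- function(scores, H_prime, n_random = 0, seed = NULL) {
  H <- length(scores)
  if (H_prime > H) stop("H_prime exceeds the number of latents")
  if (n_random > H_prime) stop("n_random exceeds H_prime")
  if (is.null(seed))
    seed <- with_seed(NULL, sample.int(.Machine$integer.max, 1))
  idx <- select_latents_cpp(scores, H_prime, n_random, seed)
  structure(list(indices = as.integer(idx),
                 n_random = min(n_random, H - (H_prime - n_random)),
                 scores = scores),
            class = "ssmca_selection")
}
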