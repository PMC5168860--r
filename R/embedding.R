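#' Perplexity heuristic
#'
#' The t-SNE perplexity grows with the number of points as
#' `floor(log(n)^2)` (natural log), clamped into the admissible range
#' `[2, floor((n - 1) / 3)]` (upper limit required by Barnes-Hut t-SNE; the
#' lower clamp yields at least 1 for very small n).
#'
#' @param n Number of data points (>= 4).
#' @return Integer perplexity.
#' @examples
#' perplexity_heuristic(1000)  # 47
#' @export
perplexity_heuristic <- function(n) {
  n <- stopifnot_scalar_count(n, "n")
  if (n < 4) stop("need at least 4 points to embed", call. = FALSE)
  p <- max(2L, as.integer(floor(log(n)^2)))
  max(1L, min(p, (n - 1L) %/% 3L))
}

#' Barnes-Hut t-SNE embedding of signature vectors
#'
#' Reduces the signature matrix to 2-D coordinates that preserve cluster
#' structure, using Barnes-Hut t-SNE on the raw frequency vectors (no scaling
#' or PCA preprocessing; Euclidean distances). The embedding is stochastic
#' across seeds but exactly reproducible for a fixed seed.
#'
#' @param x A [signature_matrix()] or a numeric matrix (rows = points).
#' @param theta Barnes-Hut speed/accuracy trade-off in `[0, 1]` (default 0.5).
#' @param perplexity Integer perplexity; default [perplexity_heuristic()] of
#'   the row count.
#' @param seed Integer seed controlling the embedding initialisation.
#' @param max_iter Number of gradient iterations (default 1000).
#' @return Numeric matrix (n x 2) with attributes `seed`, `perplexity`,
#'   `theta`.
#' @export
embed_signatures <- function(x, theta = 0.5, perplexity = NULL, seed = 1L,
                             max_iter = 1000L) {
  if (inherits(x, "signature_matrix")) x <- x$freq
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in signature matrix", call. = FALSE)
  if (theta < 0 || theta > 1) stop("`theta` must be in [0, 1]", call. = FALSE)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 rows to embed", call. = FALSE)
  perplexity <- perplexity %||% perplexity_heuristic(n)
  res <- with_seed(seed, Rtsne::Rtsne(
    x, dims = 2, theta = theta, perplexity = perplexity,
    max_iter = as.integer(max_iter), pca = FALSE, normalize = FALSE,
    check_duplicates = FALSE, num_threads = 1))
  coords <- res$Y
  dimnames(coords) <- list(NULL, c("x", "y"))
  attr(coords, "seed") <- seed
  attr(coords, "perplexity") <- perplexity
  attr(coords, "theta") <- theta
  coords
}
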