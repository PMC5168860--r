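#' Hartigan dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its empirical
#' CDF and any unimodal CDF; large values indicate multimodality. Computed
#' exactly by a convex/concave ("greatest convex minorant / least concave
#' majorant") analysis of the ECDF. For non-constant samples the dip lies in
#' `[1/(2n), 1/4]`; constant samples return 0 by convention.
#'
#' @param x Numeric sample (length >= 1, finite).
#' @return The dip statistic (scalar).
#' @examples
#' dip_statistic(c(0, 1))      # 0.25, the maximum
#' dip_statistic(rep(3, 10))   # 0 by convention
#' @export
dip_statistic <- function(x) {
  if (!is.numeric(x) || length(x) < 1) stop("`x` must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  .dip_sorted_cpp(sort(as.numeric(x)))
}

# Monte-Carlo dip null table for uniform samples of size n, cached per
# (n, null_reps, seed).  The uniform is the extreme unimodal null: any smooth
# unimodal sample has stochastically smaller dip, so p-values are conservative.
dip_null_table <- function(n, null_reps = 1000, seed = 1L) {
  n <- stopifnot_scalar_count(n, "n")
  null_reps <- stopifnot_scalar_count(null_reps, "null_reps")
  key <- sprintf("null:%d:%d:%d", n, null_reps, as.integer(seed))
  tab <- get0(key, envir = .scscreen_cache, inherits = FALSE)
  if (is.null(tab)) {
    # table accuracy 1e-9 is ample: it only feeds empirical tail counts
    tab <- with_seed(seed, .dip_unif_null_cpp(n, null_reps, 1e-9))
    assign(key, tab, envir = .scscreen_cache)
  }
  tab
}

# critical dip value: the (k+1)-th largest dip among the null samples, where
# k = floor(alpha * null_reps); a viewer's p-value is <= alpha iff its dip
# exceeds this value.  Computed lazily (exact dips only near the top), cached.
dip_null_quantile <- function(n, null_reps = 1000, alpha = 0.001, seed = 1L) {
  n <- stopifnot_scalar_count(n, "n")
  k <- floor(alpha * null_reps)
  key <- sprintf("thr:%d:%d:%d:%d", n, null_reps, k, as.integer(seed))
  t <- get0(key, envir = .scscreen_cache, inherits = FALSE)
  if (is.null(t)) {
    t <- with_seed(seed, .dip_null_threshold_cpp(n, null_reps, k, 1e-9))
    assign(key, t, envir = .scscreen_cache)
  }
  t
}

#' Monte-Carlo p-value for a dip statistic
#'
#' Fraction of `null_reps` uniform(0,1) samples of size `n` whose dip is at
#' least the observed dip. The null table is cached per sample size.
#'
#' @param dip Observed dip statistic.
#' @param n Sample size the dip was computed from (>= 4).
#' @param null_reps Number of Monte-Carlo replicates (default 1000).
#' @param seed Seed for the null table.
#' @return p-value in `[0, 1]`.
#' @examples
#' dip_pvalue(0, 100)     # 1: every uniform sample has dip >= 0
#' dip_pvalue(0.25, 100)  # 0: no uniform sample of size 100 gets near 1/4
#' @export
dip_pvalue <- function(dip, n, null_reps = 1000, seed = 1L) {
  if (n < 4) stop("`n` must be >= 4", call. = FALSE)
  mean(dip_null_table(n, null_reps, seed) >= dip)
}
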