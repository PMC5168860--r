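#' Bootstrap folds by subsampling signature rows
#'
#' Draws `B` independent subsets of `floor(fraction * n_rows)` distinct row
#' indices (without replacement within a fold), reproducibly from the master
#' seed; fold b is drawn under its own derived seed.
#'
#' @param n_rows Number of signature rows.
#' @param B Number of folds (default 10).
#' @param fraction Subsampling fraction (default 0.75).
#' @param seed Master seed.
#' @return List of `B` integer index vectors.
#' @export
make_folds <- function(n_rows, B = 10, fraction = 0.75, seed = 1L) {
  n_rows <- stopifnot_scalar_count(n_rows, "n_rows")
  B <- stopifnot_scalar_count(B, "B")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]", call. = FALSE)
  size <- floor(fraction * n_rows)
  if (size < 1)
    stop(sprintf("too few rows: %d rows at fraction %.2f leave empty folds",
                 n_rows, fraction), call. = FALSE)
  lapply(seq_len(B), function(b) {
    with_seed(fold_seed(seed, b), sample.int(n_rows, size))
  })
}

# decision rule on fold-fraction confidences; the inequalities are strict, so
# a confidence of exactly clean_below is not clean and exactly
# contaminated_above is not contaminated
verdict <- function(dip_conf, cc_conf, clean_below = 0.25,
                    contaminated_above = 0.75) {
  if (dip_conf < clean_below && cc_conf < clean_below) return("clean")
  if (dip_conf > contaminated_above || cc_conf > contaminated_above)
    return("contaminated")
  "warning"
}

#' Bootstrap contamination confidences and verdict
#'
#' Runs the embed-and-detect stack on `B` bootstrap folds of the signature
#' matrix (75\% subsampling by default). Each fold is embedded with its own
#' derived seed and perplexity recomputed for the fold size, then tested with
#' the dip detector and the mutual-k-NN component detector (the latter with
#' contig reassignment and the bp filter applied). The per-detector confidence
#' is the fraction of folds flagging contamination; the verdict is
#' \describe{
#'   \item{clean}{both confidences strictly below `clean_below`}
#'   \item{contaminated}{either confidence strictly above `contaminated_above`}
#'   \item{warning}{anything in between}
#' }
#'
#' @param sig A [signature_matrix()].
#' @param B Number of folds (default 10).
#' @param subsample Subsampling fraction (default 0.75).
#' @param clean_below,contaminated_above Fold-fraction decision thresholds
#'   (defaults 0.25 and 0.75, strict inequalities).
#' @param seed Master seed.
#' @param theta,max_iter Embedding parameters, see [embed_signatures()].
#' @param t_dip,alpha,null_reps Dip detector parameters, see [dip_detector()].
#' @param k_cc,min_cluster_bp CC detector parameters, see [cc_detector()].
#' @param threads Folds are independent; with `threads > 1` they run in
#'   parallel (forked processes) with identical results to serial execution.
#' @return An object of class `confidence_report`: list with
#'   `dip_confidence`, `cc_confidence`, `status`, `folds` (per-fold flags) and
#'   `params`.
#' @export
estimate_confidence <- function(sig, B = 10, subsample = 0.75,
                                clean_below = 0.25, contaminated_above = 0.75,
                                seed = 1L, theta = 0.5, max_iter = 1000L,
                                t_dip = 0.001, alpha = 0.001, null_reps = 1000,
                                k_cc = 9, min_cluster_bp = 5000, threads = 1L) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (clean_below < 0 || clean_below > contaminated_above || contaminated_above > 1)
    stop("need 0 <= clean_below <= contaminated_above <= 1", call. = FALSE)
  x <- sig$freq
  folds <- make_folds(nrow(x), B = B, fraction = subsample, seed = seed)

  run_fold <- function(b) {
    tryCatch({
      idx <- folds[[b]]
      fs <- fold_seed(seed, b)
      emb <- embed_signatures(x[idx, , drop = FALSE], theta = theta,
                              seed = fs, max_iter = max_iter)
      dip <- dip_detector(emb, t_dip = t_dip, alpha = alpha,
                          null_reps = null_reps, seed = seed)
      cc <- cc_detector(emb, sig$provenance$contig_id[idx], sig$contig_lengths,
                        k_cc = k_cc, min_cluster_bp = min_cluster_bp)
      list(ok = TRUE, dip = dip$contaminated, cc = cc$contaminated,
           dip_fraction = dip$detail, cc_clusters = cc$detail, error = NA_character_)
    }, error = function(e) {
      list(ok = FALSE, dip = NA, cc = NA, dip_fraction = NA_real_,
           cc_clusters = NA_integer_, error = conditionMessage(e))
    })
  }
  results <- if (threads > 1) {
    parallel::mclapply(seq_len(B), run_fold, mc.cores = threads)
  } else {
    lapply(seq_len(B), run_fold)
  }
  folds_df <- data.frame(
    fold = seq_len(B),
    rows = lengths(folds),
    ok = vapply(results, `[[`, logical(1), "ok"),
    dip = vapply(results, function(r) as.logical(r$dip), logical(1)),
    cc = vapply(results, function(r) as.logical(r$cc), logical(1)),
    dip_fraction = vapply(results, `[[`, numeric(1), "dip_fraction"),
    cc_clusters = vapply(results, function(r) as.integer(r$cc_clusters), integer(1)),
    error = vapply(results, `[[`, character(1), "error"))
  n_ok <- sum(folds_df$ok)
  for (msg in unique(stats::na.omit(folds_df$error)))
    warning("fold failed: ", msg, call. = FALSE)
  if (n_ok == 0) {
    # pathological input (e.g. far too few rows): report rather than crash
    rep <- structure(list(dip_confidence = NA_real_, cc_confidence = NA_real_,
                          status = "warning",
                          diagnostic = "all bootstrap folds failed",
                          folds = folds_df, B = B,
                          params = list(B = B, subsample = subsample,
                                        clean_below = clean_below,
                                        contaminated_above = contaminated_above,
                                        seed = seed)),
                     class = "confidence_report")
    return(rep)
  }
  if (n_ok < ceiling(B / 2))
    stop(sprintf("only %d of %d bootstrap folds succeeded", n_ok, B), call. = FALSE)
  ok <- folds_df$ok
  dip_conf <- mean(folds_df$dip[ok])
  cc_conf <- mean(folds_df$cc[ok])
  status <- verdict(dip_conf, cc_conf, clean_below, contaminated_above)
  structure(list(dip_confidence = dip_conf, cc_confidence = cc_conf,
                 status = status, diagnostic = NA_character_,
                 folds = folds_df, B = B,
                 params = list(B = B, subsample = subsample,
                               clean_below = clean_below,
                               contaminated_above = contaminated_above,
                               seed = seed)),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("contamination confidence over %d bootstrap folds:\n", x$B))
  cat(sprintf("  DIP: %s   CC: %s\n",
              formatC(x$dip_confidence, format = "f", digits = 2),
              formatC(x$cc_confidence, format = "f", digits = 2)))
  cat("  status:", toupper(x$status), "\n")
  if (!is.na(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}
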