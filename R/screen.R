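#' Screen a single-cell assembly for contamination
#'
#' The main entry point: reads the assembly, computes windowed canonical
#' tetramer signatures, estimates bootstrap contamination confidences with the
#' DIP and CC detectors, and -- when the verdict is contaminated (or
#' `force_cleanse`) -- derives a cluster split of the assembly on the
#' full-data embedding. Returns a `contam_screen` object with `print()`,
#' `summary()` and `plot()` methods; use [export_results()] or
#' [run_pipeline()] to write files.
#'
#' @param x FASTA path, named character vector of contig sequences, or a
#'   [generate_sample()] result.
#' @param n Target number of signature windows (default 1000).
#' @param k Signature word length (default 4).
#' @param theta Barnes-Hut accuracy trade-off (default 0.5).
#' @param max_iter t-SNE iterations (default 1000).
#' @param t_dip,alpha,null_reps Dip detector parameters ([dip_detector()]).
#' @param k_cc Mutual neighbour count ([cc_detector()], default 9).
#' @param min_cluster_bp Outlier cluster threshold in bp (default 5000).
#' @param B,subsample,clean_below,contaminated_above Bootstrap parameters
#'   ([estimate_confidence()]).
#' @param k_min,k_max Cleansing cluster-number range ([cleanse()]).
#' @param seed Master seed; every stochastic step derives its seed from it.
#' @param force_cleanse Run cleansing regardless of the verdict.
#' @param threads Parallel workers for the bootstrap folds.
#' @param verbose Print progress messages.
#' @return An object of class `contam_screen`.
#' @examples
#' \donttest{
#' two <- generate_sample(list(genome_model("a", gc = 0.3, total_bp = 60000),
#'                             genome_model("b", gc = 0.7, total_bp = 60000)),
#'                        seed = 1)
#' scr <- screen_assembly(two, n = 200, B = 4, seed = 1)
#' scr
#' }
#' @export
screen_assembly <- function(x, n = 1000, k = 4, theta = 0.5, max_iter = 1000L,
                            t_dip = 0.001, alpha = 0.001, null_reps = 1000,
                            k_cc = 9, min_cluster_bp = 5000,
                            B = 10, subsample = 0.75,
                            clean_below = 0.25, contaminated_above = 0.75,
                            k_min = 2, k_max = 5, seed = 1L,
                            force_cleanse = FALSE, threads = 1L,
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  sample_name <- if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
                     file.exists(x)) {
    tools::file_path_sans_ext(basename(x))
  } else "sample"
  contigs <- as_contigs(x)

  say("computing signatures (", length(contigs), " contigs)")
  sig <- signature_matrix(contigs, n = n, k = k)
  say(nrow(sig$freq), " windows of ", sig$config$w, " bp")

  say("bootstrapping detectors (", B, " folds)")
  conf <- estimate_confidence(
    sig, B = B, subsample = subsample, clean_below = clean_below,
    contaminated_above = contaminated_above, seed = seed, theta = theta,
    max_iter = max_iter, t_dip = t_dip, alpha = alpha, null_reps = null_reps,
    k_cc = k_cc, min_cluster_bp = min_cluster_bp, threads = threads)
  say("verdict: ", conf$status)

  say("embedding full data for inspection")
  emb <- embed_signatures(sig, theta = theta, seed = seed, max_iter = max_iter)

  cln <- NULL
  if (identical(conf$status, "contaminated") || force_cleanse) {
    say("cleansing")
    cln <- cleanse(contigs, emb, sig$provenance, sig$contig_lengths,
                   k_min = k_min, k_max = k_max,
                   min_cluster_bp = min_cluster_bp, sample_name = sample_name)
  }

  structure(list(
    sample = sample_name,
    contigs = contigs,
    signatures = sig,
    confidence = conf,
    embedding = emb,
    cleansing = cln,
    params = list(n = n, k = k, theta = theta, max_iter = max_iter,
                  t_dip = t_dip, alpha = alpha, null_reps = null_reps,
                  k_cc = k_cc, min_cluster_bp = min_cluster_bp, B = B,
                  subsample = subsample, clean_below = clean_below,
                  contaminated_above = contaminated_above, k_min = k_min,
                  k_max = k_max, seed = as.integer(seed),
                  force_cleanse = force_cleanse),
    version = as.character(utils::packageVersion("scscreen"))),
    class = "contam_screen")
}

#' @export
print.contam_screen <- function(x, ...) {
  cat("Reference-free contamination screen --", x$sample, "\n")
  cat(sprintf("  %d contigs, %s bp, %d signature windows\n",
              length(x$contigs),
              format(sum(x$signatures$contig_lengths), big.mark = ","),
              nrow(x$signatures$freq)))
  cat(sprintf("  DIP confidence %s | CC confidence %s -> %s\n",
              formatC(x$confidence$dip_confidence, format = "f", digits = 2),
              formatC(x$confidence$cc_confidence, format = "f", digits = 2),
              toupper(x$confidence$status)))
  if (!is.null(x$cleansing)) {
    if (x$cleansing$inconclusive) {
      cat("  cleansing: inconclusive\n")
    } else {
      cat(sprintf("  cleansing: %d clusters (k = %d by Davies-Bouldin)\n",
                  length(x$cleansing$clusters), x$cleansing$chosen_k))
    }
  }
  invisible(x)
}

#' @export
summary.contam_screen <- function(object, ...) {
  print(object)
  cat("\nper-fold detector flags:\n")
  print(object$confidence$folds[c("fold", "rows", "ok", "dip", "cc",
                                  "dip_fraction", "cc_clusters")],
        row.names = FALSE)
  if (!is.null(object$cleansing) && !object$cleansing$inconclusive) {
    cat("\nDavies-Bouldin by k:\n")
    print(object$cleansing$db_by_k)
    print(object$cleansing$assignment)
  }
  invisible(object)
}

#' Plot a contamination screen
#'
#' Scatter plot of the full-data embedding, coloured by the cleansing cluster
#' when available (outliers in grey), otherwise by contig of origin.
#'
#' @param x A `contam_screen`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.contam_screen <- function(x, ...) {
  emb <- x$embedding
  if (!is.null(x$cleansing) && !x$cleansing$inconclusive) {
    lab <- x$cleansing$assignment$labels
    col <- ifelse(lab == 0, "grey60", lab + 1L)
    legend_txt <- c(paste("cluster", seq_along(x$cleansing$clusters)),
                    if (any(lab == 0)) "outliers")
    legend_col <- c(sort(unique(lab[lab != 0])) + 1L, if (any(lab == 0)) "grey60")
  } else {
    cid <- factor(x$signatures$provenance$contig_id)
    col <- (as.integer(cid) %% 8L) + 1L
    legend_txt <- NULL
  }
  graphics::plot(emb, col = col, pch = 16, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = sprintf("%s: %s", x$sample,
                                toupper(x$confidence$status)), ...)
  if (!is.null(legend_txt))
    graphics::legend("topright", legend = legend_txt, col = legend_col,
                     pch = 16, bty = "n")
  invisible(x)
}
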