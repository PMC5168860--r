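# Cluster post-processing: contigs are atomic units of an assembly, so windows
# of one contig scattered over several clusters indicate an unstable clustering,
# and clusters holding almost no assembled sequence are treated as outliers.

#' Reassign every contig's windows to its plurality cluster
#'
#' Disregarding chimeras, a contig belongs to exactly one organism, so all its
#' windows are relabelled to the cluster holding most of them. Ties are broken
#' towards the cluster with more rows overall, then towards the smaller label.
#' The operation is idempotent and never increases the number of distinct
#' labels.
#'
#' @param labels Integer cluster label per window.
#' @param contig_ids Contig of origin per window.
#' @return Integer labels, contig-consistent.
#' @export
reassign_by_contig <- function(labels, contig_ids) {
  if (length(labels) != length(contig_ids))
    stop("`labels` and `contig_ids` lengths differ", call. = FALSE)
  labels <- as.integer(labels)
  global <- table(labels)
  pick <- function(ls) {
    t <- table(ls)
    cand <- names(t)[t == max(t)]
    if (length(cand) > 1) {
      g <- global[cand]
      cand <- cand[g == max(g)]
    }
    min(as.integer(cand))
  }
  winner <- vapply(split(labels, contig_ids), pick, integer(1))
  unname(winner[as.character(contig_ids)])
}

#' Suppress clusters below the aggressive bp threshold
#'
#' Clusters whose contigs total fewer than `min_cluster_bp` assembled bases
#' become outliers (label 0); they are excluded from contamination confidences
#' and cleansing but kept in reports. A cluster holding exactly
#' `min_cluster_bp` bases is retained. If every cluster falls below the
#' threshold the largest one (by bp; ties towards the smaller label) is
#' retained so the result is never empty. Must run after
#' [reassign_by_contig()] so each contig carries one label.
#'
#' @param labels Integer cluster label per window (contig-consistent).
#' @param contig_ids Contig of origin per window.
#' @param contig_lengths Named integer vector of contig lengths in bp.
#' @param min_cluster_bp Threshold in bp (default 5000).
#' @return An object of class `cluster_assignment`: list with
#'   \describe{
#'     \item{labels}{integer label per window, 0 = outlier}
#'     \item{retained}{sorted integer vector of retained cluster labels}
#'     \item{cluster_bp}{named numeric vector, bp per retained cluster}
#'     \item{outlier_bp}{bp held by outlier windows' contigs}
#'     \item{contigs}{named list: contig ids per retained cluster}
#'     \item{outlier_contigs}{contig ids set aside as outliers}
#'   }
#' @export
filter_small_clusters <- function(labels, contig_ids, contig_lengths,
                                  min_cluster_bp = 5000) {
  labels <- as.integer(labels)
  contig_label <- vapply(split(labels, contig_ids), function(x) {
    u <- unique(x)
    if (length(u) != 1)
      stop("labels are not contig-consistent; run reassign_by_contig() first",
           call. = FALSE)
    u
  }, integer(1))
  if (!all(names(contig_label) %in% names(contig_lengths)))
    stop("`contig_lengths` is missing some contigs", call. = FALSE)
  bp <- tapply(as.double(contig_lengths[names(contig_label)]), contig_label, sum)
  ids <- as.integer(names(bp))
  keep <- ids[bp >= min_cluster_bp]
  if (length(keep) == 0) {  # never return an empty clustering
    mx <- max(bp)
    keep <- min(ids[bp == mx])
  }
  out_labels <- ifelse(labels %in% keep, labels, 0L)
  keep <- sort(keep)
  cluster_bp <- stats::setNames(as.numeric(bp[as.character(keep)]), keep)
  contigs <- lapply(keep, function(k) names(contig_label)[contig_label == k])
  names(contigs) <- keep
  outlier_contigs <- names(contig_label)[!contig_label %in% keep]
  structure(list(labels = out_labels, retained = keep, cluster_bp = cluster_bp,
                 outlier_bp = sum(as.double(contig_lengths[outlier_contigs])),
                 contigs = contigs, outlier_contigs = outlier_contigs),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster assignment: %d retained cluster(s), %d outlier contig(s)\n",
              length(x$retained), length(x$outlier_contigs)))
  for (k in seq_along(x$retained))
    cat(sprintf("  cluster %d: %d contigs, %s bp\n", x$retained[k],
                length(x$contigs[[k]]),
                format(x$cluster_bp[[k]], big.mark = ",")))
  if (x$outlier_bp > 0)
    cat(sprintf("  outliers: %s bp\n", format(x$outlier_bp, big.mark = ",")))
  invisible(x)
}
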