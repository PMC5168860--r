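#' Ward clustering of embedded points
#'
#' Agglomerative hierarchical clustering with Ward's criterion on the
#' Euclidean 2-D coordinates, cut at `k` clusters. Deterministic for fixed
#' input.
#'
#' @param coords Numeric matrix of 2-D coordinates.
#' @param k Number of clusters (<= number of points).
#' @return Integer cluster labels (1..k).
#' @export
ward_clusters <- function(coords, k) {
  coords <- as.matrix(coords)
  k <- stopifnot_scalar_count(k, "k")
  if (k > nrow(coords)) stop("`k` exceeds the number of points", call. = FALSE)
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  as.integer(stats::cutree(hc, k = k))
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j)` where `c_i` is
#' the centroid of cluster i, `s_i` the mean Euclidean distance of its members
#' to the centroid, and `d` the centroid distance. Lower is better. Outlier
#' rows (label 0) are ignored.
#'
#' @param coords Numeric matrix of 2-D coordinates.
#' @param labels Integer cluster labels (0 = outlier); at least two non-empty
#'   non-outlier clusters.
#' @return The index (scalar).
#' @examples
#' pts <- rbind(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)),
#'              cbind(10 + c(1, -1, 0, 0), c(0, 0, 1, -1)))
#' davies_bouldin(pts, rep(1:2, each = 4))  # (1 + 1) / 10 = 0.2
#' @export
davies_bouldin <- function(coords, labels) {
  coords <- as.matrix(coords)
  keep <- labels != 0L
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2) stop("need at least two non-outlier clusters", call. = FALSE)
  cent <- t(vapply(ids, function(i) colMeans(coords[labels == i, , drop = FALSE]),
                   numeric(ncol(coords))))
  scat <- vapply(seq_len(k), function(i) {
    m <- coords[labels == ids[i], , drop = FALSE]
    mean(sqrt(rowSums((m - matrix(cent[i, ], nrow(m), ncol(m), byrow = TRUE))^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(cent))
  if (any(dc[upper.tri(dc)] == 0))
    stop("coincident cluster centroids: Davies-Bouldin undefined", call. = FALSE)
  r <- vapply(seq_len(k), function(i) {
    max((scat[i] + scat[-i]) / dc[i, -i])
  }, numeric(1))
  mean(r)
}

#' Split a contaminated assembly into per-cluster FASTA files
#'
#' Estimates the number of clusters on the full-data embedding by Ward
#' clustering over `k in k_min..k_max`, post-processing each cut (contig
#' reassignment, bp filter) and scoring the post-processed assignment with the
#' Davies-Bouldin index; the `k` minimising the index wins (ties towards
#' smaller `k`). Contigs of each retained cluster are exported to
#' `<sample>.cluster<j>.fasta`, outlier contigs to `<sample>.outliers.fasta`.
#' Every input contig appears in exactly one output file.
#'
#' When post-processing collapses every cut to a single cluster the result is
#' flagged inconclusive and the whole assembly is exported as one cluster.
#'
#' @param contigs Named character vector of sequences (or FASTA path).
#' @param coords Full-data embedding of the assembly's signature rows.
#' @param provenance Provenance data.frame of the signature matrix (row order
#'   must match `coords`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param k_min,k_max Range of cluster numbers to score (defaults 2 and 5).
#' @param min_cluster_bp Outlier threshold in bp (default 5000).
#' @param output_dir Directory for FASTA export, or `NULL` to skip writing.
#' @param sample_name Stem for output file names.
#' @return An object of class `cleansing_result`: list with `chosen_k`,
#'   `db_by_k` (named numeric, NA where undefined), `assignment`
#'   (a `cluster_assignment`), `clusters` (contig ids per exported cluster),
#'   `outlier_contigs`, `inconclusive` and `files` (paths written, if any).
#' @export
cleanse <- function(contigs, coords, provenance, contig_lengths,
                    k_min = 2, k_max = 5, min_cluster_bp = 5000,
                    output_dir = NULL, sample_name = "sample") {
  contigs <- as_contigs(contigs)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(provenance))
    stop("`coords` and `provenance` row counts differ", call. = FALSE)
  k_min <- stopifnot_scalar_count(k_min, "k_min", min = 2)
  k_max <- stopifnot_scalar_count(k_max, "k_max", min = k_min)
  ks <- seq.int(k_min, min(k_max, nrow(coords)))

  db <- stats::setNames(rep(NA_real_, length(ks)), ks)
  asgs <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    labels <- ward_clusters(coords, ks[i])
    labels <- reassign_by_contig(labels, provenance$contig_id)
    asg <- filter_small_clusters(labels, provenance$contig_id, contig_lengths,
                                 min_cluster_bp)
    asgs[[i]] <- asg
    if (length(asg$retained) >= 2) {
      db[i] <- tryCatch(davies_bouldin(coords, asg$labels),
                        error = function(e) NA_real_)
    }
  }
  inconclusive <- all(is.na(db))
  if (inconclusive) {
    chosen_k <- NA_integer_
    clusters <- list(`1` = names(contigs))
    outlier_contigs <- character()
    assignment <- NULL
  } else {
    chosen_k <- ks[which.min(db)]   # which.min takes the first (smallest k) on ties
    assignment <- asgs[[match(chosen_k, ks)]]
    clusters <- assignment$contigs
    names(clusters) <- seq_along(clusters)   # exported cluster numbering 1..K
    outlier_contigs <- assignment$outlier_contigs
  }

  files <- character()
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(clusters)) {
      f <- file.path(output_dir, sprintf("%s.cluster%s.fasta", sample_name, names(clusters)[j]))
      write_contigs(contigs[clusters[[j]]], f)
      files <- c(files, f)
    }
    if (length(outlier_contigs) > 0) {
      f <- file.path(output_dir, sprintf("%s.outliers.fasta", sample_name))
      write_contigs(contigs[outlier_contigs], f)
      files <- c(files, f)
    }
  }
  structure(list(chosen_k = chosen_k, db_by_k = db, assignment = assignment,
                 clusters = clusters, outlier_contigs = outlier_contigs,
                 inconclusive = inconclusive, files = files),
            class = "cleansing_result")
}

#' @export
print.cleansing_result <- function(x, ...) {
  if (x$inconclusive) {
    cat("cleansing inconclusive: post-processing left a single cluster for every k\n")
  } else {
    cat(sprintf("cleansing: chose k = %d (Davies-Bouldin %s)\n", x$chosen_k,
                paste(sprintf("k=%s: %.3f", names(x$db_by_k), x$db_by_k),
                      collapse = ", ")))
    for (j in seq_along(x$clusters))
      cat(sprintf("  cluster %s: %d contigs\n", names(x$clusters)[j],
                  length(x$clusters[[j]])))
    if (length(x$outlier_contigs) > 0)
      cat(sprintf("  outliers: %d contigs\n", length(x$outlier_contigs)))
  }
  invisible(x)
}
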