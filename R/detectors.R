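#' Dip detector: per-point multimodality of pairwise distances
#'
#' Every point in the 2-D embedding acts as a "viewer": the vector of its
#' Euclidean distances to all other points is tested for multimodality with
#' the dip test ([dip_statistic()]), against a Monte-Carlo uniform null.
#' A viewer splits when its dip p-value is at most `alpha`; the embedding is
#' called contaminated when the fraction of splitting viewers exceeds
#' `t_dip`. With the defaults (`t_dip = 0.001`) a single splitting viewer
#' flags typical embeddings, which makes the detector sensitive to large,
#' possibly overlapping clusters.
#'
#' @param coords Numeric matrix of 2-D coordinates (n x 2, n >= 4).
#' @param t_dip Split-viewer fraction above which the sample is flagged
#'   (default 0.001).
#' @param alpha Per-viewer significance level (default 0.001).
#' @param null_reps Monte-Carlo replicates for the dip null (default 1000).
#' @param seed Seed for the null table.
#' @return An object of class `detector_result`: list with `method` ("DIP"),
#'   `contaminated`, `detail` (the split fraction), `split_fraction`,
#'   `n_split`, and `threshold` (the critical dip value).
#' @export
dip_detector <- function(coords, t_dip = 0.001, alpha = 0.001,
                         null_reps = 1000, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (t_dip < 0 || t_dip > 1) stop("`t_dip` must be in [0, 1]", call. = FALSE)
  # p(dip) = (share of null dips >= dip) <= alpha  <=>  dip > (k+1)-th largest
  # null dip, with k = floor(alpha * null_reps); the comparison is exact, so
  # the split decision needs only a feasibility test per viewer
  tstar <- dip_null_quantile(n - 1, null_reps, alpha, seed)
  splits <- .dip_rows_exceed_cpp(as.matrix(stats::dist(coords)), tstar)
  frac <- mean(splits)
  structure(list(method = "DIP", contaminated = frac > t_dip, detail = frac,
                 split_fraction = frac, n_split = sum(splits),
                 threshold = tstar),
            class = "detector_result")
}

# mutual k-nearest-neighbour edges of a 2-D point set (Euclidean); each edge
# (i, j) requires i among j's k nearest AND j among i's
mutual_knn_edges <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(coords, k = k)$nn.index
  from <- rep.int(seq_len(n), k)
  to <- as.vector(nn)
  key <- paste(pmin(from, to), pmax(from, to))
  counted <- table(key)
  # a mutual pair appears exactly twice (i->j and j->i)
  mutual <- names(counted)[counted == 2L]
  if (length(mutual) == 0) return(matrix(integer(), ncol = 2))
  parts <- strsplit(mutual, " ", fixed = TRUE)
  cbind(as.integer(vapply(parts, `[[`, character(1), 1L)),
        as.integer(vapply(parts, `[[`, character(1), 2L)))
}

#' CC detector: components of the mutual k-NN graph
#'
#' Builds the mutual `k_cc`-nearest-neighbour graph of the embedding (an edge
#' requires both endpoints to list each other among their `k_cc` nearest
#' neighbours, Euclidean in 2-D) and labels points by connected component.
#' Components are then repaired by contig identity
#' ([reassign_by_contig()]) and components holding fewer than `min_cluster_bp`
#' assembled bases are set aside as outliers ([filter_small_clusters()]). The
#' embedding is called contaminated when more than one component remains, which
#' makes the detector sensitive to small, well-separated contamination.
#'
#' @param coords Numeric matrix of 2-D coordinates (n x 2, n >= 2).
#' @param contig_ids Character vector: contig of origin per row of `coords`.
#' @param contig_lengths Named integer vector of contig lengths in bp.
#' @param k_cc Mutual neighbour count (default 9).
#' @param min_cluster_bp Minimum assembled bases a cluster may hold
#'   (default 5000).
#' @return An object of class `detector_result`: list with `method` ("CC"),
#'   `contaminated`, `detail` (the retained component count), `n_components`
#'   (before post-processing) and `assignment` (a `cluster_assignment`).
#' @export
cc_detector <- function(coords, contig_ids, contig_lengths, k_cc = 9,
                        min_cluster_bp = 5000) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (length(contig_ids) != n) stop("`contig_ids` must match rows of `coords`", call. = FALSE)
  k_cc <- stopifnot_scalar_count(k_cc, "k_cc")
  edges <- mutual_knn_edges(coords, k_cc)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  labels <- as.integer(igraph::components(g)$membership)
  ncomp <- max(labels)
  labels <- reassign_by_contig(labels, contig_ids)
  asg <- filter_small_clusters(labels, contig_ids, contig_lengths, min_cluster_bp)
  retained <- length(asg$retained)
  structure(list(method = "CC", contaminated = retained > 1, detail = retained,
                 n_components = ncomp, assignment = asg),
            class = "detector_result")
}

#' @export
print.detector_result <- function(x, ...) {
  what <- if (x$method == "DIP") sprintf("split fraction %.4f", x$detail)
          else sprintf("%d retained cluster(s)", x$detail)
  cat(sprintf("%s detector: %s -> %s\n", x$method, what,
              if (x$contaminated) "contaminated" else "no contamination"))
  invisible(x)
}
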