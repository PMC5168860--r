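#' Window configuration for signature extraction
#'
#' The window width is chosen so that the assembly yields a target number of
#' data points: `w = max(1, floor(sum(lengths) / n))`, with step
#' `dw = max(1, floor(w / 2))` (50\% overlap). Contigs shorter than `w`
#' contribute a single window covering the whole contig, so no contig is
#' discarded.
#'
#' @param lengths Integer vector of contig lengths in bp (all >= 1).
#' @param n Target number of data points (default 1000).
#' @param k Word length of the signature k-mers (default 4, tetramers).
#' @return An object of class `window_config`: list with `n`, `w`, `dw`, `k`.
#' @examples
#' window_config(c(5000, 3000, 2000), n = 10)  # w = 1000, dw = 500
#' @export
window_config <- function(lengths, n = 1000, k = 4) {
  if (length(lengths) == 0) stop("no contig lengths given", call. = FALSE)
  if (any(lengths < 1)) stop("contig lengths must be >= 1", call. = FALSE)
  n <- stopifnot_scalar_count(n, "n")
  k <- stopifnot_scalar_count(k, "k")
  w <- max(1L, as.integer(floor(sum(as.double(lengths)) / n)))
  structure(list(n = n, w = w, dw = max(1L, w %/% 2L), k = k),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("window config: target n = %d, width w = %d bp, step = %d bp, k = %d\n",
              x$n, x$w, x$dw, x$k))
  invisible(x)
}

#' Canonical k-mer map
#'
#' Partitions the 4^k words over \{A, C, G, T\} into equivalence classes under
#' reverse complementation, so both strands of a sequence produce the same
#' signature. Each class is represented by its lexicographically smallest
#' member; classes are ordered by representative. For k = 4 the 256 tetramers
#' collapse to 136 classes; k = 1 gives the two classes A/T and C/G (GC
#' content).
#'
#' @param k Word length, 1 to 8.
#' @return An object of class `canonical_kmer_map`: list with `k`, `n_classes`,
#'   `classes` (representative words, in order) and `class_of` (integer vector
#'   of length 4^k mapping each word index, in lexicographic order, to its
#'   class).
#' @examples
#' canonical_kmer_map(4)$n_classes  # 136
#' @export
canonical_kmer_map <- function(k) {
  k <- stopifnot_scalar_count(k, "k")
  if (k > 8) stop("k must be <= 8", call. = FALSE)
  nw <- 4L^k
  idx <- 0:(nw - 1)
  # base-4 digits, most significant first; A=0 < C=1 < G=2 < T=3 matches
  # lexicographic word order
  pow <- 4L^((k - 1):0)
  rc <- integer(nw)
  for (pos in seq_len(k)) {
    digit <- (idx %/% pow[pos]) %% 4L
    rc <- rc + (3L - digit) * pow[k + 1 - pos]   # complement and reverse
  }
  canon <- pmin(idx, rc)
  reps <- sort(unique(canon))
  class_of <- match(canon, reps)
  bases <- c("A", "C", "G", "T")
  words <- vapply(reps, function(i) {
    paste(bases[((i %/% pow) %% 4L) + 1L], collapse = "")
  }, character(1))
  structure(list(k = k, n_classes = length(reps), classes = words,
                 class_of = class_of),
            class = "canonical_kmer_map")
}

#' @export
print.canonical_kmer_map <- function(x, ...) {
  cat(sprintf("canonical %d-mer map: %d words in %d reverse-complement classes\n",
              x$k, 4L^x$k, x$n_classes))
  invisible(x)
}

#' Sliding window spans over a contig
#'
#' Returns 0-based half-open spans (BED-style). A contig shorter than the
#' window width yields a single span covering the whole contig; otherwise the
#' window is shifted by `cfg$dw` while it still fits. A trailing remainder
#' shorter than the step is not given an extra window (the 50\% overlap already
#' covers most of it).
#'
#' @param length Contig length in bp.
#' @param cfg A [window_config()].
#' @return data.frame with columns `start` and `end` (0-based, half-open).
#' @examples
#' nrow(sliding_windows(10000, window_config(10000, n = 10)))  # 19 spans
#' @export
sliding_windows <- function(length, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  length <- stopifnot_scalar_count(length, "length")
  if (length < cfg$w) return(data.frame(start = 0L, end = length))
  starts <- seq.int(0L, length - cfg$w, by = cfg$dw)
  data.frame(start = starts, end = starts + cfg$w)
}

#' Canonical k-mer signature of a single sequence window
#'
#' Counts the k-mers made of plain A/C/G/T only (windows may contain ambiguous
#' bases, which invalidate any k-mer overlapping them) under the canonical
#' classes of `map` and normalises the counts to frequencies.
#'
#' @param seq A DNA string (character scalar).
#' @param map A [canonical_kmer_map()].
#' @return Named numeric vector of length `map$n_classes` summing to 1, or
#'   `NULL` when the window contains no valid k-mer.
#' @examples
#' window_signature("ACGT", canonical_kmer_map(4))["ACGT"]  # 1
#' @export
window_signature <- function(seq, map) {
  stopifnot(inherits(map, "canonical_kmer_map"))
  if (!is.character(seq) || length(seq) != 1) stop("`seq` must be a single string", call. = FALSE)
  if (nchar(seq) < map$k) stop("window shorter than k", call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(seq)), width = map$k)
  total <- sum(counts)
  if (total == 0) return(NULL)
  v <- as.numeric(rowsum(as.numeric(counts), map$class_of))
  names(v) <- map$classes
  v / total
}

#' Windowed canonical k-mer signature matrix of an assembly
#'
#' Slides a window over every contig ([sliding_windows()]) and computes one
#' canonical k-mer frequency vector per window. Windows without a single valid
#' k-mer (e.g. all ambiguous bases) are dropped and recorded. Rows are ordered
#' by contig (input order), then window start.
#'
#' @param contigs FASTA path, named character vector of sequences, or a
#'   [generate_sample()] result.
#' @param n Target number of data points used to derive the window width
#'   (default 1000); ignored when `cfg` is given.
#' @param k Word length (default 4); ignored when `cfg` is given.
#' @param cfg Optional [window_config()] overriding `n` and `k`.
#' @param map Optional [canonical_kmer_map()] (must match `cfg$k`).
#' @return An object of class `signature_matrix`: list with
#'   \describe{
#'     \item{freq}{numeric matrix, one row per window, one column per
#'       canonical class (columns named by representative word); rows sum to 1}
#'     \item{provenance}{data.frame with `contig_id`, `start`, `end` (0-based,
#'       half-open) and `width` per row}
#'     \item{contig_lengths}{named integer vector of contig lengths}
#'     \item{config}{the [window_config()] used}
#'     \item{dropped}{data.frame of dropped windows (same columns as
#'       `provenance`)}
#'   }
#' @export
signature_matrix <- function(contigs, n = 1000, k = 4, cfg = NULL, map = NULL) {
  contigs <- as_contigs(contigs)
  lens <- nchar(contigs)
  cfg <- cfg %||% window_config(lens, n = n, k = k)
  map <- map %||% canonical_kmer_map(cfg$k)
  if (map$k != cfg$k) stop("`map` and `cfg` disagree on k", call. = FALSE)

  rows <- vector("list", length(contigs))
  prov <- vector("list", length(contigs))
  dropped <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    id <- names(contigs)[ci]
    spans <- sliding_windows(lens[[ci]], cfg)
    if (lens[[ci]] < cfg$k) {   # window too short for any k-mer
      dropped[[ci]] <- data.frame(contig_id = id, spans, width = spans$end - spans$start)
      next
    }
    xs <- Biostrings::DNAString(contigs[[ci]])
    v <- Biostrings::Views(xs, start = spans$start + 1L, end = spans$end)
    counts <- Biostrings::oligonucleotideFrequency(v, width = cfg$k)
    valid <- rowSums(counts)
    keep <- valid > 0
    pr <- data.frame(contig_id = id, spans, width = spans$end - spans$start)
    if (any(!keep)) dropped[[ci]] <- pr[!keep, , drop = FALSE]
    if (!any(keep)) next
    # collapse the 4^k columns onto canonical classes, then normalise per row
    cc <- t(rowsum(t(counts[keep, , drop = FALSE]), map$class_of))
    rows[[ci]] <- cc / valid[keep]
    prov[[ci]] <- pr[keep, , drop = FALSE]
  }
  freq <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(freq) || nrow(freq) == 0)
    stop("no usable sequence: every window was dropped", call. = FALSE)
  colnames(freq) <- map$classes
  rownames(freq) <- NULL
  provenance <- do.call(rbind, prov[!vapply(prov, is.null, logical(1))])
  rownames(provenance) <- NULL
  dropped <- if (any(!vapply(dropped, is.null, logical(1)))) {
    d <- do.call(rbind, dropped[!vapply(dropped, is.null, logical(1))])
    rownames(d) <- NULL
    d
  } else {
    data.frame(contig_id = character(), start = integer(), end = integer(),
               width = integer())
  }
  structure(list(freq = freq, provenance = provenance,
                 contig_lengths = stats::setNames(as.integer(lens), names(contigs)),
                 config = cfg, dropped = dropped),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf(paste0("signature matrix: %d windows x %d canonical %d-mer classes",
                     " from %d contigs (%s bp; %d windows dropped)\n"),
              nrow(x$freq), ncol(x$freq), x$config$k, length(x$contig_lengths),
              format(sum(x$contig_lengths), big.mark = ","), nrow(x$dropped)))
  invisible(x)
}

#' Export a signature matrix as TSV
#'
#' Columns: `contig_id`, `start`, `end`, then one column per canonical class
#' named by its representative word.
#'
#' @param sig A [signature_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  df <- cbind(sig$provenance[c("contig_id", "start", "end")],
              as.data.frame(sig$freq, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
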