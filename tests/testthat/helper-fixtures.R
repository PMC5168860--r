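# shared fixtures built in code

# a signature_matrix-shaped object from an arbitrary feature matrix, with block
# pseudo-contig provenance (rows_per_contig consecutive rows per contig)
fake_signatures <- function(freq, rows_per_contig = 20, contig_bp = 10000) {
  n <- nrow(freq)
  ids <- sprintf("c%03d", rep(seq_len(ceiling(n / rows_per_contig)),
                              each = rows_per_contig)[seq_len(n)])
  lens <- stats::setNames(rep(contig_bp, length(unique(ids))), unique(ids))
  structure(list(
    freq = as.matrix(freq),
    provenance = data.frame(contig_id = ids, start = 0L, end = 0L, width = 0L),
    contig_lengths = lens,
    config = structure(list(n = n, w = contig_bp, dw = contig_bp %/% 2, k = 4),
                       class = "window_config"),
    dropped = data.frame(contig_id = character(), start = integer(),
                         end = integer(), width = integer())),
    class = "signature_matrix")
}

# block contig ids for bare coordinate fixtures
block_contigs <- function(n, per = 50, prefix = "c") {
  sprintf("%s%03d", prefix, rep(seq_len(ceiling(n / per)), each = per)[seq_len(n)])
}

uniform_bp <- function(ids, bp = 25000) {
  stats::setNames(rep(bp, length(unique(ids))), unique(ids))
}

# an isotropic Gaussian cloud in signature space: the null (single organism)
# fixture for the detector stack
blob_signatures <- function(n = 400, dims = 16, sd = 0.02, seed = 1) {
  set.seed(seed)
  freq <- matrix(stats::rnorm(n * dims, mean = 0.5, sd = sd), n, dims)
  fake_signatures(freq, rows_per_contig = 20, contig_bp = 10000)
}

# small two- or three-genome synthetic assemblies for end-to-end tests (scaled
# study conditions: 150 kb per genome unless stated otherwise)
mixture_sample <- function(gcs, seed, total_bp = 150000) {
  models <- lapply(seq_along(gcs), function(i)
    genome_model(paste0("g", i), gc = gcs[i], total_bp = total_bp))
  generate_sample(models, seed = seed)
}

# bp-weighted purity of exported clusters against ground-truth genome labels
cluster_purity <- function(clusters, truth, contig_lengths) {
  vapply(clusters, function(ids) {
    bp <- tapply(as.double(contig_lengths[ids]), truth[ids], sum)
    max(bp) / sum(bp)
  }, numeric(1))
}

# reverse complement of a DNA string (test-side oracle)
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
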