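#' Nucleotide-composition genome model for synthetic assemblies
#'
#' Describes one genome by either an order-0 base composition (`base_probs` or
#' the `gc` shorthand, which spreads the GC fraction evenly over C and G) or an
#' order-1 Markov `transition` matrix, plus a contig length law. Synthetic
#' assemblies built from such models carry genome-characteristic tetramer
#' signatures whose separation is controlled by the composition distance
#' between models, emulating contaminants of varying relatedness.
#'
#' @param id Genome identifier.
#' @param gc GC content shorthand; sets `base_probs` to
#'   `((1-gc)/2, gc/2, gc/2, (1-gc)/2)` over A, C, G, T.
#' @param base_probs Numeric length-4 probability vector over A, C, G, T.
#' @param transition Optional 4x4 row-stochastic matrix (order-1 model,
#'   rows/columns in A, C, G, T order); overrides `base_probs` for sequence
#'   generation (which then starts from `base_probs` or uniform).
#' @param total_bp Total assembled bases to generate (default 500000).
#' @param contig_min,contig_max Contig length bounds in bp (defaults 5000 and
#'   50000, typical single-cell assembly contig sizes).
#' @param length_law Contig length distribution between the bounds:
#'   `"uniform"` or `"lognormal"` (clamped to the bounds).
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(id, gc = NULL, base_probs = NULL, transition = NULL,
                         total_bp = 500000, contig_min = 5000,
                         contig_max = 50000,
                         length_law = c("uniform", "lognormal")) {
  length_law <- match.arg(length_law)
  if (!is.null(gc)) {
    if (!is.null(base_probs)) stop("give either `gc` or `base_probs`", call. = FALSE)
    if (gc < 0 || gc > 1) stop("`gc` must be in [0, 1]", call. = FALSE)
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  }
  if (is.null(base_probs) && is.null(transition))
    stop("give `gc`, `base_probs` or `transition`", call. = FALSE)
  if (!is.null(base_probs)) {
    if (length(base_probs) != 4 || any(base_probs < 0) ||
        abs(sum(base_probs) - 1) > 1e-9)
      stop("`base_probs` must be 4 non-negative values summing to 1", call. = FALSE)
    base_probs <- stats::setNames(as.numeric(base_probs), c("A", "C", "G", "T"))
  }
  if (!is.null(transition)) {
    transition <- as.matrix(transition)
    if (!all(dim(transition) == 4) || any(transition < 0) ||
        any(abs(rowSums(transition) - 1) > 1e-9))
      stop("`transition` must be a 4x4 row-stochastic matrix", call. = FALSE)
  }
  total_bp <- stopifnot_scalar_count(total_bp, "total_bp")
  contig_min <- stopifnot_scalar_count(contig_min, "contig_min")
  contig_max <- stopifnot_scalar_count(contig_max, "contig_max")
  if (contig_min > contig_max) stop("`contig_min` > `contig_max`", call. = FALSE)
  if (total_bp < contig_min) stop("`total_bp` smaller than `contig_min`", call. = FALSE)
  structure(list(id = as.character(id), base_probs = base_probs,
                 transition = transition, total_bp = total_bp,
                 contig_min = contig_min, contig_max = contig_max,
                 length_law = length_law),
            class = "genome_model")
}

draw_contig_lengths <- function(model) {
  lens <- integer()
  total <- 0
  while (total < model$total_bp) {
    l <- switch(model$length_law,
      uniform = sample.int(model$contig_max - model$contig_min + 1L, 1L) +
        model$contig_min - 1L,
      lognormal = {
        mu <- mean(log(c(model$contig_min, model$contig_max)))
        sdl <- (log(model$contig_max) - log(model$contig_min)) / 4
        as.integer(pmin(pmax(round(stats::rlnorm(1, mu, sdl)),
                             model$contig_min), model$contig_max))
      })
    lens <- c(lens, l)
    total <- total + l
  }
  lens
}

draw_sequence <- function(model, len) {
  bases <- c("A", "C", "G", "T")
  if (is.null(model$transition)) {
    paste(sample(bases, len, replace = TRUE, prob = model$base_probs),
          collapse = "")
  } else {
    init <- model$base_probs %||% rep(0.25, 4)
    paste(bases[.markov_chain_cpp(model$transition, init, len)], collapse = "")
  }
}

#' Generate a synthetic assembly with ground-truth labels
#'
#' Draws contigs independently per genome model (lengths from the model's law
#' until its `total_bp` is reached, bases from its composition model), shuffles
#' them into one assembly and records the genome of origin of every contig.
#' Deterministic per seed.
#'
#' @param models A [genome_model()] or list of them.
#' @param seed Integer seed.
#' @return An object of class `synthetic_sample`: list with `contigs` (named
#'   character vector), `truth` (named character vector contig id -> genome
#'   id), `seed` and `models`.
#' @export
generate_sample <- function(models, seed = 1L) {
  if (inherits(models, "genome_model")) models <- list(models)
  if (length(models) == 0 || !all(vapply(models, inherits, logical(1), "genome_model")))
    stop("`models` must be genome_model objects", call. = FALSE)
  with_seed(seed, {
    seqs <- character()
    genome <- character()
    for (m in models) {
      lens <- draw_contig_lengths(m)
      for (l in lens) {
        seqs <- c(seqs, draw_sequence(m, l))
        genome <- c(genome, m$id)
      }
    }
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]
    genome <- genome[ord]
    ids <- sprintf("contig_%04d", seq_along(seqs))
    names(seqs) <- ids
    structure(list(contigs = seqs,
                   truth = stats::setNames(genome, ids),
                   seed = as.integer(seed), models = models),
              class = "synthetic_sample")
  })
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("synthetic assembly: %d contigs, %s bp, %d genome(s) [seed %d]\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              length(unique(x$truth)), x$seed))
  invisible(x)
}

#' Write a synthetic sample to FASTA (and its truth table to TSV)
#'
#' @param sample A [generate_sample()] result.
#' @param fasta Output FASTA path.
#' @param truth_path Optional TSV path for the contig -> genome table.
#' @return `fasta`, invisibly.
#' @export
write_sample <- function(sample, fasta, truth_path = NULL) {
  stopifnot(inherits(sample, "synthetic_sample"))
  write_contigs(sample$contigs, fasta)
  if (!is.null(truth_path)) {
    write.table(data.frame(contig_id = names(sample$truth),
                           genome_id = unname(sample$truth)),
                truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
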