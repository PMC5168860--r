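#' Read contigs from a FASTA file
#'
#' Reads a multi-record FASTA assembly into a named character vector of
#' uppercase DNA sequences. The contig id is the first whitespace-delimited
#' token of each header; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are contig ids).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GGGG"), fa)
#' read_contigs(fa)
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate contig id in FASTA file: ", dup, call. = FALSE)
  }
  if (any(Biostrings::width(set) < 1)) stop("empty sequence record in FASTA file", call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write contigs to a FASTA file
#'
#' @param contigs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(contigs)
  names(set) <- names(contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# coerce the accepted contig inputs (path, named character vector, or a
# synthetic sample) to a named character vector
as_contigs <- function(x) {
  if (inherits(x, "synthetic_sample")) return(x$contigs)
  if (is.character(x) && length(x) == 1 && is.null(names(x))) return(read_contigs(x))
  if (is.character(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("contigs must be uniquely named", call. = FALSE)
    return(toupper(x))
  }
  stop("cannot interpret `x` as contigs: give a FASTA path or a named character vector",
       call. = FALSE)
}
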