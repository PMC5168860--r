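#' Export screening results to an output directory
#'
#' Writes `report.json` (verdict, confidences, per-fold flags, parameters,
#' cleansing summary), `coords.tsv` (row provenance plus the 2-D embedding)
#' and, when a cleansing result is present, one FASTA per retained cluster
#' plus an outlier FASTA. Deterministic except for the `generated` timestamp
#' field of the report.
#'
#' @param scr A [screen_assembly()] result.
#' @param output_dir Output directory (created if needed).
#' @param annotations Optional data.frame (`contig_id`, `taxon`) from an
#'   external classifier, echoed per contig into the report. The package never
#'   runs external tools itself.
#' @return The report list, invisibly (with `exit_code`: 0 clean,
#'   2 contaminated, 3 warning).
#' @export
export_results <- function(scr, output_dir, annotations = NULL) {
  stopifnot(inherits(scr, "contam_screen"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  coords <- data.frame(scr$signatures$provenance,
                       x = scr$embedding[, 1], y = scr$embedding[, 2])
  write.table(coords, file.path(output_dir, "coords.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- character()
  if (!is.null(scr$cleansing)) {
    cln <- cleanse_export(scr, output_dir)
    files <- cln$files
  }

  report <- build_report(scr, annotations, files)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(report)
}

# re-export cluster FASTAs from a stored cleansing result
cleanse_export <- function(scr, output_dir) {
  cln <- scr$cleansing
  files <- character()
  for (j in seq_along(cln$clusters)) {
    f <- file.path(output_dir,
                   sprintf("%s.cluster%s.fasta", scr$sample, names(cln$clusters)[j]))
    write_contigs(scr$contigs[cln$clusters[[j]]], f)
    files <- c(files, f)
  }
  if (length(cln$outlier_contigs) > 0) {
    f <- file.path(output_dir, sprintf("%s.outliers.fasta", scr$sample))
    write_contigs(scr$contigs[cln$outlier_contigs], f)
    files <- c(files, f)
  }
  list(files = files)
}

build_report <- function(scr, annotations = NULL, files = character()) {
  conf <- scr$confidence
  cln <- scr$cleansing
  report <- list(
    sample = scr$sample,
    tool = "scscreen",
    version = scr$version,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = scr$params$seed,
    params = scr$params,
    contigs = length(scr$contigs),
    total_bp = sum(scr$signatures$contig_lengths),
    rows = nrow(scr$signatures$freq),
    window_bp = scr$signatures$config$w,
    window_step_bp = scr$signatures$config$dw,
    dropped_windows = nrow(scr$signatures$dropped),
    dip_confidence = conf$dip_confidence,
    cc_confidence = conf$cc_confidence,
    status = conf$status,
    folds = conf$folds[c("fold", "rows", "ok", "dip", "cc", "dip_fraction",
                         "cc_clusters")],
    cleansing = if (!is.null(cln)) list(
      inconclusive = cln$inconclusive,
      chosen_k = cln$chosen_k,
      db_by_k = as.list(cln$db_by_k),
      clusters = lapply(seq_along(cln$clusters), function(j) list(
        id = names(cln$clusters)[j],
        contigs = cln$clusters[[j]],
        bp = sum(scr$signatures$contig_lengths[cln$clusters[[j]]]))),
      outlier_contigs = cln$outlier_contigs),
    files = files)
  if (!is.null(annotations)) {
    if (!all(c("contig_id", "taxon") %in% names(annotations)))
      stop("`annotations` needs columns contig_id and taxon", call. = FALSE)
    report$annotations <- annotations[annotations$contig_id %in% names(scr$contigs),
                                      c("contig_id", "taxon")]
  }
  report$exit_code <- switch(conf$status, clean = 0L, contaminated = 2L,
                             warning = 3L)
  report
}

#' Run the full screening pipeline on a FASTA file
#'
#' Convenience wrapper: [screen_assembly()] followed by [export_results()].
#' Mirrors the command-line interface (`inst/cli/scscreen.R`), whose exit code
#' is 0 for a clean verdict, 2 for contaminated, 3 for warning and 1 for an
#' error.
#'
#' @param input Input FASTA path.
#' @param output_dir Output directory.
#' @param ... Passed to [screen_assembly()].
#' @param annotations Optional annotation TSV path or data.frame
#'   (`contig_id`, `taxon`); see [export_results()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(input, output_dir, ..., annotations = NULL) {
  if (is.character(annotations))
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  scr <- screen_assembly(input, ...)
  export_results(scr, output_dir, annotations = annotations)
}
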