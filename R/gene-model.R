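#' Construct a gene model
#'
#' A gene model is a gene with one or more transcripts, each an ordered list
#' of exon intervals. All internal coordinates are 0-based half-open
#' `[start, end)`; GTF input/output converts at the boundary (see
#' [read_gtf()] / [write_gtf()]).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts Named list; each element a two-column numeric matrix
#'   (`start`, `end`) of exon intervals, sorted by start, non-overlapping
#'   and separated by at least 1 bp of intron.
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  g <- structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = match.arg(strand, c("+", "-")),
         transcripts = transcripts),
    class = "gene_model")
  validate_gene_model(g)
  g
}

#' Validate a gene model
#'
#' Checks the structural invariants every downstream operation relies on:
#' at least one transcript, every transcript at least one exon, each exon
#' `start < end`, and exons within a transcript strictly increasing with
#' positive intron length. Errors name the offending transcript.
#'
#' @param gene A `gene_model`.
#' @return The gene, invisibly, if valid.
#' @export
validate_gene_model <- function(gene) {
  if (!inherits(gene, "gene_model")) stop("not a gene_model object")
  tx <- gene$transcripts
  if (length(tx) < 1L) stop("gene ", gene$gene_id, " has no transcripts")
  if (is.null(names(tx)) || anyDuplicated(names(tx)))
    stop("gene ", gene$gene_id, ": transcripts must be uniquely named")
  for (tn in names(tx)) {
    ex <- tx[[tn]]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
      stop("transcript ", tn, ": exons must be a matrix with >=1 row and 2 columns")
    if (any(ex[, 1L] >= ex[, 2L]))
      stop("transcript ", tn, ": exon with start >= end")
    if (nrow(ex) > 1L) {
      if (is.unsorted(ex[, 1L], strictly = TRUE))
        stop("transcript ", tn, ": exons not sorted by start")
      if (any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
        stop("transcript ", tn, ": overlapping or touching exons")
    }
  }
  invisible(gene)
}

#' @export
print.gene_model <- function(x, ...) {
  nex <- vapply(x$transcripts, nrow, integer(1))
  cat("<gene_model> ", x$gene_id, "  ", x$chrom, ":", x$strand, "  ",
      length(x$transcripts), " transcript(s), ",
      paste(nex, collapse = "/"), " exons\n", sep = "")
  invisible(x)
}
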