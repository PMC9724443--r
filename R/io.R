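# File formats. TSV with a header row for tabular interchange; BED strictly
# 0-based half-open; GTF strictly 1-based closed. Conversion happens here
# and nowhere else. Every writer prepends a comment line declaring the
# coordinate convention of the file.

write_tsv <- function(df, path, convention = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(convention))
    writeLines(paste0("# coordinates: ", convention), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write gene models to GTF
#'
#' Ensembl-dialect GTF: `gene`, `transcript` and `exon` features with
#' `gene_id` / `transcript_id` attributes, 1-based closed intervals
#' (converted from the internal 0-based half-open convention). Output is
#' deterministic: genes in input order, exons sorted.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (gm in genes) {
    gstart <- min(vapply(gm$transcripts, function(e) min(e[, 1]), numeric(1)))
    gend <- max(vapply(gm$transcripts, function(e) max(e[, 2]), numeric(1)))
    fmt <- function(feature, s, e, attrs)
      sprintf("%s\tspliceMeth\t%s\t%d\t%d\t.\t%s\t.\t%s",
              gm$chrom, feature, as.integer(s) + 1L, as.integer(e),
              gm$strand, attrs)
    lines <- c(lines, fmt("gene", gstart, gend,
                          sprintf('gene_id "%s";', gm$gene_id)))
    for (tn in names(gm$transcripts)) {
      tid <- paste0(gm$gene_id, ".", tn)
      ex <- gm$transcripts[[tn]]
      lines <- c(lines, fmt("transcript", min(ex[, 1]), max(ex[, 2]),
                            sprintf('gene_id "%s"; transcript_id "%s";',
                                    gm$gene_id, tid)))
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, fmt("exon", ex[j, 1], ex[j, 2],
                              sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                                      gm$gene_id, tid, j)))
    }
  }
  writeLines(c("#!coordinates: 1-based closed (GTF)", lines), path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Parses exon features (1-based closed, converted to internal 0-based
#' half-open), groups them by transcript and gene, and validates the
#' resulting models. Exon order in the file is irrelevant.
#'
#' @param path GTF file path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  md <- S4Vectors::mcols(ex)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = BiocGenerics::start(ex) - 1L,   # to half-open
                   end = BiocGenerics::end(ex),
                   strand = as.character(BiocGenerics::strand(ex)),
                   gene_id = md$gene_id, transcript_id = md$transcript_id,
                   stringsAsFactors = FALSE)
  out <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    txs <- lapply(split(sub, sub$transcript_id), function(s) {
      m <- cbind(s$start, s$end)[order(s$start), , drop = FALSE]
      dimnames(m) <- NULL
      m
    })
    # strip the "<gene>." prefix written by write_gtf, if present
    names(txs) <- sub(paste0("^", gid, "\\."), "", names(txs))
    out[[gid]] <- gene_model(gid, sub$chrom[1], sub$strand[1], txs)
  }
  out
}

#' Write a synthetic dataset to a directory
#'
#' Materialises every pipeline input: `annotation.gtf`, `event_counts.tsv`,
#' `event_catalogue.tsv` (truth catalogue incl. effective lengths),
#' `gene_counts.tsv` (with a `length` column; splicing-factor rows
#' included), `merip_bins.tsv` + `merip_bins.bed`, `sample_sheet.tsv`,
#' `sf_list.txt` and `truth.json`.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(ds$genes, p("annotation.gtf"))
  write_tsv(ds$event_counts, p("event_counts.tsv"))
  cat_tab <- merge(ds$events, ds$event_lengths, by = "event_id", sort = FALSE)
  write_tsv(cat_tab, p("event_catalogue.tsv"), "0-based half-open")
  gc <- data.frame(gene_id = rownames(ds$gene_counts),
                   length = c(ds$gene_info$length[
                       match(rownames(ds$gene_counts), ds$gene_info$gene_id)]),
                   ds$gene_counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  gc$length[is.na(gc$length)] <- 1000   # splicing-factor nominal length
  write_tsv(gc, p("gene_counts.tsv"))
  write_tsv(ds$merip_bins, p("merip_bins.tsv"), "0-based half-open")
  bed <- ds$merip_bins[, c("chrom", "start", "end", "bin_id")]
  writeLines(c("# coordinates: 0-based half-open (BED)",
               sprintf("%s\t%d\t%d\t%s", bed$chrom, as.integer(bed$start),
                       as.integer(bed$end), bed$bin_id)),
             p("merip_bins.bed"))
  write_tsv(ds$design, p("sample_sheet.tsv"))
  writeLines(names(ds$truth$sf_targets), p("sf_list.txt"))
  truth <- list(das_events = as.character(ds$truth$das_events),
                de_genes = as.character(ds$truth$de_genes),
                sf_targets = as.list(ds$truth$sf_targets),
                m6a_genes = as.character(ds$truth$m6a_genes),
                dm_peak_genes =
                  as.character(ds$truth$peaks$gene_id[ds$truth$peaks$differential]))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
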