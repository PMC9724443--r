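# Integration of differential splicing with differential m6A methylation:
# modified-vs-unmodified AS fractions, AS-count quartile groups, SE-DMAS
# four-quadrant classification, knockdown intersection, RRACH motif scan,
# and the RT-PCR band-intensity inclusion formula.

#' Fraction of genes with AS among m6A-modified vs unmodified genes
#'
#' @param gene_ids Character vector of (expressed) gene ids.
#' @param m6a_flags Logical, same length: gene contains >= 1 called m6A peak.
#' @param as_flags Logical, same length: gene contains >= 1 AS event.
#' @return List: `fraction_modified`, `fraction_unmodified`, `ratio`.
#' @export
as_fraction_by_modification <- function(gene_ids, m6a_flags, as_flags) {
  stopifnot(length(gene_ids) == length(m6a_flags),
            length(gene_ids) == length(as_flags))
  if (!any(m6a_flags)) stop("no m6A-modified genes: fraction undefined")
  if (all(m6a_flags)) stop("no unmodified genes: fraction undefined")
  fm <- mean(as_flags[m6a_flags])
  fu <- mean(as_flags[!m6a_flags])
  list(fraction_modified = fm, fraction_unmodified = fu,
       ratio = if (fu > 0) fm / fu else Inf)
}

#' Group m6A-modified genes by their AS-event counts
#'
#' Quartiles (type-7, linear interpolation) of the AS-count distribution
#' over the m6A-modified gene set define three groups: `high`
#' (count >= Q3), `low` (count <= Q1), `medium` (between). When Q1 == Q3 a
#' gene satisfying both boundary rules is assigned `high` (precedence
#' high, then low), keeping the partition total.
#'
#' @param gene_ids m6A-modified gene ids.
#' @param as_counts AS event count per gene (>= 0), same length/order.
#' @return Data frame `gene_id`, `as_count`, `group`, plus attributes
#'   `q1`/`q3`.
#' @export
group_by_as_counts <- function(gene_ids, as_counts) {
  stopifnot(length(gene_ids) == length(as_counts), all(as_counts >= 0))
  if (length(gene_ids) < 4L) stop("need >= 4 genes to form quartile groups")
  q <- stats::quantile(as_counts, c(0.25, 0.75), type = 7, names = FALSE)
  group <- ifelse(as_counts >= q[2], "high",
                  ifelse(as_counts <= q[1], "low", "medium"))
  out <- data.frame(gene_id = gene_ids, as_count = as_counts, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "q1") <- q[1]; attr(out, "q3") <- q[2]
  out
}

#' Compare m6A enrichment change across AS-count groups
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) tests of the gene-level
#' `log2FC(MFPKM)` between the `high` vs `low` AS-count groups (alternative:
#' values in `high` are shifted up), plus group means.
#'
#' @param groups Output of [group_by_as_counts()].
#' @param log2fc_mfpkm Per-gene log2 fold-change of MFPKM, aligned with
#'   `groups$gene_id`.
#' @return List: `means` (named by group), `p_high_vs_low`.
#' @export
compare_as_count_groups <- function(groups, log2fc_mfpkm) {
  stopifnot(length(log2fc_mfpkm) == nrow(groups))
  means <- tapply(log2fc_mfpkm, groups$group, mean, na.rm = TRUE)
  hi <- log2fc_mfpkm[groups$group == "high"]
  lo <- log2fc_mfpkm[groups$group == "low"]
  p <- stats::wilcox.test(hi, lo, alternative = "greater", exact = FALSE)$p.value
  list(means = means, p_high_vs_low = p)
}

#' Classify SE-DMAS records into four quadrants
#'
#' Joins SE-type differential-splicing results (FDR < alpha) with
#' significant differential-methylation peaks (padj < alpha) that overlap
#' the event's cassette exon. When several significant peaks overlap one
#' exon, the peak with the largest overlap wins (ties: leftmost peak
#' start). Each record carries the quadrant label
#' `(psi_direction, m6a_direction)` with `psi_direction` in
#' increased/decreased and `m6a_direction` in hyper/hypo.
#'
#' @param das SE-event differential results ([test_differential_psi()]
#'   joined with event metadata; needs `event_id`, `gene_id`, `delta_psi`,
#'   `padj`, `das`, `direction`).
#' @param peaks Differential-methylation peak table
#'   ([test_differential_methylation()]; needs `peak_id`, `log2fc`, `padj`,
#'   `significant`, `direction`, `start`).
#' @param overlaps Peak-feature overlap table ([overlap_peaks_features()])
#'   with `feature_id` = event ids of the cassette exons; only
#'   `within-exon` / `spans-boundary` relations count as overlap.
#' @return List: `records` (one row per SE-DMAS event), `quadrants` (2x2
#'   count matrix, rows = PSI direction, cols = m6A direction),
#'   `n_genes` gene-level roll-up.
#' @export
classify_sedmas <- function(das, peaks, overlaps) {
  sig_das <- das[das$das, , drop = FALSE]
  sig_pk <- peaks[peaks$significant, , drop = FALSE]
  ov <- overlaps[overlaps$relation %in% c("within-exon", "spans-boundary") &
                 overlaps$feature_id %in% sig_das$event_id &
                 overlaps$peak_id %in% sig_pk$peak_id, , drop = FALSE]
  quad_levels <- list(psi = c("increased", "decreased"),
                      m6a = c("hyper", "hypo"))
  if (nrow(ov) == 0L) {
    rec <- data.frame(event_id = character(), gene_id = character(),
                      delta_psi = numeric(), das_fdr = numeric(),
                      peak_id = character(), m6a_log2fc = numeric(),
                      m6a_padj = numeric(), psi_direction = character(),
                      m6a_direction = character(), quadrant = character(),
                      stringsAsFactors = FALSE)
    qd <- matrix(0L, 2, 2, dimnames = quad_levels)
    return(list(records = rec, quadrants = qd, n_genes = 0L))
  }
  # largest overlap wins, ties by leftmost peak start
  ov$peak_start <- sig_pk$start[match(ov$peak_id, sig_pk$peak_id)]
  ov <- ov[order(ov$feature_id, -ov$overlap_bp, ov$peak_start), , drop = FALSE]
  ov <- ov[!duplicated(ov$feature_id), , drop = FALSE]
  di <- match(ov$feature_id, sig_das$event_id)
  pi <- match(ov$peak_id, sig_pk$peak_id)
  rec <- data.frame(event_id = sig_das$event_id[di],
                    gene_id = sig_das$gene_id[di],
                    delta_psi = sig_das$delta_psi[di],
                    das_fdr = sig_das$padj[di],
                    peak_id = sig_pk$peak_id[pi],
                    m6a_log2fc = sig_pk$log2fc[pi],
                    m6a_padj = sig_pk$padj[pi],
                    psi_direction = sig_das$direction[di],
                    m6a_direction = sig_pk$direction[pi],
                    stringsAsFactors = FALSE)
  rec$quadrant <- paste(rec$psi_direction, rec$m6a_direction, sep = "/")
  qd <- table(factor(rec$psi_direction, quad_levels$psi),
              factor(rec$m6a_direction, quad_levels$m6a))
  qd <- matrix(as.integer(qd), 2, 2, dimnames = quad_levels)
  rec <- rec[order(rec$event_id), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, quadrants = qd,
       n_genes = length(unique(rec$gene_id)))
}

#' Marginal totals of a four-quadrant table
#'
#' @param quadrants 2x2 count matrix (rows: PSI increased/decreased,
#'   columns: m6A hyper/hypo), as produced by [classify_sedmas()].
#' @return List: `by_psi` (per-PSI-direction totals), `by_m6a`, `total`.
#' @export
summarize_quadrants <- function(quadrants) {
  stopifnot(all(dim(quadrants) == c(2L, 2L)))
  list(by_psi = rowSums(quadrants), by_m6a = colSums(quadrants),
       total = sum(quadrants))
}

#' Intersect tissue SE-DMAS events with knockdown SE-DAS events
#'
#' Event identity is `(gene_id, cassette-exon start/end, strand)`; both
#' inputs must use the same (0-based half-open) convention. If the two sets
#' share nothing as given but match perfectly after shifting one set by
#' 1 bp, a loud warning flags a likely 0-based/1-based convention mismatch.
#'
#' @param tissue Data frame with `gene_id`, `e1_start`, `e1_end`, `strand`
#'   (e.g. SE-DMAS records joined back to event coordinates).
#' @param knockdown Data frame with the same columns for the knockdown
#'   SE-DAS events.
#' @return List: `n_tissue`, `n_knockdown`, `n_shared`, `shared` (data
#'   frame), `percent_of_tissue` (one-decimal percentage).
#' @export
intersect_knockdown <- function(tissue, knockdown) {
  key <- function(d, shift = 0)
    paste(d$gene_id, d$e1_start + shift, d$e1_end + shift, d$strand, sep = "|")
  kt <- key(tissue); kk <- key(knockdown)
  shared <- kt %in% kk
  if (!any(shared) && nrow(tissue) > 0 && nrow(knockdown) > 0) {
    if (any(key(tissue, 1) %in% kk) || any(key(tissue, -1) %in% kk))
      warning("no shared events as given, but events match after a 1-bp ",
              "shift: check 0-based/1-based coordinate conventions",
              call. = FALSE)
  }
  out <- tissue[shared, , drop = FALSE]
  rownames(out) <- NULL
  pct <- if (nrow(tissue) > 0) round(100 * sum(shared) / nrow(tissue), 1) else NA_real_
  list(n_tissue = nrow(tissue), n_knockdown = nrow(knockdown),
       n_shared = sum(shared), shared = out, percent_of_tissue = pct)
}

#' Scan a sequence for the RRACH m6A consensus motif
#'
#' Counts positions matching `[AG][AG]AC[ACU]` (RRACH; R = A/G, H = A/C/U).
#' Overlapping occurrences are counted; `N` never matches; `U` is treated
#' as `T`. With `reverse_complement = TRUE` the reverse strand is scanned
#' and positions are reported on the input coordinates.
#'
#' @param sequence A single character string over `A C G T U N`
#'   (case-insensitive).
#' @param reverse_complement Scan the reverse complement instead.
#' @return List: `count`, `positions` (0-based match start positions on the
#'   input sequence).
#' @export
rrach_scan <- function(sequence, reverse_complement = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "t", tolower(sequence))
  if (grepl("[^acgtn]", s))
    stop("sequence contains characters outside {A, C, G, T, U, N}")
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  if (reverse_complement)
    v <- rev(chartr("ACGT", "TGCA", v))
  n <- length(v)
  if (n < 5L) return(list(count = 0L, positions = integer(0)))
  isR <- v == "A" | v == "G"
  isA <- v == "A"
  isC <- v == "C"
  isH <- v == "A" | v == "C" | v == "T"
  i <- seq_len(n - 4L)
  hit <- isR[i] & isR[i + 1L] & isA[i + 2L] & isC[i + 3L] & isH[i + 4L]
  pos <- i[hit] - 1L
  if (reverse_complement && length(pos))
    pos <- n - (pos + 5L)
  pos <- sort(pos)
  list(count = length(pos), positions = as.integer(pos))
}

#' Scan FASTA sequence windows for RRACH motifs
#'
#' Reads a FASTA file (e.g. 1 kb windows around skipped exons) and applies
#' [rrach_scan()] to every record.
#'
#' @param path FASTA file path.
#' @param reverse_complement Scan the reverse strand instead.
#' @return Data frame: `seq_id`, `length`, `n_rrach`, `per_kb`.
#' @export
scan_fasta_rrach <- function(path, reverse_complement = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  n <- vapply(as.character(seqs), function(s)
    rrach_scan(s, reverse_complement)$count, numeric(1))
  data.frame(seq_id = names(seqs), length = BiocGenerics::width(seqs),
             n_rrach = as.integer(n),
             per_kb = 1000 * n / BiocGenerics::width(seqs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exon-inclusion level from RT-PCR band intensities
#'
#' `inclusion = upper / (upper + lower)` where the upper band is the
#' exon-inclusion product and the lower band the exon-skipping product.
#'
#' @param upper_intensity,lower_intensity Non-negative band intensities,
#'   not both zero (vectorised).
#' @return Inclusion level(s) in `[0, 1]`.
#' @export
rtpcr_inclusion <- function(upper_intensity, lower_intensity) {
  stopifnot(all(upper_intensity >= 0), all(lower_intensity >= 0))
  if (any(upper_intensity + lower_intensity == 0))
    stop("both band intensities are zero")
  upper_intensity / (upper_intensity + lower_intensity)
}
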