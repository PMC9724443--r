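# MeRIP-seq enrichment analysis: window peak calling from binned IP/input
# coverage, MFPKM enrichment, differential methylation, and peak-feature
# overlap with bedtools-style half-open interval semantics.

# One-sided Fisher exact p (enrichment of a in its column) for the table
# [[a, A-a], [b, B-b]], vectorised via the hypergeometric tail.
fisher_greater <- function(a, A, b, B) {
  stats::phyper(a - 1, a + b, (A - a) + (B - b), A, lower.tail = FALSE)
}

#' Call m6A peaks from binned IP/input counts
#'
#' Window caller: per bin and condition, IP counts pooled across replicates
#' are tested for enrichment over pooled input counts with a one-sided
#' Fisher exact test of `(IP_bin, IP_total - IP_bin)` vs
#' `(input_bin, input_total - input_bin)`. P-values are BH-adjusted across
#' bins within a condition; bins with `padj < alpha` and fold enrichment
#' `>= fold_min` are significant. Fold enrichment is the bin's IP/input
#' ratio divided by the library's median bin ratio -- a robust background
#' estimate that is not inflated by the enriched bins themselves.
#' Adjacent significant bins on the same gene are merged; per-condition peak
#' sets are then unioned over conditions into a single peak list (one
#' downstream testing family) with per-sample counts recomputed by summing
#' member bins.
#'
#' @param bins Data frame, one row per bin: `bin_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `gene_id`, plus one IP and one input count
#'   column per sample named `ip_<sample>` / `input_<sample>`.
#' @param design Data frame with `sample_id`, `condition`.
#' @param alpha BH-adjusted significance threshold per bin (default 0.05).
#' @param fold_min Minimum normalised IP/input fold enrichment (default 2).
#' @return Data frame of peaks: `peak_id`, `chrom`, `start`, `end`,
#'   `gene_id`, `n_bins`, detection condition(s), and the summed per-sample
#'   `ip_*` / `input_*` count columns. Genome-wide per-sample library
#'   totals are attached as attributes `lib_ip` / `lib_input` for
#'   downstream MFPKM normalisation.
#' @export
call_peaks <- function(bins, design, alpha = 0.05, fold_min = 2) {
  stopifnot(all(c("bin_id", "chrom", "start", "end", "gene_id") %in% names(bins)))
  samples <- design$sample_id
  ipc <- paste0("ip_", samples); inc <- paste0("input_", samples)
  if (!all(c(ipc, inc) %in% names(bins)))
    stop("bins table lacks ip_/input_ columns for the design's samples")
  conds <- unique(as.character(design$condition))
  ord <- order(bins$chrom, bins$gene_id, bins$start)
  bins <- bins[ord, , drop = FALSE]
  sig_by_cond <- list()
  for (cn in conds) {
    sm <- samples[design$condition == cn]
    ip <- rowSums(bins[, paste0("ip_", sm), drop = FALSE])
    inp <- rowSums(bins[, paste0("input_", sm), drop = FALSE])
    IPt <- sum(ip); INt <- sum(inp)
    if (IPt == 0 || INt == 0) stop("condition ", cn, " has zero total counts")
    p <- fisher_greater(ip, IPt, inp, INt)
    padj <- benjamini_hochberg(p)
    bg <- stats::median((ip / inp)[inp > 0])
    if (!is.finite(bg) || bg <= 0) bg <- IPt / INt
    fold <- ifelse(inp > 0, (ip / inp) / bg, Inf)
    fold[ip == 0] <- 0
    sig_by_cond[[cn]] <- !is.na(padj) & padj < alpha & fold >= fold_min
  }
  sig <- Reduce(`|`, sig_by_cond)
  if (!any(sig)) {
    out <- data.frame(peak_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character(), n_bins = integer(),
                      stringsAsFactors = FALSE)
    for (cc in c(ipc, inc)) out[[cc]] <- numeric()
    return(out)
  }
  # merge runs of adjacent significant bins within a gene
  newrun <- c(TRUE, diff(as.integer(sig)) != 0 |
                bins$gene_id[-1] != bins$gene_id[-nrow(bins)] |
                bins$start[-1] != bins$end[-nrow(bins)])
  runid <- cumsum(newrun)
  keep <- sig
  pk <- split(which(keep), runid[keep])
  rows <- lapply(pk, function(ix) {
    r <- data.frame(peak_id = NA_character_,
                    chrom = bins$chrom[ix[1]],
                    start = min(bins$start[ix]), end = max(bins$end[ix]),
                    gene_id = bins$gene_id[ix[1]],
                    n_bins = length(ix), stringsAsFactors = FALSE)
    for (cc in c(ipc, inc)) r[[cc]] <- sum(bins[ix, cc])
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$peak_id <- sprintf("peak_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  # genome-wide library totals, for downstream FPKM/MFPKM normalisation
  attr(out, "lib_ip") <- stats::setNames(colSums(bins[, ipc, drop = FALSE]),
                                         samples)
  attr(out, "lib_input") <- stats::setNames(colSums(bins[, inc, drop = FALSE]),
                                            samples)
  out
}

#' MFPKM enrichment per region and condition
#'
#' `MFPKM = FPKM_IP / FPKM_input`, computed per replicate and then averaged
#' (arithmetic mean) over the replicates of each condition. Replicates with
#' zero input FPKM are excluded from the mean and counted in `n_excluded`;
#' a condition where every replicate is undefined yields `NA`.
#'
#' @param fpkm_ip Region x sample FPKM matrix of IP libraries.
#' @param fpkm_input Matching input FPKM matrix (same dimnames).
#' @param design Data frame with `sample_id` (matching columns) and
#'   `condition`.
#' @return List of matrices: `mfpkm` (region x condition) and `n_excluded`.
#' @export
compute_mfpkm <- function(fpkm_ip, fpkm_input, design) {
  stopifnot(identical(dim(fpkm_ip), dim(fpkm_input)),
            identical(colnames(fpkm_ip), colnames(fpkm_input)),
            all(design$sample_id %in% colnames(fpkm_ip)))
  conds <- unique(as.character(design$condition))
  ratio <- fpkm_ip / fpkm_input
  ratio[fpkm_input == 0] <- NA_real_
  mf <- sapply(conds, function(cn) {
    sm <- design$sample_id[design$condition == cn]
    rowMeans(ratio[, sm, drop = FALSE], na.rm = TRUE)
  })
  mf[is.nan(mf)] <- NA_real_
  nex <- sapply(conds, function(cn) {
    sm <- design$sample_id[design$condition == cn]
    rowSums(is.na(ratio[, sm, drop = FALSE]))
  })
  mf <- matrix(mf, nrow = nrow(fpkm_ip),
               dimnames = list(rownames(fpkm_ip), conds))
  nex <- matrix(nex, nrow = nrow(fpkm_ip),
                dimnames = list(rownames(fpkm_ip), conds))
  list(mfpkm = mf, n_excluded = nex)
}

#' Differential m6A methylation per peak
#'
#' Per peak, `log2FC = log2(MFPKM_cond2 / MFPKM_cond1)` with MFPKM from
#' [compute_mfpkm()]; the p-value comes from a two-sided Fisher exact test
#' on the pooled 2x2 table of (IP, input) counts per condition, BH-adjusted
#' across peaks. A peak is significant when `padj < alpha`; direction is
#' `hyper` (`log2fc > 0`, condition 2 enriched) or `hypo`. Peaks with
#' undefined MFPKM in either condition are reported untested.
#'
#' @param peaks Peak table from [call_peaks()] (needs the per-sample
#'   `ip_*` / `input_*` columns).
#' @param design Data frame with `sample_id`, `condition`; the second
#'   unique condition is the numerator.
#' @param lengths Optional per-peak region lengths for the FPKM step;
#'   defaults to `end - start`.
#' @param lib_ip,lib_input Optional per-sample library sizes; default to
#'   the genome-wide totals recorded by [call_peaks()], falling back to the
#'   column sums of the peak counts.
#' @param alpha FDR threshold (default 0.05).
#' @return `peaks` with added columns `mfpkm1`, `mfpkm2`, `log2fc`,
#'   `pvalue`, `padj`, `significant`, `direction`.
#' @export
test_differential_methylation <- function(peaks, design, lengths = NULL,
                                          lib_ip = NULL, lib_input = NULL,
                                          alpha = 0.05) {
  conds <- unique(as.character(design$condition))
  stopifnot(length(conds) == 2L)
  samples <- design$sample_id
  ipc <- paste0("ip_", samples); inc <- paste0("input_", samples)
  ip <- as.matrix(peaks[, ipc, drop = FALSE]); colnames(ip) <- samples
  inp <- as.matrix(peaks[, inc, drop = FALSE]); colnames(inp) <- samples
  if (is.null(lengths)) lengths <- peaks$end - peaks$start
  # prefer the genome-wide library totals recorded by call_peaks(); the
  # peak-subset column sums are only a fallback and measure change relative
  # to the average peak rather than to the library
  if (is.null(lib_ip))
    lib_ip <- attr(peaks, "lib_ip")[samples]
  if (is.null(lib_input))
    lib_input <- attr(peaks, "lib_input")[samples]
  if (is.null(lib_ip) || anyNA(lib_ip)) lib_ip <- pmax(colSums(ip), 1)
  if (is.null(lib_input) || anyNA(lib_input))
    lib_input <- pmax(colSums(inp), 1)
  if (nrow(peaks) == 0L) {
    for (cc in c("mfpkm1", "mfpkm2", "log2fc", "pvalue", "padj"))
      peaks[[cc]] <- numeric()
    peaks$significant <- logical(); peaks$direction <- character()
    return(peaks)
  }
  rownames(ip) <- rownames(inp) <- peaks$peak_id
  fip <- compute_fpkm(ip, lengths, lib_ip)
  fin <- compute_fpkm(inp, lengths, lib_input)
  mf <- compute_mfpkm(fip, fin, design)$mfpkm
  m1 <- mf[, conds[1]]; m2 <- mf[, conds[2]]
  s1 <- samples[design$condition == conds[1]]
  s2 <- samples[design$condition == conds[2]]
  ip1 <- rowSums(ip[, s1, drop = FALSE]); in1 <- rowSums(inp[, s1, drop = FALSE])
  ip2 <- rowSums(ip[, s2, drop = FALSE]); in2 <- rowSums(inp[, s2, drop = FALSE])
  tested <- !is.na(m1) & !is.na(m2) & m1 > 0
  pval <- rep(NA_real_, nrow(peaks))
  for (k in which(tested)) {
    tab <- matrix(c(ip2[k], in2[k], ip1[k], in1[k]), nrow = 2)
    pval[k] <- stats::fisher.test(round(tab))$p.value
  }
  log2fc <- ifelse(tested, log2(m2 / m1), NA_real_)
  padj <- benjamini_hochberg(pval)
  peaks$mfpkm1 <- m1; peaks$mfpkm2 <- m2
  peaks$log2fc <- log2fc; peaks$pvalue <- pval; peaks$padj <- padj
  peaks$significant <- !is.na(padj) & padj < alpha
  peaks$direction <- ifelse(is.na(log2fc), NA_character_,
                            ifelse(log2fc > 0, "hyper", "hypo"))
  peaks
}

#' Overlap peaks with genomic features
#'
#' Half-open interval intersection (bedtools semantics): intervals touching
#' only at a shared boundary do not overlap. Each overlapping (peak,
#' feature) pair is reported with its overlap length and a relation:
#' `within-exon` (peak contained in the feature), `spans-boundary` (partial
#' overlap or peak containing the feature), or `flanking-1kb` (no overlap
#' but within `flank` bp).
#'
#' @param peaks Data frame with `peak_id`, `chrom`, `start`, `end`.
#' @param features Data frame with `feature_id`, `chrom`, `start`, `end`
#'   (same 0-based half-open convention).
#' @param flank Flanking distance in bp for the `flanking-1kb` relation
#'   (default 1000; must be >= 0).
#' @return Data frame: `peak_id`, `feature_id`, `overlap_bp`, `relation`.
#' @export
overlap_peaks_features <- function(peaks, features, flank = 1000) {
  if (flank < 0) stop("flank must be >= 0")
  empty <- data.frame(peak_id = character(), feature_id = character(),
                      overlap_bp = numeric(), relation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(features) == 0L) return(empty)
  lv <- sort(unique(c(peaks$chrom, features$chrom)))
  gp <- GenomicRanges::GRanges(factor(peaks$chrom, lv),
          IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  gf <- GenomicRanges::GRanges(factor(features$chrom, lv),
          IRanges::IRanges(start = features$start + 1, end = features$end))
  hit <- GenomicRanges::findOverlaps(gp, gf, maxgap = flank, minoverlap = 0L)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  if (!length(qi)) return(empty)
  ov <- pmin(peaks$end[qi], features$end[si]) -
        pmax(peaks$start[qi], features$start[si])
  rel <- ifelse(ov >= 1,
                ifelse(peaks$start[qi] >= features$start[si] &
                       peaks$end[qi] <= features$end[si],
                       "within-exon", "spans-boundary"),
                "flanking-1kb")
  out <- data.frame(peak_id = peaks$peak_id[qi],
                    feature_id = features$feature_id[si],
                    overlap_bp = pmax(ov, 0), relation = rel,
                    stringsAsFactors = FALSE)
  out[out$overlap_bp >= 1 | out$relation == "flanking-1kb", , drop = FALSE]
}
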