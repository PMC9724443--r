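# Differential expression (NB Wald), differential splicing (pooled binomial
# LRT on length-normalised junction counts), and shared multiple-testing
# machinery.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `padj_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, ties stable.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed; NA
#'   entries are excluded from the family and returned as NA).
#' @return Adjusted p-values, same length and order as input.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

# DESeq-style median-of-ratios size factors. Falls back to library-size
# ratios when no gene is positive in all samples.
size_factors <- function(counts) {
  logs <- log(counts)
  finite <- rowSums(is.finite(logs)) == ncol(counts)
  if (!any(finite)) {
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  ref <- rowMeans(logs[finite, , drop = FALSE])
  apply(logs[finite, , drop = FALSE], 2, function(lc) exp(stats::median(lc - ref)))
}

#' Differential gene expression by a negative-binomial Wald test
#'
#' A compact two-group NB test: median-of-ratios size factors, per-gene
#' method-of-moments dispersion pooled within conditions, a common
#' dispersion-mean trend `alpha(mu) = a0 + a1/mu` fitted across genes, and a
#' Wald test on the log2 fold-change of normalised condition means (delta
#' method standard error using the trend dispersion). P-values are BH
#' adjusted across all genes tested; a gene is flagged differentially
#' expressed when `|log2FC| >= lfc_min` and `FDR < alpha`.
#'
#' @param counts Gene x sample count matrix (rownames = gene ids).
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels; the second level is the numerator of the fold-change.
#' @param lfc_min Absolute log2 fold-change floor for the DEG flag
#'   (default 1, inclusive).
#' @param alpha FDR threshold for the DEG flag (default 0.05).
#' @return Data frame: `gene_id`, `base_mean`, `log2fc`, `pvalue`, `padj`,
#'   `deg` flag.
#' @export
test_differential_expression <- function(counts, condition, lfc_min = 1,
                                         alpha = 0.05) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2L, length(condition) == ncol(counts))
  if (any(table(condition) < 2L)) stop("need >= 2 replicates per condition")
  if (any(vapply(levels(condition),
                 function(l) all(counts[, condition == l] == 0), logical(1))))
    stop("a condition has all-zero libraries")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  # method-of-moments dispersion per gene, pooled over conditions
  mu_bar <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  v_bar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  disp_mom <- (v_bar - mu_bar) / mu_bar^2
  # common trend alpha(mu) = a0 + a1/mu over informative genes
  use <- is.finite(disp_mom) & mu_bar > 1
  a0 <- 1e-8; a1 <- 0
  if (sum(use) >= 10L) {
    fit <- stats::lm(disp_mom[use] ~ I(1 / mu_bar[use]))
    a0 <- max(stats::coef(fit)[1], 1e-8)
    a1 <- max(stats::coef(fit)[2], 0)
  } else if (any(use)) {
    a0 <- max(stats::median(disp_mom[use]), 1e-8)
  }
  disp1 <- a0 + a1 / pmax(mu1, 0.5)
  disp2 <- a0 + a1 / pmax(mu2, 0.5)
  pc <- 0.5   # pseudocount guards log of zero means
  lfc <- log2(mu2 + pc) - log2(mu1 + pc)
  se2 <- ((1 / (mu1 + pc) + disp1) / n1 + (1 / (mu2 + pc) + disp2) / n2) / log(2)^2
  z <- lfc / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- benjamini_hochberg(p)
  data.frame(gene_id = rownames(counts),
             base_mean = mu_bar, log2fc = lfc, pvalue = p, padj = padj,
             deg = abs(lfc) >= lfc_min & !is.na(padj) & padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

# binomial log-likelihood, 0*log(0) treated as 0
binom_ll <- function(k, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  k * log(p) + (n - k) * log(1 - p)
}

# Read-level inclusion proportion implied by an isoform-level PSI under the
# event's effective lengths, and its inverse. estimate_psi() is the inverse
# map applied to observed counts, so the two are used consistently.
psi_to_read_prop <- function(psi, l_I, l_S) {
  psi * l_I / (psi * l_I + (1 - psi) * l_S)
}

#' Differential PSI by a pooled binomial likelihood-ratio test
#'
#' Per event, inclusion/skipping junction counts are pooled across the
#' replicates of each condition and modelled as binomial draws of the
#' read-level inclusion proportion, which maps one-to-one onto the
#' isoform-level PSI through the event's effective lengths (the same map
#' [estimate_psi()] inverts). The likelihood-ratio statistic compares a
#' shared PSI against condition-specific PSI values; p-values come from a
#' chi-squared distribution with 1 df and are BH-adjusted across all tested
#' events. Reported `delta_psi` is the difference of condition mean PSI
#' (length-normalised, averaged over samples with defined PSI), condition 2
#' minus condition 1. Events with PSI defined in fewer than two samples of
#' either condition are reported untested (`NA` p, excluded from the BH
#' family).
#'
#' @param event_counts Event-count table (`event_id`, `sample_id`,
#'   `inclusion_count`, `skipping_count`).
#' @param lengths Effective-length table (`event_id`, `l_I`, `l_S`).
#' @param design Data frame with `sample_id`, `condition` (two levels;
#'   level 2 minus level 1 defines the sign of `delta_psi`).
#' @param min_total Per-sample coverage floor for a defined PSI.
#' @param alpha FDR threshold for the DAS flag.
#' @param delta_min Optional reporting floor on `|delta_psi|` (default 0,
#'   off); when set, the DAS flag additionally requires
#'   `|delta_psi| >= delta_min`.
#' @return Data frame: `event_id`, `psi1`, `psi2`, `delta_psi`, `lr_stat`,
#'   `pvalue`, `padj`, `das` flag, `direction` (`"increased"` /
#'   `"decreased"` in condition 2 vs 1).
#' @export
test_differential_psi <- function(event_counts, lengths, design,
                                  min_total = 10, alpha = 0.05,
                                  delta_min = 0) {
  stopifnot(all(c("sample_id", "condition") %in% names(design)))
  cond <- as.factor(design$condition)
  stopifnot(nlevels(cond) == 2L)
  lv <- levels(cond)
  psi <- psi_matrix(event_counts, lengths, min_total = min_total)
  s1 <- design$sample_id[cond == lv[1]]
  s2 <- design$sample_id[cond == lv[2]]
  ev <- rownames(psi)
  # pooled length-normalised counts per condition
  ec <- event_counts
  ec$grp <- ifelse(ec$sample_id %in% s1, 1L, 2L)
  agg <- stats::aggregate(cbind(I = ec$inclusion_count, S = ec$skipping_count),
                          by = list(event_id = ec$event_id, grp = ec$grp), FUN = sum)
  I1 <- S1 <- I2 <- S2 <- stats::setNames(numeric(length(ev)), ev)
  a1 <- agg[agg$grp == 1L, ]; a2 <- agg[agg$grp == 2L, ]
  I1[a1$event_id] <- a1$I; S1[a1$event_id] <- a1$S
  I2[a2$event_id] <- a2$I; S2[a2$event_id] <- a2$S
  # The raw junction counts are the binomially distributed quantity; the
  # read-level proportion q maps monotonically onto PSI through the
  # effective lengths, so a shared-q vs per-condition-q LRT is exactly the
  # shared-PSI vs per-condition-PSI LRT.
  n1 <- I1 + S1; n2 <- I2 + S2
  q1 <- ifelse(n1 > 0, I1 / n1, NA_real_)
  q2 <- ifelse(n2 > 0, I2 / n2, NA_real_)
  q0 <- ifelse(n1 + n2 > 0, (I1 + I2) / (n1 + n2), NA_real_)
  lr <- 2 * (binom_ll(I1, n1, q1) + binom_ll(I2, n2, q2) -
             binom_ll(I1, n1, q0) - binom_ll(I2, n2, q0))
  lr <- pmax(lr, 0)
  tested <- rowSums(!is.na(psi[, s1, drop = FALSE])) >= 2L &
            rowSums(!is.na(psi[, s2, drop = FALSE])) >= 2L
  pval <- rep(NA_real_, length(ev))
  pval[tested] <- stats::pchisq(lr[tested], df = 1, lower.tail = FALSE)
  psi1 <- rowMeans(psi[, s1, drop = FALSE], na.rm = TRUE)
  psi2 <- rowMeans(psi[, s2, drop = FALSE], na.rm = TRUE)
  dpsi <- psi2 - psi1
  padj <- benjamini_hochberg(pval)
  das <- !is.na(padj) & padj < alpha & abs(dpsi) >= delta_min
  data.frame(event_id = ev, psi1 = psi1, psi2 = psi2, delta_psi = dpsi,
             lr_stat = as.numeric(lr), pvalue = pval, padj = padj,
             das = das,
             direction = ifelse(dpsi >= 0, "increased", "decreased"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect differentially expressed and differentially spliced gene sets
#'
#' @param deg_genes Character vector of DEG ids.
#' @param das_genes Character vector of DAS gene ids (same namespace).
#' @return List with `n_deg`, `n_dasg`, `n_intersect`, `intersect_ids`.
#' @export
intersect_deg_dasg <- function(deg_genes, das_genes) {
  deg_genes <- unique(deg_genes); das_genes <- unique(das_genes)
  ids <- sort(intersect(deg_genes, das_genes))
  list(n_deg = length(deg_genes), n_dasg = length(das_genes),
       n_intersect = length(ids), intersect_ids = ids)
}
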