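test_that("AS fraction by modification class: hand case, errors, null ratio", {
  g <- sprintf("g%02d", 1:20)
  m6a <- rep(c(TRUE, FALSE), each = 10)
  as_ <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 6))
  r <- as_fraction_by_modification(g, m6a, as_)
  expect_equal(r$fraction_modified, 0.8)
  expect_equal(r$fraction_unmodified, 0.4)
  expect_equal(r$ratio, 2.0)
  expect_error(as_fraction_by_modification(g, rep(TRUE, 20), as_), "unmodified")
  # independent flags give a ratio near 1
  set.seed(21)
  ratios <- replicate(50, {
    m <- runif(400) < 0.5; a <- runif(400) < 0.6
    as_fraction_by_modification(as.character(1:400), m, a)$ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("AS-count quartile groups: hand quantiles and degenerate ties", {
  g <- group_by_as_counts(letters[1:8], 1:8)
  expect_equal(attr(g, "q1"), 2.75)
  expect_equal(attr(g, "q3"), 6.25)
  expect_equal(g$gene_id[g$group == "low"], c("a", "b"))
  expect_equal(g$gene_id[g$group == "high"], c("g", "h"))
  expect_equal(sum(g$group == "medium"), 4)
  # all counts equal: Q1 == Q3, precedence assigns everything to high
  ge <- group_by_as_counts(letters[1:6], rep(3, 6))
  expect_true(all(ge$group == "high"))
  expect_equal(nrow(ge), 6)
  expect_error(group_by_as_counts(letters[1:3], 1:3), ">= 4")
})

test_that("planted AS-count/m6A coupling orders the groups", {
  set.seed(4)
  n <- 500
  cnt <- rpois(n, 3)
  lfc <- 0.3 * scale(cnt)[, 1] + rnorm(n, 0, 0.5)
  g <- group_by_as_counts(sprintf("g%03d", 1:n), cnt)
  cmp <- compare_as_count_groups(g, lfc)
  expect_true(cmp$means[["high"]] > cmp$means[["medium"]])
  expect_true(cmp$means[["medium"]] > cmp$means[["low"]])
  expect_lt(cmp$p_high_vs_low, 0.05)
})

sedmas_fixture <- function() {
  das <- data.frame(
    event_id = c("e1", "e2", "e3", "e4"),
    gene_id = c("g1", "g2", "g3", "g4"),
    delta_psi = c(0.3, -0.25, 0.2, 0.4),
    padj = c(0.001, 0.002, 0.2, 0.003),
    das = c(TRUE, TRUE, FALSE, TRUE),
    direction = c("increased", "decreased", "increased", "increased"),
    stringsAsFactors = FALSE)
  peaks <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4"),
    start = c(100, 500, 900, 1300),
    log2fc = c(1.5, -2, 1, 2),
    padj = c(0.01, 0.01, 0.3, 0.01),
    significant = c(TRUE, TRUE, FALSE, TRUE),
    direction = c("hyper", "hypo", "hyper", "hyper"),
    stringsAsFactors = FALSE)
  overlaps <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4", "p1"),
    feature_id = c("e1", "e2", "e3", "e4", "e4"),
    overlap_bp = c(50, 80, 60, 40, 90),
    relation = c("within-exon", "spans-boundary", "within-exon",
                 "within-exon", "within-exon"),
    stringsAsFactors = FALSE)
  list(das = das, peaks = peaks, overlaps = overlaps)
}

test_that("SE-DMAS classification: sign rule, filters, largest-overlap pairing", {
  fx <- sedmas_fixture()
  r <- classify_sedmas(fx$das, fx$peaks, fx$overlaps)
  expect_equal(nrow(r$records), 3L)            # e3 not DAS, p3 not significant
  expect_equal(sum(r$quadrants), 3)
  e1 <- r$records[r$records$event_id == "e1", ]
  expect_equal(e1$quadrant, "increased/hyper")
  e2 <- r$records[r$records$event_id == "e2", ]
  expect_equal(e2$quadrant, "decreased/hypo")
  # e4 overlaps p4 (40 bp) and p1 (90 bp): largest overlap wins
  e4 <- r$records[r$records$event_id == "e4", ]
  expect_equal(e4$peak_id, "p1")
  expect_equal(r$quadrants["increased", "hyper"], 2L)
  expect_equal(r$quadrants["decreased", "hypo"], 1L)
  # quadrant marginals
  s <- summarize_quadrants(r$quadrants)
  expect_equal(unname(s$by_psi), c(2, 1))
  expect_equal(s$total, 3)
  # pure function: identical inputs give identical outputs
  expect_identical(r, classify_sedmas(fx$das, fx$peaks, fx$overlaps))
})

test_that("quadrant counts match planted truth at depth 1000", {
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 100, depth_per_event = 1000,
                      planted_dpsi = 0.3, frac_das = 0.45,
                      type_fractions = c(SE = 0.6, SE2 = 0.1, A5SS = 0.04,
                                         A3SS = 0.04, MXE = 0.06, RI = 0.06,
                                         none = 0.1),
                      frac_peak_genes = 0.25, frac_dm_peaks = 1,
                      merip_depth_per_bin = 200, seed = s)
    ds <- simulate_dataset(cfg)
    das <- test_differential_psi(ds$event_counts, ds$event_lengths, ds$design)
    das$gene_id <- ds$events$gene_id[match(das$event_id, ds$events$event_id)]
    pk <- call_peaks(ds$merip_bins, ds$design)
    dm <- test_differential_methylation(pk, ds$design)
    se <- ds$events[ds$events$event_type == "SE",
                    c("event_id", "chrom", "e1_start", "e1_end")]
    names(se) <- c("feature_id", "chrom", "start", "end")
    ov <- overlap_peaks_features(dm, se)
    sed <- classify_sedmas(das, dm, ov)
    tr <- ds$truth$peaks[ds$truth$peaks$differential &
                           !is.na(ds$truth$peaks$event_id), ]
    dpsi <- ds$truth$psi[tr$event_id, "SOL"] - ds$truth$psi[tr$event_id, "EDL"]
    planted <- table(
      factor(ifelse(dpsi > 0, "increased", "decreased"),
             c("increased", "decreased")),
      factor(ifelse(tr$log2fc > 0, "hyper", "hypo"), c("hyper", "hypo")))
    expect_equal(unname(sed$quadrants), unname(as.matrix(planted)),
                 info = paste("seed", s))
  }
})

test_that("knockdown intersection: disjoint, exact subset, off-by-one guard", {
  tis <- data.frame(gene_id = c("g1", "g2", "g3"),
                    e1_start = c(100, 500, 900), e1_end = c(200, 600, 1000),
                    strand = "+", stringsAsFactors = FALSE)
  kd_disjoint <- data.frame(gene_id = "g9", e1_start = 1, e1_end = 2,
                            strand = "+", stringsAsFactors = FALSE)
  expect_equal(intersect_knockdown(tis, kd_disjoint)$n_shared, 0)
  kd <- tis[1:2, ]
  r <- intersect_knockdown(tis, kd)
  expect_equal(r$n_shared, 2)
  expect_equal(r$percent_of_tissue, 66.7)
  expect_equal(r$shared$gene_id, c("g1", "g2"))
  kd_shift <- kd
  kd_shift$e1_start <- kd_shift$e1_start + 1
  kd_shift$e1_end <- kd_shift$e1_end + 1
  expect_warning(intersect_knockdown(tis, kd_shift), "coordinate conventions")
})

test_that("knockdown truth subset is recovered end-to-end", {
  cfg <- sim_config(n_genes = 80, depth_per_event = 500, planted_dpsi = 0.35,
                    frac_das = 0.4, seed = 31)
  ds <- simulate_dataset(cfg)
  das <- test_differential_psi(ds$event_counts, ds$event_lengths, ds$design)
  sig <- das$event_id[das$das]
  ev <- ds$events
  tis <- ev[ev$event_id %in% sig, c("gene_id", "e1_start", "e1_end", "strand")]
  # knockdown run: same catalogue, a chosen half of the tissue events
  sub <- tis[seq_len(floor(nrow(tis) / 2)), ]
  r <- intersect_knockdown(tis, sub)
  expect_equal(r$n_shared, nrow(sub))
  expect_equal(r$shared[order(r$shared$gene_id), ],
               sub[order(sub$gene_id), ], ignore_attr = TRUE)
})

test_that("RRACH scan: canonical motifs, overlaps, N handling, regex oracle", {
  expect_equal(rrach_scan("GGACU")$count, 1)
  expect_equal(rrach_scan("GGACU")$positions, 0)
  expect_equal(rrach_scan("CCCCC")$count, 0)
  expect_equal(rrach_scan("GGACAGACU")$positions, c(0, 4))
  expect_equal(rrach_scan("GGNCU")$count, 0)
  expect_error(rrach_scan("GGAXU"), "characters")
  # reverse strand: motif on the complement reported in input coordinates
  fwd <- "GGACT"
  rc <- "AGTCC"
  expect_equal(rrach_scan(rc, reverse_complement = TRUE)$count, 1)

  set.seed(13)
  for (i in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 1000, TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    got <- rrach_scan(s)
    expect_identical(got$positions, rrach_regex(s), info = paste("seq", i))
    expect_equal(got$count, length(rrach_regex(s)))
  }
})

test_that("RT-PCR inclusion formula", {
  expect_equal(rtpcr_inclusion(1, 0), 1)
  expect_equal(rtpcr_inclusion(0, 1), 0)
  expect_equal(rtpcr_inclusion(30, 70), 0.3)
  expect_error(rtpcr_inclusion(0, 0), "zero")
})
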