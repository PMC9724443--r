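merip_fixture <- function(seed = 1, n_genes = 60, enrich = 0, dm = 0,
                          depth = 100) {
  cfg <- sim_config(n_genes = n_genes, merip_depth_per_bin = depth,
                    merip_base_log2 = enrich, planted_m6a_log2fc = dm,
                    frac_peak_genes = if (enrich > 0) 0.3 else 0,
                    frac_dm_peaks = if (dm > 0) 1 else 0, seed = seed)
  m <- simulate_gene_models(cfg)
  tp <- simulate_true_psi(m$events, cfg)
  list(cfg = cfg, mer = simulate_merip(m, tp$das_events, cfg),
       design = sim_design(cfg))
}

test_that("no peaks without enrichment; planted 4x bins recovered", {
  fx <- merip_fixture(seed = 2, enrich = 0)
  pk <- call_peaks(fx$mer$bins, fx$design)
  # biological overdispersion leaves the pooled Fisher test a little
  # anti-conservative; stray peaks must stay a trace fraction of the bins
  expect_lte(nrow(pk), ceiling(0.01 * nrow(fx$mer$bins)))

  rec <- vapply(1:10, function(s) {
    fx <- merip_fixture(seed = s, enrich = 2)
    pk <- call_peaks(fx$mer$bins, fx$design)
    tr <- fx$mer$peaks_truth
    hit <- vapply(seq_len(nrow(tr)), function(j)
      any(pk$gene_id == tr$gene_id[j] & pk$start < tr$end[j] &
            pk$end > tr$start[j]), logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})

test_that("adjacent significant bins merge into one peak", {
  des <- data.frame(sample_id = c("a1", "b1"), condition = c("EDL", "SOL"))
  bins <- data.frame(bin_id = sprintf("b%02d", 1:20), chrom = "1",
                     start = seq(0, 1900, 100), end = seq(100, 2000, 100),
                     gene_id = "g1",
                     ip_a1 = 100, input_a1 = 100,
                     ip_b1 = 100, input_b1 = 100,
                     stringsAsFactors = FALSE)
  bins$ip_a1[8:9] <- 4000; bins$ip_b1[8:9] <- 4000
  pk <- call_peaks(bins, des)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start, pk$end), c(700, 900))
  expect_equal(pk$n_bins, 2L)
})

test_that("MFPKM: identity, hand mean, zero-input exclusion", {
  des <- data.frame(sample_id = paste0("s", 1:3), condition = "EDL")
  ip <- matrix(c(2, 4, 6), 1, 3, dimnames = list("p1", paste0("s", 1:3)))
  inp <- matrix(1, 1, 3, dimnames = list("p1", paste0("s", 1:3)))
  expect_equal(unname(compute_mfpkm(ip, ip, des)$mfpkm[1, 1]), 1)
  expect_equal(unname(compute_mfpkm(ip, inp, des)$mfpkm[1, 1]), 4)
  inp0 <- inp; inp0[1, 2] <- 0
  r <- compute_mfpkm(ip, inp0, des)
  expect_equal(unname(r$mfpkm[1, 1]), mean(c(2, 6)))
  expect_equal(unname(r$n_excluded[1, 1]), 1)
  inp_all0 <- inp * 0
  expect_true(is.na(compute_mfpkm(ip, inp_all0, des)$mfpkm[1, 1]))
})

test_that("differential methylation: null peak not flagged, label swap negates", {
  des <- data.frame(sample_id = paste0("s", 1:6),
                    condition = rep(c("EDL", "SOL"), each = 3))
  pk <- data.frame(peak_id = "p1", chrom = "1", start = 0, end = 200,
                   gene_id = "g1", n_bins = 2, stringsAsFactors = FALSE)
  for (s in paste0("s", 1:6)) { pk[[paste0("ip_", s)]] <- 400
                                pk[[paste0("input_", s)]] <- 100 }
  r <- test_differential_methylation(pk, des)
  expect_equal(r$log2fc, 0)
  expect_false(r$significant)

  pk2 <- pk
  for (s in paste0("s", 4:6)) pk2[[paste0("ip_", s)]] <- 1600
  # a second, balanced peak anchors the library totals
  pk2 <- rbind(pk2, pk)
  pk2$peak_id <- c("p1", "p2")
  r2 <- test_differential_methylation(pk2, des)
  # presenting the SOL samples first makes EDL the numerator condition
  des_sw <- des[c(4:6, 1:3), ]
  r3 <- test_differential_methylation(pk2, des_sw)
  expect_equal(r3$log2fc, -r2$log2fc)
  expect_equal(r3$pvalue, r2$pvalue, tolerance = 1e-10)
  expect_equal(r2$direction[1], "hyper")
})

test_that("planted differential enrichment is recovered with direction", {
  hits <- vapply(1:10, function(s) {
    fx <- merip_fixture(seed = s, enrich = 2, dm = 2, depth = 200)
    pk <- call_peaks(fx$mer$bins, fx$design)
    dm <- test_differential_methylation(pk, fx$design)
    tr <- fx$mer$peaks_truth[fx$mer$peaks_truth$differential, ]
    ok <- vapply(seq_len(nrow(tr)), function(j) {
      m <- dm$gene_id == tr$gene_id[j] & dm$start < tr$end[j] &
        dm$end > tr$start[j]
      any(m & dm$significant &
            sign(dm$log2fc) == sign(tr$log2fc[j]), na.rm = TRUE)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("interval overlap: hand cases and all-pairs oracle", {
  pk <- data.frame(peak_id = c("p1", "p2"), chrom = "1",
                   start = c(100, 0), end = c(200, 50),
                   stringsAsFactors = FALSE)
  ft <- data.frame(feature_id = c("f1", "f2", "f3"), chrom = "1",
                   start = c(150, 200, 600), end = c(250, 300, 700),
                   stringsAsFactors = FALSE)
  ov <- overlap_peaks_features(pk, ft, flank = 1000)
  o11 <- ov[ov$peak_id == "p1" & ov$feature_id == "f1", ]
  expect_equal(o11$overlap_bp, 50)
  expect_equal(o11$relation, "spans-boundary")
  # shared boundary point does not overlap under half-open semantics
  o12 <- ov[ov$peak_id == "p1" & ov$feature_id == "f2", ]
  expect_equal(o12$relation, "flanking-1kb")
  o23 <- ov[ov$peak_id == "p2" & ov$feature_id == "f3", ]
  expect_equal(o23$relation, "flanking-1kb")
  expect_error(overlap_peaks_features(pk, ft, flank = -1), ">= 0")

  set.seed(11)
  for (rep in 1:5) {
    pk <- data.frame(peak_id = sprintf("p%03d", 1:80),
                     chrom = sample(c("1", "2"), 80, TRUE),
                     start = sample(0:5000, 80), stringsAsFactors = FALSE)
    pk$end <- pk$start + sample(20:400, 80, TRUE)
    ft <- data.frame(feature_id = sprintf("f%03d", 1:60),
                     chrom = sample(c("1", "2"), 60, TRUE),
                     start = sample(0:5000, 60), stringsAsFactors = FALSE)
    ft$end <- ft$start + sample(20:400, 60, TRUE)
    got <- overlap_peaks_features(pk, ft, flank = 500)
    want <- overlap_naive(pk, ft, flank = 500)
    key <- function(d) sort(paste(d$peak_id, d$feature_id, d$overlap_bp,
                                  d$relation))
    expect_identical(key(got), key(want))
  }
})
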