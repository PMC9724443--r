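test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(depth_per_event = -1), "depth_per_event")
  expect_error(sim_config(planted_dpsi = 1.2), "planted_dpsi")
  expect_error(sim_config(exons_per_gene = c(3, 4)), "exons_per_gene")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
})

test_that("same seed gives bit-identical outputs, including the GTF stream", {
  cfg <- sim_config(n_genes = 40, seed = 123)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$event_counts, d2$event_counts)
  expect_identical(d1$gene_counts, d2$gene_counts)
  expect_identical(d1$merip_bins, d2$merip_bins)
  expect_identical(d1$truth, d2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(d1$genes, f1); write_gtf(d2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  d3 <- simulate_dataset(sim_config(n_genes = 40, seed = 124))
  expect_false(identical(d1$gene_counts, d3$gene_counts))
})

test_that("classification round-trips the generated truth exactly", {
  for (s in c(1, 2)) {
    cfg <- sim_config(n_genes = 100, seed = s)
    m <- simulate_gene_models(cfg)
    catal <- build_event_catalogue(m$genes)
    expect_setequal(catal$event_id, m$events$event_id)
    # per-type totals agree with truth totals
    expect_equal(count_events_per_gene(catal)$per_type,
                 count_events_per_gene(m$events)$per_type)
  }
})

test_that("truth ids all resolve to generated records", {
  ds <- simulate_dataset(sim_config(n_genes = 80, seed = 19))
  expect_true(all(ds$truth$das_events %in% ds$events$event_id))
  se_ids <- ds$events$event_id[ds$events$event_type == "SE"]
  expect_true(all(ds$truth$das_events %in% se_ids))
  expect_true(all(ds$truth$de_genes %in% ds$gene_info$gene_id))
  expect_true(all(ds$truth$m6a_genes %in% ds$gene_info$gene_id))
  expect_true(all(ds$truth$sf_targets %in% ds$events$event_id))
  expect_true(all(names(ds$truth$sf_targets) %in% rownames(ds$gene_counts)))
  expect_true(all(ds$truth$peaks$gene_id %in% ds$gene_info$gene_id))
})

test_that("junction counts: empty library, PSI boundary, binomial depth", {
  cfg0 <- sim_config(n_genes = 20, depth_per_event = 0, seed = 2)
  m <- simulate_gene_models(cfg0)
  tp <- simulate_true_psi(m$events, cfg0)
  ec <- simulate_event_counts(m$events, tp$psi, cfg0)
  expect_true(all(ec$counts$inclusion_count == 0))
  expect_true(all(ec$counts$skipping_count == 0))

  cfg <- sim_config(n_genes = 20, depth_per_event = 50, seed = 3)
  m <- simulate_gene_models(cfg)
  psi1 <- matrix(1, nrow(m$events), 2,
                 dimnames = list(m$events$event_id, c("EDL", "SOL")))
  ec1 <- simulate_event_counts(m$events, psi1, cfg)
  expect_true(all(ec1$counts$skipping_count == 0))
})

test_that("expression noise: Poisson limit and planted fold-change", {
  cfg <- sim_config(n_genes = 1200, nb_dispersion = 0, frac_de = 0, seed = 4)
  m <- simulate_gene_models(cfg)
  ex <- simulate_expression(m$gene_info, cfg)
  # after dividing out the library factors, variance/mean ~ 1 under Poisson
  # (mean across genes; the per-gene ratio is chi-squared noisy at 5 df)
  norm <- sweep(ex$counts, 2, ex$lib_factors, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  expect_lt(abs(mean(v / mu) - 1), 0.1)

  cfg2 <- sim_config(n_genes = 400, nb_dispersion = 0.02, frac_de = 0.25,
                     planted_de_log2fc = 2, seed = 5)
  m2 <- simulate_gene_models(cfg2)
  ex2 <- simulate_expression(m2$gene_info, cfg2)
  d <- sim_design(cfg2)
  norm2 <- sweep(ex2$counts, 2, ex2$lib_factors, "/")
  up <- ex2$de_genes[ex2$log2fc[ex2$de_genes] > 0]
  fc <- rowMeans(norm2[up, d$condition == "SOL"]) /
    rowMeans(norm2[up, d$condition == "EDL"])
  # Monte-Carlo aggregate lands in [3.5, 4.5] around the planted 4x
  expect_gt(mean(fc), 3.5)
  expect_lt(mean(fc), 4.5)
})

test_that("MeRIP simulation: null ratio near 1 and zero-input bins flagged", {
  cfg <- sim_config(n_genes = 60, frac_peak_genes = 0, seed = 6)
  m <- simulate_gene_models(cfg)
  tp <- simulate_true_psi(m$events, cfg)
  mer <- simulate_merip(m, tp$das_events, cfg)
  d <- sim_design(cfg)
  ip <- rowSums(as.matrix(mer$bins[, paste0("ip_", d$sample_id)]))
  inp <- rowSums(as.matrix(mer$bins[, paste0("input_", d$sample_id)]))
  expect_lt(abs(median(ip / inp) - 1), 0.1)
  expect_equal(nrow(mer$peaks_truth), 0)

  # a zero-input region yields NA MFPKM, not a division error
  des <- data.frame(sample_id = "s1", condition = "EDL")
  mf <- compute_mfpkm(matrix(5, 1, 1, dimnames = list("r", "s1")),
                      matrix(0, 1, 1, dimnames = list("r", "s1")), des)
  expect_true(is.na(mf$mfpkm[1, 1]))
})

test_that("SF coupling: sign of slope fixes the sign of rho; collisions rejected", {
  psi <- matrix(runif(12, 0.1, 0.9), 2, 6,
                dimnames = list(c("evA", "evB"), paste0("s", 1:6)))
  counts <- matrix(10, 1, 6, dimnames = list("gX", paste0("s", 1:6)))
  cfg <- sim_config(sf_coupling_noise = 0, n_sf = 2, seed = 8)
  sf <- simulate_sf_coupling(counts, c("evA", "evB"), psi, cfg)
  r1 <- spearman_rho(sf$counts["SF01", ], psi["evA", ])$rho
  r2 <- spearman_rho(sf$counts["SF02", ], psi["evB", ])$rho
  expect_equal(r1, sign(sf$sf_slopes[["SF01"]]))
  expect_equal(r2, sign(sf$sf_slopes[["SF02"]]))

  counts2 <- matrix(10, 1, 6, dimnames = list("SF01", paste0("s", 1:6)))
  expect_error(simulate_sf_coupling(counts2, "evA", psi, cfg), "collide")
})
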