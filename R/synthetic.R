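# Synthetic-data generator with planted ground truth.
#
# Emulates the study design the pipeline targets: two conditions (an
# oxidative, soleus-like muscle "SOL" and a glycolytic, extensor-like
# muscle "EDL") x three biological replicates, paired IP/input MeRIP
# libraries, negative-binomial expression noise, binomial junction counts,
# planted delta-PSI on a subset of cassette exons, planted differential m6A
# enrichment on exon-overlapping peaks, and splicing-factor expression
# monotonically coupled to target-event PSI. Every planted effect is
# returned as machine-readable truth so downstream stages are testable.

# per-stream sub-seeds so adding a stage never perturbs earlier streams
stream_seed <- function(seed, stream) {
  offs <- c(models = 1L, counts = 2L, expression = 3L, merip = 4L, sf = 5L,
            psi = 6L)
  if (!stream %in% names(offs)) stop("unknown RNG stream: ", stream)
  as.integer(((as.numeric(seed) %% 94906265) * 22695477 +
                offs[[stream]] * 1009) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults mirror the targeted study design: 2 conditions x 3 biological
#' replicates, with effect sizes chosen for test power at desk scale.
#'
#' @param n_genes Number of genes to generate.
#' @param exons_per_gene Integer range (length 2) of exons per gene.
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param depth_per_event Mean junction-read count per event per sample
#'   (Poisson).
#' @param nb_dispersion Negative-binomial dispersion for gene and MeRIP
#'   counts (0 = Poisson limit).
#' @param planted_dpsi Planted PSI shift (condition 2 vs 1) on the chosen
#'   SE events, in `[0, 1]`.
#' @param planted_m6a_log2fc Planted log2 enrichment change on differential
#'   m6A peaks.
#' @param planted_de_log2fc Planted expression log2 fold-change on DE genes.
#' @param sf_coupling_noise SD of the noise on the splicing-factor / PSI
#'   coupling (log2 expression scale).
#' @param type_fractions Named fractions of genes carrying each planted AS
#'   type (`SE`, `SE2` = two cassettes, `A5SS`, `A3SS`, `MXE`, `RI`,
#'   `none`); must sum to 1.
#' @param frac_das Fraction of SE events given the planted delta-PSI.
#' @param frac_de Fraction of genes given the planted expression change.
#' @param frac_peak_genes Fraction of genes carrying an m6A peak.
#' @param frac_dm_peaks Among peak genes, fraction whose peak is
#'   differential (the rest are constitutive, equally enriched in both
#'   conditions). Differential peaks are preferentially placed on cassette
#'   exons of planted differential SE events.
#' @param merip_base_log2 Baseline log2 IP/input enrichment of a peak
#'   (default 2, i.e. 4x).
#' @param merip_depth_per_bin Mean input read count per bin.
#' @param bin_width MeRIP bin width in bp.
#' @param n_sf Number of splicing-factor genes appended.
#' @param l_I,l_S Effective lengths (bp) of the inclusion and skipping
#'   isoform forms used for junction-count simulation and PSI estimation.
#' @param seed Integer RNG seed; identical configs give bit-identical data.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, exons_per_gene = c(6L, 9L),
                       n_replicates = 3L, depth_per_event = 100,
                       nb_dispersion = 0.05, planted_dpsi = 0.3,
                       planted_m6a_log2fc = 2, planted_de_log2fc = 2,
                       sf_coupling_noise = 0.1,
                       type_fractions = c(SE = 0.30, SE2 = 0.10, A5SS = 0.05,
                                          A3SS = 0.07, MXE = 0.08, RI = 0.10,
                                          none = 0.30),
                       frac_das = 0.3, frac_de = 0.1,
                       frac_peak_genes = 0.4, frac_dm_peaks = 0.5,
                       merip_base_log2 = 2, merip_depth_per_bin = 100,
                       bin_width = 100, n_sf = 8L,
                       l_I = 198, l_S = 99, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_conditions = 2L, n_replicates = as.integer(n_replicates),
              depth_per_event = depth_per_event,
              nb_dispersion = nb_dispersion,
              planted_dpsi = planted_dpsi,
              planted_m6a_log2fc = planted_m6a_log2fc,
              planted_de_log2fc = planted_de_log2fc,
              sf_coupling_noise = sf_coupling_noise,
              type_fractions = type_fractions,
              frac_das = frac_das, frac_de = frac_de,
              frac_peak_genes = frac_peak_genes,
              frac_dm_peaks = frac_dm_peaks,
              merip_base_log2 = merip_base_log2,
              merip_depth_per_bin = merip_depth_per_bin,
              bin_width = as.integer(bin_width), n_sf = as.integer(n_sf),
              l_I = l_I, l_S = l_S, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, length(cfg$exons_per_gene) == 2L)
  if (cfg$exons_per_gene[1] < 5L || cfg$exons_per_gene[2] < cfg$exons_per_gene[1])
    stop("exons_per_gene must be an increasing range with minimum >= 5 ",
         "(planted event geometry needs internal exons)")
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (cfg$depth_per_event < 0) stop("depth_per_event must be >= 0")
  if (cfg$planted_dpsi < 0 || cfg$planted_dpsi > 1)
    stop("planted_dpsi must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (abs(sum(cfg$type_fractions) - 1) > 1e-8 || any(cfg$type_fractions < 0))
    stop("type_fractions must be non-negative and sum to 1")
  if (cfg$sf_coupling_noise < 0) stop("sf_coupling_noise must be >= 0")
  invisible(cfg)
}

#' Design (sample sheet) implied by a simulation configuration
#'
#' Condition 1 is `EDL` (glycolytic-like), condition 2 is `SOL`
#' (oxidative-like); all directions downstream are condition 2 minus
#' condition 1.
#'
#' @param config A [sim_config()].
#' @return Data frame: `sample_id`, `condition`, `replicate`.
#' @export
sim_design <- function(config) {
  conds <- c("EDL", "SOL")
  data.frame(
    sample_id = paste0(rep(conds, each = config$n_replicates), "_",
                       rep(seq_len(config$n_replicates), 2L)),
    condition = rep(conds, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), 2L),
    stringsAsFactors = FALSE)
}

# negative-binomial sampler with a Poisson limit at dispersion ~ 0
rnb <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate gene models with planted AS events
#'
#' Each gene receives a chain of exons (lengths 80-300 bp, introns
#' 400-1500 bp) and, per its assigned type, transcripts that differ by
#' exactly the planted event: a skipped cassette exon (SE; `SE2` plants two
#' non-adjacent cassettes), an alternative 5'/3' splice site (intron-ward
#' extension of one exon boundary), a pair of mutually exclusive exons, or
#' a retained intron. Exon geometry is valid by construction; the returned
#' truth catalogue is exactly what [classify_as_events()] must recover.
#'
#' @param config A [sim_config()].
#' @return List: `genes` (list of [gene_model()]), `events` (truth event
#'   catalogue, same schema as [build_event_catalogue()]), `gene_info`
#'   (data frame: `gene_id`, `chrom`, `strand`, `start`, `end`, `length` =
#'   summed exon length, `planted_type`).
#' @export
simulate_gene_models <- function(config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, "models"))
  n <- config$n_genes
  types <- sample(names(config$type_fractions), n, replace = TRUE,
                  prob = config$type_fractions)
  genes <- vector("list", n)
  truth <- vector("list", n)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    chrom <- as.character(sample.int(18L, 1L))
    strand <- sample(c("+", "-"), 1L)
    k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    exlen <- sample(80:300, k, replace = TRUE)
    intlen <- sample(400:1500, k - 1L, replace = TRUE)
    offset <- (i - 1) * 2e6 + sample.int(1000L, 1L)
    starts <- offset + cumsum(c(0, exlen[-k] + intlen))
    ends <- starts + exlen
    ex <- cbind(starts, ends)
    ty <- types[i]
    tx <- list(t1 = ex)
    ev <- NULL
    g <- list(gene_id = gid, chrom = chrom, strand = strand)
    mkrow <- function(type, e1, e2 = c(NA_real_, NA_real_),
                      fl = c(NA_real_, NA_real_), fr = c(NA_real_, NA_real_))
      event_row(g, type, e1, e2, fl, fr)
    if (ty == "SE") {
      ci <- sample(2:(k - 1L), 1L)
      tx$t2 <- ex[-ci, , drop = FALSE]
      ev <- mkrow("SE", ex[ci, ], fl = ex[ci - 1L, ], fr = ex[ci + 1L, ])
    } else if (ty == "SE2") {
      c1 <- 2L; c2 <- sample(seq(c1 + 2L, k - 1L), 1L)
      tx$t2 <- ex[-c1, , drop = FALSE]
      tx$t3 <- ex[-c2, , drop = FALSE]
      ev <- rbind(mkrow("SE", ex[c1, ], fl = ex[c1 - 1L, ], fr = ex[c1 + 1L, ]),
                  mkrow("SE", ex[c2, ], fl = ex[c2 - 1L, ], fr = ex[c2 + 1L, ]))
    } else if (ty %in% c("A5SS", "A3SS")) {
      # geometry chosen so the strand-aware label equals the planted type
      alt_end <- (ty == "A5SS") == (strand == "+")
      delta <- sample(30:120, 1L)
      if (alt_end) {
        ai <- sample(seq_len(k - 1L), 1L)
        ex2 <- ex; ex2[ai, 2L] <- ex2[ai, 2L] + delta
        tx$t2 <- ex2
        long <- ex2[ai, ]; short <- ex[ai, ]
        ev <- mkrow(ty, long, short, fl = c(NA_real_, long[2]),
                    fr = ex[ai + 1L, ])
      } else {
        ai <- sample(2:k, 1L)
        ex2 <- ex; ex2[ai, 1L] <- ex2[ai, 1L] - delta
        tx$t2 <- ex2
        long <- ex2[ai, ]; short <- ex[ai, ]
        ev <- mkrow(ty, long, short, fl = ex[ai - 1L, ],
                    fr = c(long[1], NA_real_))
      }
    } else if (ty == "MXE") {
      mi <- sample(2:(k - 1L), 1L)
      gap <- ex[mi + 1L, 1L] - ex[mi, 2L]        # intron after exon mi
      blen <- sample(80:150, 1L)
      bstart <- ex[mi, 2L] + sample(30:(gap - blen - 30L), 1L)
      bex <- c(bstart, bstart + blen)
      ex2 <- ex; ex2[mi, ] <- bex
      tx$t2 <- ex2
      ev <- mkrow("MXE", ex[mi, ], bex, fl = ex[mi - 1L, ], fr = ex[mi + 1L, ])
    } else if (ty == "RI") {
      ri <- sample(seq_len(k - 1L), 1L)
      merged <- ex
      merged[ri, 2L] <- ex[ri + 1L, 2L]
      merged <- merged[-(ri + 1L), , drop = FALSE]
      tx$t2 <- merged
      ev <- mkrow("RI", c(ex[ri, 1L], ex[ri + 1L, 2L]),
                  fl = ex[ri, ], fr = ex[ri + 1L, ])
    }
    genes[[i]] <- gene_model(gid, chrom, strand, tx)
    truth[[i]] <- ev
    info[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                            start = starts[1], end = max(ends),
                            length = sum(exlen), planted_type = ty,
                            stringsAsFactors = FALSE)
  }
  truth <- truth[!vapply(truth, is.null, logical(1))]
  events <- if (length(truth)) finalize_events(do.call(rbind, truth))
            else empty_event_frame()
  list(genes = genes, events = events, gene_info = do.call(rbind, info))
}

#' Plant true PSI values per event and condition
#'
#' Baseline PSI is uniform on `[0.15, 0.65]`; a chosen subset of SE events
#' (fraction `frac_das`) additionally receives `+planted_dpsi` in
#' condition 2 (random sign per event), clamped to `[0.02, 0.98]`.
#'
#' @param events Truth event catalogue from [simulate_gene_models()].
#' @param config A [sim_config()].
#' @return List: `psi` (event x condition matrix, columns `EDL`, `SOL`),
#'   `das_events` (ids with planted non-zero delta).
#' @export
simulate_true_psi <- function(events, config) {
  set.seed(stream_seed(config$seed, "psi"))
  ev <- events$event_id
  base <- stats::runif(length(ev), 0.15, 0.65)
  psi <- cbind(EDL = base, SOL = base)
  rownames(psi) <- ev
  se <- ev[events$event_type == "SE"]
  n_das <- round(config$frac_das * length(se))
  das <- sort(sample(se, n_das))
  if (length(das) && config$planted_dpsi > 0) {
    sgn <- sample(c(-1, 1), length(das), replace = TRUE)
    psi[das, "SOL"] <- pmin(pmax(psi[das, "EDL"] +
                                   sgn * config$planted_dpsi, 0.02), 0.98)
  }
  das <- das[abs(psi[das, "SOL"] - psi[das, "EDL"]) > 1e-9]
  list(psi = psi, das_events = das)
}

#' Simulate inclusion/skipping junction counts
#'
#' Per event and sample: total junction reads `n ~ Poisson(depth)`,
#' inclusion reads `I ~ Binomial(n, q)` with `q` the read-level proportion
#' implied by the sample's true PSI under the configured effective lengths
#' (so [estimate_psi()] is unbiased for true PSI), and `S = n - I`.
#'
#' @param events Truth event catalogue.
#' @param true_psi Event x condition PSI matrix ([simulate_true_psi()]).
#' @param config A [sim_config()].
#' @param design Sample sheet ([sim_design()]).
#' @return List: `counts` (long data frame `event_id`, `sample_id`,
#'   `inclusion_count`, `skipping_count`), `lengths` (`event_id`, `l_I`,
#'   `l_S`).
#' @export
simulate_event_counts <- function(events, true_psi, config,
                                  design = sim_design(config)) {
  set.seed(stream_seed(config$seed, "counts"))
  ev <- events$event_id
  stopifnot(all(ev %in% rownames(true_psi)))
  ne <- length(ev); ns <- nrow(design)
  psi_s <- true_psi[ev, design$condition, drop = FALSE]
  q <- psi_to_read_prop(psi_s, config$l_I, config$l_S)
  n <- matrix(stats::rpois(ne * ns, config$depth_per_event), ne, ns)
  I <- matrix(stats::rbinom(ne * ns, as.vector(n), as.vector(q)), ne, ns)
  counts <- data.frame(
    event_id = rep(ev, times = ns),
    sample_id = rep(design$sample_id, each = ne),
    inclusion_count = as.vector(I),
    skipping_count = as.vector(n - I),
    stringsAsFactors = FALSE)
  lengths <- data.frame(event_id = ev, l_I = config$l_I, l_S = config$l_S,
                        stringsAsFactors = FALSE)
  list(counts = counts, lengths = lengths)
}

#' Simulate the gene-level count matrix
#'
#' Counts are negative binomial with mean
#' `baseline * (length/1kb) * libfactor * 2^(log2FC * [condition == SOL])`;
#' a fraction `frac_de` of genes receives the planted expression change
#' (random sign).
#'
#' @param gene_info Gene table from [simulate_gene_models()].
#' @param config A [sim_config()].
#' @param design Sample sheet.
#' @return List: `counts` (gene x sample matrix), `de_genes` (planted ids),
#'   `log2fc` (named per-gene planted log2FC), `lib_factors` (per-sample
#'   library-size factors used).
#' @export
simulate_expression <- function(gene_info, config, design = sim_design(config)) {
  if (config$nb_dispersion < 0) stop("negative dispersion")
  set.seed(stream_seed(config$seed, "expression"))
  g <- gene_info$gene_id
  baseline <- exp(stats::rnorm(length(g), log(150), 0.8))
  libfac <- stats::runif(nrow(design), 0.85, 1.15)
  n_de <- round(config$frac_de * length(g))
  de <- sort(sample(g, n_de))
  lfc <- stats::setNames(numeric(length(g)), g)
  lfc[de] <- sample(c(-1, 1), n_de, replace = TRUE) * config$planted_de_log2fc
  is_sol <- as.integer(design$condition == "SOL")
  mu <- outer(baseline * gene_info$length / 1e3, libfac) *
    2^(outer(lfc, is_sol))
  counts <- matrix(rnb(length(mu), as.vector(mu), config$nb_dispersion),
                   nrow = length(g),
                   dimnames = list(g, design$sample_id))
  list(counts = counts, de_genes = de, log2fc = lfc,
       lib_factors = stats::setNames(libfac, design$sample_id))
}

#' Simulate binned MeRIP-seq IP/input counts
#'
#' Bins of `bin_width` bp tile each gene's exonic regions. Input counts are
#' NB with mean `merip_depth_per_bin * libfactor`; IP counts are NB around
#' the input mean times the bin's enrichment: 1 for background bins,
#' `2^merip_base_log2` for peak bins, and
#' `2^(merip_base_log2 + planted_m6a_log2fc)` in condition SOL for
#' differential peak bins (sign per peak, random for peaks not tied to a
#' splicing event, otherwise drawn independently of the event's PSI sign).
#' Peaks are planted on one exon per chosen gene; differential peaks are
#' placed preferentially on cassette exons of planted differential SE
#' events.
#'
#' @param models Output of [simulate_gene_models()].
#' @param das_events Event ids with planted delta-PSI
#'   ([simulate_true_psi()]).
#' @param config A [sim_config()].
#' @param design Sample sheet.
#' @return List: `bins` (data frame ready for [call_peaks()]),
#'   `peaks_truth` (data frame: `gene_id`, `chrom`, `start`, `end`,
#'   `differential`, `log2fc`, `event_id` of the covered cassette exon or
#'   NA), `m6a_genes`.
#' @export
simulate_merip <- function(models, das_events, config,
                           design = sim_design(config)) {
  set.seed(stream_seed(config$seed, "merip"))
  info <- models$gene_info
  events <- models$events
  bw <- config$bin_width
  # tile exons of the union transcript (t1 covers all constitutive exons)
  binrows <- lapply(models$genes, function(gm) {
    ex <- gm$transcripts$t1
    per_exon <- lapply(seq_len(nrow(ex)), function(j) {
      from <- seq(ex[j, 1], ex[j, 2] - 1, by = bw)
      data.frame(chrom = gm$chrom, start = from,
                 end = pmin(from + bw, ex[j, 2]),
                 gene_id = gm$gene_id, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_exon)
  })
  bins <- do.call(rbind, binrows)
  bins <- bins[order(bins$chrom, bins$gene_id, bins$start), , drop = FALSE]
  bins$bin_id <- sprintf("bin_%06d", seq_len(nrow(bins)))
  rownames(bins) <- NULL
  # choose peak genes: genes of DAS SE events first (their cassette exon
  # carries the differential peak), then others
  das_se <- events[events$event_id %in% das_events &
                     events$event_type == "SE", , drop = FALSE]
  n_peak <- round(config$frac_peak_genes * nrow(info))
  n_dm <- round(config$frac_dm_peaks * n_peak)
  dm_on_das <- das_se[sample.int(nrow(das_se),
                                 min(n_dm, nrow(das_se))), , drop = FALSE]
  pool <- setdiff(info$gene_id, dm_on_das$gene_id)
  extra_dm <- sample(pool, max(0, n_dm - nrow(dm_on_das)))
  pool <- setdiff(pool, extra_dm)
  const_genes <- sample(pool, min(length(pool), n_peak - n_dm))
  peak_list <- list()
  add_peak <- function(gene_id, start, end, differential, lfc, event_id)
    data.frame(gene_id = gene_id, start = start, end = end,
               differential = differential, log2fc = lfc,
               event_id = event_id, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(dm_on_das)))
    peak_list[[length(peak_list) + 1L]] <-
      add_peak(dm_on_das$gene_id[j], dm_on_das$e1_start[j], dm_on_das$e1_end[j],
               TRUE, sample(c(-1, 1), 1L) * config$planted_m6a_log2fc,
               dm_on_das$event_id[j])
  gene_exon <- function(gid) {
    gm <- models$genes[[match(gid, info$gene_id)]]
    ex <- gm$transcripts$t1
    ex[sample.int(nrow(ex), 1L), ]
  }
  for (gid in extra_dm) {
    e <- gene_exon(gid)
    peak_list[[length(peak_list) + 1L]] <-
      add_peak(gid, e[1], e[2], TRUE,
               sample(c(-1, 1), 1L) * config$planted_m6a_log2fc, NA_character_)
  }
  for (gid in const_genes) {
    e <- gene_exon(gid)
    peak_list[[length(peak_list) + 1L]] <-
      add_peak(gid, e[1], e[2], FALSE, 0, NA_character_)
  }
  peaks_truth <- if (length(peak_list)) do.call(rbind, peak_list) else
    add_peak(character(0), numeric(0), numeric(0), logical(0), numeric(0),
             character(0))
  peaks_truth$chrom <- info$chrom[match(peaks_truth$gene_id, info$gene_id)]
  # per-bin enrichment per condition
  enr <- matrix(1, nrow(bins), 2, dimnames = list(bins$bin_id, c("EDL", "SOL")))
  for (j in seq_len(nrow(peaks_truth))) {
    hit <- bins$gene_id == peaks_truth$gene_id[j] &
      bins$start < peaks_truth$end[j] & bins$end > peaks_truth$start[j]
    enr[hit, "EDL"] <- 2^config$merip_base_log2
    enr[hit, "SOL"] <- 2^(config$merip_base_log2 +
                            (peaks_truth$differential[j]) * peaks_truth$log2fc[j])
  }
  libfac_ip <- stats::runif(nrow(design), 0.85, 1.15)
  libfac_in <- stats::runif(nrow(design), 0.85, 1.15)
  nb <- nrow(bins)
  for (s in seq_len(nrow(design))) {
    cn <- design$condition[s]
    mu_in <- config$merip_depth_per_bin * libfac_in[s] *
      (bins$end - bins$start) / config$bin_width
    mu_ip <- config$merip_depth_per_bin * libfac_ip[s] * enr[, cn] *
      (bins$end - bins$start) / config$bin_width
    bins[[paste0("input_", design$sample_id[s])]] <-
      rnb(nb, mu_in, config$nb_dispersion)
    bins[[paste0("ip_", design$sample_id[s])]] <-
      rnb(nb, mu_ip, config$nb_dispersion)
  }
  list(bins = bins, peaks_truth = peaks_truth,
       m6a_genes = sort(unique(peaks_truth$gene_id)))
}

#' Append splicing-factor expression coupled to target-event PSI
#'
#' Each splicing factor is assigned one target event; its log2 expression
#' is `a + b * PSI_sample + Normal(0, sf_coupling_noise)` with slope sign
#' alternating per factor, so with zero noise the SF/PSI Spearman
#' correlation is exactly +1 or -1.
#'
#' @param counts Gene x sample count matrix to append to.
#' @param target_events Event ids to couple to (recycled across factors).
#' @param psi_sample Event x sample matrix of per-sample true PSI.
#' @param config A [sim_config()].
#' @return List: `counts` (matrix with SF rows appended), `sf_targets`
#'   (named character: SF id -> event id), `sf_slopes` (named numeric).
#' @export
simulate_sf_coupling <- function(counts, target_events, psi_sample, config) {
  set.seed(stream_seed(config$seed, "sf"))
  n_sf <- config$n_sf
  if (n_sf == 0L)
    return(list(counts = counts, sf_targets = character(0),
                sf_slopes = numeric(0)))
  if (!length(target_events)) stop("no target events to couple to")
  sf_ids <- sprintf("SF%02d", seq_len(n_sf))
  if (any(sf_ids %in% rownames(counts)))
    stop("splicing-factor ids collide with existing gene ids")
  tgt <- rep_len(target_events, n_sf)
  b <- rep_len(c(8, -8), n_sf)
  rows <- matrix(NA_real_, n_sf, ncol(counts),
                 dimnames = list(sf_ids, colnames(counts)))
  for (j in seq_len(n_sf)) {
    lg <- 6 + b[j] * psi_sample[tgt[j], ] +
      stats::rnorm(ncol(counts), 0, config$sf_coupling_noise)
    rows[j, ] <- 2^lg
  }
  list(counts = rbind(counts, rows),
       sf_targets = stats::setNames(tgt, sf_ids),
       sf_slopes = stats::setNames(b, sf_ids))
}

#' Generate a complete synthetic dataset with truth
#'
#' Orchestrates [simulate_gene_models()], [simulate_true_psi()],
#' [simulate_event_counts()], [simulate_expression()], [simulate_merip()]
#' and [simulate_sf_coupling()] under one seed (each stage on its own RNG
#' stream, so outputs are reproducible stage-by-stage).
#'
#' @param config A [sim_config()].
#' @return List with `config`, `design`, `genes`, `gene_info`, `events`
#'   (truth catalogue), `event_counts`, `event_lengths`, `gene_counts`
#'   (including SF rows), `merip_bins`, and `truth` (list: `psi`
#'   event x condition, `psi_sample` event x sample, `das_events`,
#'   `de_genes`, `sf_targets`, `sf_slopes`, `peaks`, `m6a_genes`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  design <- sim_design(config)
  models <- simulate_gene_models(config)
  tp <- simulate_true_psi(models$events, config)
  ec <- simulate_event_counts(models$events, tp$psi, config, design)
  expr <- simulate_expression(models$gene_info, config, design)
  mer <- simulate_merip(models, tp$das_events, config, design)
  psi_sample <- tp$psi[, design$condition, drop = FALSE]
  colnames(psi_sample) <- design$sample_id
  sf <- simulate_sf_coupling(expr$counts,
                             if (length(tp$das_events)) tp$das_events else
                               models$events$event_id,
                             psi_sample, config)
  list(config = config, design = design,
       genes = models$genes, gene_info = models$gene_info,
       events = models$events,
       event_counts = ec$counts, event_lengths = ec$lengths,
       gene_counts = sf$counts, merip_bins = mer$bins,
       truth = list(psi = tp$psi, psi_sample = psi_sample,
                    das_events = tp$das_events, de_genes = expr$de_genes,
                    de_log2fc = expr$log2fc,
                    sf_targets = sf$sf_targets, sf_slopes = sf$sf_slopes,
                    peaks = mer$peaks_truth, m6a_genes = mer$m6a_genes))
}
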