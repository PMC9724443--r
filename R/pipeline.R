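# End-to-end pipeline driver: annotation -> quantification -> differential
# -> methylation -> integration -> network, with a machine-readable report.

#' Pipeline run configuration
#'
#' Bundles input paths and every analysis threshold. Thresholds default to
#' the decision rules the pipeline is built around: expressed at
#' FPKM >= 0.5 in >= 1 library; DEG at |log2FC| >= 1 and FDR < 0.05; DAS at
#' FDR < 0.05; peak bins at padj < 0.05 and fold >= 2; network edges at
#' |rho| >= 0.9 and padj < 0.05; PSI defined at >= 10 junction reads.
#'
#' @param input_dir Directory holding the input files (as written by
#'   [write_dataset()]): `annotation.gtf`, `event_counts.tsv`,
#'   `event_catalogue.tsv`, `gene_counts.tsv`, `merip_bins.tsv`,
#'   `sample_sheet.tsv`, `sf_list.txt`.
#' @param output_dir Directory for pipeline outputs (created).
#' @param fpkm_min,min_libraries Expressed-gene filter.
#' @param de_log2fc,fdr DEG criteria; `fdr` is also the DAS / peak /
#'   differential-methylation / network significance threshold.
#' @param rho_min Network correlation floor.
#' @param peak_fold Peak-calling fold floor.
#' @param flank Peak-feature flanking distance (bp).
#' @param psi_min_total Junction-coverage floor for a defined PSI.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       fpkm_min = 0.5, min_libraries = 1L,
                       de_log2fc = 1, fdr = 0.05, rho_min = 0.9,
                       peak_fold = 2, flank = 1000, psi_min_total = 10,
                       seed = 1L) {
  stopifnot(fpkm_min >= 0, de_log2fc >= 0, fdr > 0, fdr < 1,
            rho_min >= 0, rho_min <= 1, peak_fold >= 1, flank >= 0,
            psi_min_total >= 0)
  needed <- c("annotation.gtf", "event_counts.tsv", "event_catalogue.tsv",
              "gene_counts.tsv", "merip_bins.tsv", "sample_sheet.tsv",
              "sf_list.txt")
  missing <- needed[!file.exists(file.path(input_dir, needed))]
  if (length(missing))
    stop("missing input files in ", input_dir, ": ",
         paste(missing, collapse = ", "))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 fpkm_min = fpkm_min, min_libraries = as.integer(min_libraries),
                 de_log2fc = de_log2fc, fdr = fdr, rho_min = rho_min,
                 peak_fold = peak_fold, flank = flank,
                 psi_min_total = psi_min_total, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full splicing / m6A integration pipeline
#'
#' Stages: (1) read the gene models and event catalogue and summarise the
#' event types; (2) FPKM, expressed-gene filter, PSI; (3) differential
#' expression and differential PSI, DEG/DASG intersection; (4) peak
#' calling, MFPKM, differential methylation; (5) SE-DMAS four-quadrant
#' integration, AS-by-modification fractions and AS-count quartile groups;
#' (6) splicing-factor correlation network. Writes one TSV per stage plus
#' `report.json` under `config$output_dir` and returns the report.
#' Identical config and inputs produce a byte-identical `report.json`.
#' Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return The run report (class `spliceMeth_report`), invisibly a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ip <- function(f) file.path(config$input_dir, f)
  op <- function(f) file.path(config$output_dir, f)
  stage <- "setup"
  warn_counts <- list()
  res <- tryCatch({
    stage <- "annotation"
    genes <- read_gtf(ip("annotation.gtf"))
    catalogue <- read_tsv(ip("event_catalogue.tsv"))
    classified <- build_event_catalogue(genes)
    summ <- count_events_per_gene(classified)
    cat_sum <- summarize_event_catalogue(summ$per_type)
    write_tsv(classified, op("event_catalogue.tsv"), "0-based half-open")

    stage <- "quantification"
    design <- read_tsv(ip("sample_sheet.tsv"))
    gc <- read_tsv(ip("gene_counts.tsv"))
    counts <- as.matrix(gc[, design$sample_id, drop = FALSE])
    rownames(counts) <- gc$gene_id
    fpkm <- compute_fpkm(counts, gc$length)
    expressed <- filter_expressed(fpkm, config$fpkm_min, config$min_libraries)
    sf_ids <- readLines(ip("sf_list.txt"))
    expressed <- setdiff(expressed, sf_ids)
    ec <- read_tsv(ip("event_counts.tsv"))
    lens <- catalogue[, c("event_id", "l_I", "l_S")]
    psi <- psi_matrix(ec, lens, min_total = config$psi_min_total)
    write_tsv(data.frame(gene_id = rownames(fpkm), fpkm,
                         check.names = FALSE), op("fpkm.tsv"))
    write_tsv(data.frame(event_id = rownames(psi), psi,
                         check.names = FALSE), op("psi.tsv"))

    stage <- "differential"
    gene_rows <- setdiff(rownames(counts), sf_ids)
    de <- test_differential_expression(counts[gene_rows, , drop = FALSE],
                                       design$condition,
                                       lfc_min = config$de_log2fc,
                                       alpha = config$fdr)
    das <- test_differential_psi(ec, lens, design,
                                 min_total = config$psi_min_total,
                                 alpha = config$fdr)
    das$gene_id <- catalogue$gene_id[match(das$event_id, catalogue$event_id)]
    das$event_type <- catalogue$event_type[match(das$event_id,
                                                 catalogue$event_id)]
    venn <- intersect_deg_dasg(de$gene_id[de$deg],
                               das$gene_id[das$das])
    write_tsv(de, op("differential_expression.tsv"))
    write_tsv(das, op("differential_psi.tsv"))

    stage <- "methylation"
    bins <- read_tsv(ip("merip_bins.tsv"))
    peaks <- call_peaks(bins, design, alpha = config$fdr,
                        fold_min = config$peak_fold)
    dm <- test_differential_methylation(peaks, design, alpha = config$fdr)
    write_tsv(dm, op("peaks.tsv"), "0-based half-open")

    stage <- "integration"
    se_feat <- catalogue[catalogue$event_type == "SE",
                         c("event_id", "chrom", "e1_start", "e1_end")]
    names(se_feat) <- c("feature_id", "chrom", "start", "end")
    overlaps <- overlap_peaks_features(dm, se_feat, flank = config$flank)
    sed <- classify_sedmas(das, dm, overlaps)
    quad <- summarize_quadrants(sed$quadrants)
    write_tsv(sed$records, op("sedmas.tsv"))
    m6a_genes <- unique(dm$gene_id)
    expressed_genes <- intersect(expressed, gene_rows)
    as_genes <- unique(catalogue$gene_id)
    frac <- tryCatch(
      as_fraction_by_modification(expressed_genes,
                                  expressed_genes %in% m6a_genes,
                                  expressed_genes %in% as_genes),
      error = function(e) list(fraction_modified = NA_real_,
                               fraction_unmodified = NA_real_,
                               ratio = NA_real_))
    m6a_as <- intersect(m6a_genes, as_genes)
    groups <- tryCatch({
      cnt <- table(catalogue$gene_id)
      group_by_as_counts(m6a_as, as.integer(cnt[m6a_as]))
    }, error = function(e) NULL)

    stage <- "network"
    sf_fpkm <- fpkm[intersect(sf_ids, rownames(fpkm)), , drop = FALSE]
    net <- build_sf_network(sf_fpkm, psi,
                            das_events = das$event_id[das$das],
                            rho_min = config$rho_min, alpha = config$fdr,
                            sf_de_flags = NULL)
    etypes <- stats::setNames(catalogue$event_type, catalogue$event_id)
    export_network(net$edges, op("network.graphml"), op("network.sif"),
                   event_types = etypes)
    write_tsv(net$edges, op("network_edges.tsv"))

    list(classified = classified, summ = summ, cat_sum = cat_sum,
         expressed = expressed, de = de, das = das, venn = venn,
         dm = dm, sed = sed, quad = quad, frac = frac, groups = groups,
         net = net, design = design)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  report <- list(
    pipeline = "spliceMeth",
    seed = config$seed,
    thresholds = config[c("fpkm_min", "min_libraries", "de_log2fc", "fdr",
                          "rho_min", "peak_fold", "flank", "psi_min_total")],
    n_samples = nrow(res$design),
    events = list(total = res$cat_sum$total,
                  per_type = as.list(res$summ$per_type),
                  genes_per_type = as.list(res$summ$genes_per_type),
                  se_ri_percent = res$cat_sum$subset_percent,
                  genes_multi_event = sum(res$summ$per_gene$multi)),
    expression = list(n_expressed = length(res$expressed),
                      n_deg = sum(res$de$deg)),
    splicing = list(n_tested = sum(!is.na(res$das$padj)),
                    n_das = sum(res$das$das),
                    n_das_increased = sum(res$das$das &
                                            res$das$direction == "increased"),
                    n_das_decreased = sum(res$das$das &
                                            res$das$direction == "decreased")),
    deg_dasg = res$venn[c("n_deg", "n_dasg", "n_intersect")],
    methylation = list(n_peaks = nrow(res$dm),
                       n_dm_peaks = sum(res$dm$significant, na.rm = TRUE)),
    integration = list(
      n_sedmas = nrow(res$sed$records),
      n_sedmas_genes = res$sed$n_genes,
      quadrants = list(
        increased_hyper = res$sed$quadrants["increased", "hyper"],
        increased_hypo = res$sed$quadrants["increased", "hypo"],
        decreased_hyper = res$sed$quadrants["decreased", "hyper"],
        decreased_hypo = res$sed$quadrants["decreased", "hypo"]),
      by_psi = as.list(res$quad$by_psi),
      as_fraction_modified = res$frac$fraction_modified,
      as_fraction_unmodified = res$frac$fraction_unmodified,
      as_fraction_ratio = res$frac$ratio),
    network = list(n_tested = res$net$n_tested,
                   n_skipped = res$net$n_skipped,
                   n_edges = nrow(res$net$edges),
                   n_sf_connected = length(unique(res$net$edges$sf_gene_id))))
  class(report) <- c("spliceMeth_report", "list")
  validate_report(report)
  jsonlite::write_json(unclass(report), file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Validate a run report against the bundled schema
#'
#' Checks the presence and type of every required report field listed in
#' `inst/schema/report-schema.json`.
#'
#' @param report A pipeline report.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "spliceMeth"))
  check <- function(obj, spec, where) {
    for (key in names(spec)) {
      if (is.null(obj[[key]]))
        stop("report field missing: ", where, key)
      want <- spec[[key]]
      if (is.list(want)) {
        check(obj[[key]], want, paste0(where, key, "."))
      } else {
        ok <- switch(want,
                     number = is.numeric(obj[[key]]),
                     string = is.character(obj[[key]]),
                     object = is.list(obj[[key]]),
                     TRUE)
        if (!ok) stop("report field ", where, key, " must be ", want)
      }
    }
  }
  check(report, schema, "")
  invisible(TRUE)
}

#' @export
print.spliceMeth_report <- function(x, ...) {
  cat("spliceMeth pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  AS events:    ", x$events$total, " (",
      paste(names(x$events$per_type), unlist(x$events$per_type),
            sep = "=", collapse = ", "), "); SE+RI ",
      x$events$se_ri_percent, "%\n", sep = "")
  cat("  expressed:    ", x$expression$n_expressed, " genes, ",
      x$expression$n_deg, " DEG\n", sep = "")
  cat("  splicing:     ", x$splicing$n_das, "/", x$splicing$n_tested,
      " DAS (", x$splicing$n_das_increased, " up / ",
      x$splicing$n_das_decreased, " down); DEG∩DASG ",
      x$deg_dasg$n_intersect, "\n", sep = "")
  cat("  methylation:  ", x$methylation$n_peaks, " peaks, ",
      x$methylation$n_dm_peaks, " differential\n", sep = "")
  q <- x$integration$quadrants
  cat("  SE-DMAS:      ", x$integration$n_sedmas, " events / ",
      x$integration$n_sedmas_genes, " genes; quadrants ",
      "inc/hyper=", q$increased_hyper, " inc/hypo=", q$increased_hypo,
      " dec/hyper=", q$decreased_hyper, " dec/hypo=", q$decreased_hypo,
      "\n", sep = "")
  cat("  network:      ", x$network$n_edges, " edges over ",
      x$network$n_sf_connected, " splicing factors\n", sep = "")
  invisible(x)
}
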