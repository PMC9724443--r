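# Splicing-factor / AS-event correlation network: Spearman correlation of
# SF expression against PSI of differential events, BH over all tested
# pairs, edges retained at |rho| >= rho_min and padj < alpha.

#' Spearman rank correlation with analytic or exact permutation p-value
#'
#' Rho is Pearson correlation of mid-ranks (ties averaged). The default
#' p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df (two-sided);
#' `method = "exact"` enumerates all `n!` permutations (supported for
#' `n <= 8`, the small-sample regime of a 2x3 design) and reports the
#' two-sided permutation tail probability of `|rho|`.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @param method `"t"` (default) or `"exact"`.
#' @return List: `rho`, `p`, `n`. A constant vector yields `rho = NA`
#'   (callers skip such pairs).
#' @export
spearman_rho <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8L) stop("exact permutation p supported for n <= 8")
    perms <- permutations_of(n)
    rho_perm <- as.numeric(stats::cor(rx, matrix(ry[perms], nrow = n)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = p, n = n)
}

# all permutations of 1..n as an n x n! index matrix (n <= 8), built by
# inserting n at every position of each permutation of 1..(n-1)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (pos in seq_len(n)) for (j in seq_len(ncol(sub))) {
    k <- k + 1L
    out[, k] <- append(sub[, j], n, after = pos - 1L)
  }
  out
}

#' Build the splicing-factor / DAS-event correlation network
#'
#' Tests every (SF, differential AS event) pair: Spearman correlation of SF
#' expression against event PSI across samples, dropping samples with
#' missing PSI per pair; pairs with fewer than `min_n` complete samples or
#' a constant vector are skipped (and counted). BH adjustment is applied
#' over all tested pairs as one family; an edge is retained when
#' `|rho| >= rho_min` (set `signed = "positive"` to keep only positive
#' correlations) and `padj < alpha`.
#'
#' @param sf_expr SF x sample expression matrix (e.g. FPKM), rownames = SF
#'   gene ids.
#' @param psi Event x sample PSI matrix (same sample columns, NA allowed).
#' @param das_events Character vector of event ids to test (the
#'   differential events); defaults to all rows of `psi`.
#' @param rho_min Correlation floor (default 0.9).
#' @param alpha FDR threshold (default 0.05).
#' @param min_n Minimum complete sample pairs (default 4).
#' @param method P-value method, see [spearman_rho()].
#' @param signed `"both"` (default, threshold on `|rho|`) or `"positive"`.
#' @param sf_de_flags Optional named logical: SF differentially expressed.
#' @return List: `edges` (data frame `sf_gene_id`, `event_id`, `rho`, `p`,
#'   `padj`, `sf_de`), `n_tested`, `n_skipped`, `hubs` (per-SF degree,
#'   decreasing).
#' @export
build_sf_network <- function(sf_expr, psi, das_events = rownames(psi),
                             rho_min = 0.9, alpha = 0.05, min_n = 4L,
                             method = c("t", "exact"), signed = c("both", "positive"),
                             sf_de_flags = NULL) {
  method <- match.arg(method); signed <- match.arg(signed)
  if (!identical(colnames(sf_expr), colnames(psi)))
    stop("sample columns of sf_expr and psi do not match")
  das_events <- intersect(das_events, rownames(psi))
  sfs <- rownames(sf_expr)
  res <- vector("list", length(sfs) * length(das_events))
  k <- 0L; n_tested <- 0L; n_skipped <- 0L
  for (sf in sfs) {
    xs <- sf_expr[sf, ]
    for (evt in das_events) {
      ys <- psi[evt, ]
      ok <- !is.na(ys)
      if (sum(ok) < min_n) { n_skipped <- n_skipped + 1L; next }
      st <- spearman_rho(xs[ok], ys[ok], method = method)
      if (is.na(st$rho)) { n_skipped <- n_skipped + 1L; next }
      n_tested <- n_tested + 1L
      k <- k + 1L
      res[[k]] <- data.frame(sf_gene_id = sf, event_id = evt,
                             rho = st$rho, p = st$p, n = st$n,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    edges <- data.frame(sf_gene_id = character(), event_id = character(),
                        rho = numeric(), p = numeric(), padj = numeric(),
                        sf_de = logical(), stringsAsFactors = FALSE)
    return(list(edges = edges, n_tested = 0L, n_skipped = n_skipped,
                hubs = integer(0)))
  }
  tab <- do.call(rbind, res[seq_len(k)])
  tab$padj <- benjamini_hochberg(tab$p)
  keep <- if (signed == "both") abs(tab$rho) >= rho_min else tab$rho >= rho_min
  keep <- keep & !is.na(tab$padj) & tab$padj < alpha
  edges <- tab[keep, c("sf_gene_id", "event_id", "rho", "p", "padj"), drop = FALSE]
  edges$sf_de <- if (is.null(sf_de_flags)) NA else
    unname(sf_de_flags[edges$sf_gene_id])
  edges <- edges[order(edges$sf_gene_id, edges$event_id), , drop = FALSE]
  rownames(edges) <- NULL
  hubs <- sort(table(edges$sf_gene_id), decreasing = TRUE)
  list(edges = edges, n_tested = n_tested, n_skipped = n_skipped,
       hubs = hubs)
}

#' Export a correlation network to GraphML and SIF
#'
#' Writes a bipartite SF/event graph with node attributes `role`
#' (`"SF"` / `"event"`), `event_type` and `de` (SF differential-expression
#' flag), and edge attribute `rho`.
#'
#' @param edges Edge table from [build_sf_network()].
#' @param path_graphml,path_sif Output paths (either may be `NULL` to skip).
#' @param event_types Optional named character: event id -> event type.
#' @return The `igraph` graph, invisibly.
#' @export
export_network <- function(edges, path_graphml = NULL, path_sif = NULL,
                           event_types = NULL) {
  if (anyDuplicated(paste(edges$sf_gene_id, edges$event_id)))
    stop("duplicate edges")
  sfs <- unique(edges$sf_gene_id); evs <- unique(edges$event_id)
  nodes <- data.frame(name = c(sfs, evs),
                      role = c(rep("SF", length(sfs)), rep("event", length(evs))),
                      stringsAsFactors = FALSE)
  nodes$event_type <- if (is.null(event_types)) rep(NA_character_, nrow(nodes)) else
    ifelse(nodes$role == "event", unname(event_types[nodes$name]), NA_character_)
  de <- rep(NA, nrow(nodes))
  if (!is.null(edges$sf_de) && nrow(edges)) {
    m <- match(nodes$name, edges$sf_gene_id)
    de <- edges$sf_de[m]
  }
  nodes$de <- as.logical(de)
  g <- igraph::graph_from_data_frame(
    edges[, c("sf_gene_id", "event_id", "rho"), drop = FALSE],
    directed = FALSE, vertices = nodes)
  if (!is.null(path_graphml))
    igraph::write_graph(g, path_graphml, format = "graphml")
  if (!is.null(path_sif)) {
    sif <- if (nrow(edges)) paste(edges$sf_gene_id, "correlates",
                                  edges$event_id) else character(0)
    writeLines(sif, path_sif)
  }
  invisible(g)
}
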