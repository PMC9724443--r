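# AS event classification from annotated transcript structures.
#
# Events follow the five-type taxonomy (SE, A5SS, A3SS, MXE, RI) defined by
# pairwise transcript comparison. Coordinates are 0-based half-open. The
# catalogue is annotation-driven: novel junctions are not discovered.

AS_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")

empty_event_frame <- function() {
  data.frame(event_id = character(), event_type = character(),
             gene_id = character(), chrom = character(), strand = character(),
             e1_start = numeric(), e1_end = numeric(),
             e2_start = numeric(), e2_end = numeric(),
             flank_left_start = numeric(), flank_left_end = numeric(),
             flank_right_start = numeric(), flank_right_end = numeric(),
             stringsAsFactors = FALSE)
}

event_row <- function(gene, type, e1, e2 = c(NA_real_, NA_real_),
                      fl = c(NA_real_, NA_real_), fr = c(NA_real_, NA_real_)) {
  data.frame(event_id = NA_character_, event_type = type,
             gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
             e1_start = e1[1], e1_end = e1[2],
             e2_start = e2[1], e2_end = e2[2],
             flank_left_start = fl[1], flank_left_end = fl[2],
             flank_right_start = fr[1], flank_right_end = fr[2],
             stringsAsFactors = FALSE)
}

# Duplicate-suppression key: type + strand + the junction-defining
# coordinates of the event. Flanking-exon outer edges are annotation detail,
# not part of event identity.
event_key <- function(ev) {
  co <- switch(ev$event_type,
    SE   = c(ev$e1_start, ev$e1_end, ev$flank_left_end, ev$flank_right_start),
    RI   = c(ev$e1_start, ev$e1_end, ev$flank_left_end, ev$flank_right_start),
    MXE  = c(ev$e1_start, ev$e1_end, ev$e2_start, ev$e2_end,
             ev$flank_left_end, ev$flank_right_start),
    A5SS = c(ev$e1_start, ev$e1_end, ev$e2_start, ev$e2_end,
             ev$flank_left_end, ev$flank_right_start),
    A3SS = c(ev$e1_start, ev$e1_end, ev$e2_start, ev$e2_end,
             ev$flank_left_end, ev$flank_right_start))
  paste(c(ev$event_type, ev$strand, co), collapse = ":")
}

tx_junctions <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-n, 2L], ex[-1L, 1L])
}

has_junction <- function(jn, donor, acceptor) {
  nrow(jn) > 0L && any(jn[, 1L] == donor & jn[, 2L] == acceptor)
}

contains_exon <- function(ex, e) any(ex[, 1L] == e[1] & ex[, 2L] == e[2])

#' Classify alternative-splicing events in one gene
#'
#' Evaluates every ordered pair of transcripts of `gene` against the
#' five-type event taxonomy:
#' \describe{
#'   \item{SE}{a cassette exon present (with both flanking junctions) in one
#'     transcript while another transcript splices its flanking exons
#'     directly together.}
#'   \item{RI}{one transcript carries a single exon spanning exactly two
#'     exons plus the intervening intron of another transcript.}
#'   \item{A5SS / A3SS}{two transcripts share one splice site of an exon but
#'     use alternative sites on the other side, with the adjacent exon's
#'     facing splice site shared. Labels are strand-aware: the alternative
#'     site is named 5' or 3' relative to transcript orientation.}
#'   \item{MXE}{two internal exons, each present in one transcript and never
#'     co-occurring in any transcript of the gene, sharing both flanking
#'     junctions; exons must not overlap.}
#' }
#' Duplicate events (same type, strand and junction-defining coordinates)
#' are emitted once; output order is stable (type, then coordinates).
#'
#' @param gene A [gene_model()].
#' @return A data frame of events with columns `event_id`, `event_type`,
#'   `gene_id`, `chrom`, `strand`, `e1_start/end` (cassette exon, retained
#'   region, long exon or left MXE exon), `e2_start/end` (short exon or
#'   right MXE exon) and flanking-exon coordinates. Single-transcript genes
#'   yield zero rows.
#' @examples
#' g <- gene_model("g1", "1", "+", list(
#'   t1 = cbind(c(0, 200, 400), c(100, 300, 500)),
#'   t2 = cbind(c(0, 400), c(100, 500))))
#' classify_as_events(g)
#' @export
classify_as_events <- function(gene) {
  validate_gene_model(gene)
  tx <- gene$transcripts
  nt <- length(tx)
  out <- list()
  if (nt >= 2L) {
    juncs <- lapply(tx, tx_junctions)
    for (ia in seq_len(nt)) for (ib in seq_len(nt)) {
      if (ia == ib) next
      a <- tx[[ia]]; b <- tx[[ib]]; jb <- juncs[[ib]]
      na <- nrow(a)
      # SE: internal exon i of A skipped by B
      if (na >= 3L) for (i in 2:(na - 1L)) {
        if (has_junction(jb, a[i - 1L, 2L], a[i + 1L, 1L]))
          out[[length(out) + 1L]] <- event_row(gene, "SE", a[i, ],
            fl = a[i - 1L, ], fr = a[i + 1L, ])
      }
      # RI: consecutive exons x,y of A retained as one exon z of B
      if (na >= 2L) for (i in seq_len(na - 1L)) {
        x <- a[i, ]; y <- a[i + 1L, ]
        hit <- b[, 1L] == x[1] & b[, 2L] == y[2]
        if (any(hit))
          out[[length(out) + 1L]] <- event_row(gene, "RI",
            c(x[1], y[2]), fl = x, fr = y)
      }
      # A5SS / A3SS and MXE need both transcripts walked in parallel
      nb <- nrow(b)
      for (i in seq_len(na)) for (j in seq_len(nb)) {
        ae <- a[i, ]; be <- b[j, ]
        # shared start, alternative end, shared downstream acceptor
        if (ae[1] == be[1] && ae[2] != be[2] && i < na && j < nb &&
            a[i + 1L, 1L] == b[j + 1L, 1L]) {
          long <- if (ae[2] > be[2]) ae else be
          short <- if (ae[2] > be[2]) be else ae
          type <- if (gene$strand == "+") "A5SS" else "A3SS"
          dn <- if (ae[2] > be[2]) a[i + 1L, ] else b[j + 1L, ]
          out[[length(out) + 1L]] <- event_row(gene, type, long, short,
            fl = c(NA_real_, long[2]), fr = dn)
        }
        # shared end, alternative start, shared upstream donor
        if (ae[2] == be[2] && ae[1] != be[1] && i > 1L && j > 1L &&
            a[i - 1L, 2L] == b[j - 1L, 2L]) {
          long <- if (ae[1] < be[1]) ae else be
          short <- if (ae[1] < be[1]) be else ae
          type <- if (gene$strand == "+") "A3SS" else "A5SS"
          up <- if (ae[1] < be[1]) a[i - 1L, ] else b[j - 1L, ]
          out[[length(out) + 1L]] <- event_row(gene, type, long, short,
            fl = up, fr = c(long[1], NA_real_))
        }
      }
      # MXE: internal exon of A vs internal exon of B, shared flank
      # junctions, mutually exclusive across the whole gene
      if (na >= 3L && nb >= 3L) for (i in 2:(na - 1L)) for (j in 2:(nb - 1L)) {
        ea <- a[i, ]; eb <- b[j, ]
        if (identical(unname(ea), unname(eb))) next
        if (a[i - 1L, 2L] != b[j - 1L, 2L] || a[i + 1L, 1L] != b[j + 1L, 1L]) next
        if (!(ea[2] <= eb[1] || eb[2] <= ea[1])) next          # must not overlap
        both <- vapply(tx, function(e) contains_exon(e, ea) && contains_exon(e, eb),
                       logical(1))
        if (any(both)) next
        e1 <- if (ea[1] < eb[1]) ea else eb
        e2 <- if (ea[1] < eb[1]) eb else ea
        out[[length(out) + 1L]] <- event_row(gene, "MXE", e1, e2,
          fl = a[i - 1L, ], fr = a[i + 1L, ])
      }
    }
  }
  if (!length(out)) return(empty_event_frame())
  finalize_events(do.call(rbind, out))
}

# deduplicate by event key, order stably, assign deterministic ids; shared
# by the classifier and the synthetic generator's truth construction
finalize_events <- function(ev) {
  keys <- vapply(seq_len(nrow(ev)), function(k) event_key(ev[k, ]), character(1))
  ev <- ev[!duplicated(keys), , drop = FALSE]
  ev <- ev[order(match(ev$event_type, AS_TYPES), ev$e1_start, ev$e1_end,
                 ev$e2_start, na.last = TRUE), , drop = FALSE]
  ev$event_id <- vapply(seq_len(nrow(ev)), function(k)
    paste0(ev$event_type[k], "|", ev$gene_id[k], "|",
           event_key(ev[k, ])), character(1))
  rownames(ev) <- NULL
  ev
}

#' Build the AS event catalogue for a set of genes
#'
#' @param genes A list of [gene_model()] objects.
#' @return One event data frame (see [classify_as_events()]) over all genes.
#' @export
build_event_catalogue <- function(genes) {
  evs <- lapply(genes, classify_as_events)
  evs <- evs[vapply(evs, nrow, integer(1)) > 0L]
  if (!length(evs)) return(empty_event_frame())
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Per-gene event multiplicity summary
#'
#' Tabulates, per gene, how many events of each type it carries, and flags
#' genes containing two or more events.
#'
#' @param events Event data frame from [classify_as_events()] /
#'   [build_event_catalogue()].
#' @return A list with `per_gene` (data frame: gene_id, one column per event
#'   type, `n_events`, `multi` flag) and `per_type` (named vector of event
#'   counts) and `genes_per_type` (named vector of parent-gene counts).
#' @export
count_events_per_gene <- function(events) {
  if (nrow(events) == 0L) {
    pg <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    for (t in AS_TYPES) pg[[t]] <- integer()
    pg$n_events <- integer(); pg$multi <- logical()
    return(list(per_gene = pg,
                per_type = stats::setNames(integer(length(AS_TYPES)), AS_TYPES),
                genes_per_type = stats::setNames(integer(length(AS_TYPES)), AS_TYPES)))
  }
  tab <- table(factor(events$gene_id), factor(events$event_type, levels = AS_TYPES))
  pg <- data.frame(gene_id = rownames(tab), stringsAsFactors = FALSE)
  for (t in AS_TYPES) pg[[t]] <- as.integer(tab[, t])
  pg$n_events <- as.integer(rowSums(tab))
  pg$multi <- pg$n_events >= 2L
  per_type <- stats::setNames(as.integer(colSums(tab)), AS_TYPES)
  genes_per_type <- stats::setNames(as.integer(colSums(tab > 0L)), AS_TYPES)
  rownames(pg) <- NULL
  list(per_gene = pg, per_type = per_type, genes_per_type = genes_per_type)
}

#' Catalogue totals and per-type percentages
#'
#' Computes the total event count and the percentage contributed by each
#' type (and any requested subset of types), rounded to two decimals with
#' round-half-to-even.
#'
#' @param per_type_counts Named non-negative counts for the five event types
#'   (names among `SE, A5SS, A3SS, MXE, RI`).
#' @param subset Character vector of types whose combined share to report
#'   (default `c("SE", "RI")`, the two dominant classes).
#' @return List with `total`, `percent` (named per-type vector) and
#'   `subset_percent`.
#' @examples
#' summarize_event_catalogue(c(SE = 23416, A5SS = 1013, A3SS = 1778,
#'                             MXE = 1968, RI = 2178))
#' @export
summarize_event_catalogue <- function(per_type_counts, subset = c("SE", "RI")) {
  stopifnot(all(names(per_type_counts) %in% AS_TYPES),
            all(per_type_counts >= 0))
  total <- sum(per_type_counts)
  if (total == 0) stop("all per-type counts are zero; percentages undefined")
  pct <- round(100 * per_type_counts / total, 2)
  sub <- round(100 * sum(per_type_counts[intersect(subset, names(per_type_counts))]) / total, 2)
  list(total = as.numeric(total), percent = pct, subset_percent = as.numeric(sub))
}
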