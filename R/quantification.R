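# FPKM normalisation, the expressed-gene filter, and PSI estimation.

#' Fragments per kilobase per million (FPKM)
#'
#' `FPKM = count / (length/1000) / (library_size/1e6)`. Library size is the
#' total number of counted fragments per sample (configurable by passing
#' your own `library_sizes`).
#'
#' @param counts Gene x sample numeric matrix of non-negative counts.
#' @param lengths Per-gene effective lengths in bp (> 0).
#' @param library_sizes Per-sample library sizes; defaults to column sums.
#' @return FPKM matrix, same dimensions as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(library_sizes) == ncol(counts),
            all(lengths > 0), all(counts >= 0))
  if (any(library_sizes <= 0)) stop("library size must be > 0 for every sample")
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, library_sizes / 1e6, "/")
}

#' Expressed-gene filter
#'
#' A gene is considered expressed when its FPKM reaches `threshold`
#' (inclusive) in at least `min_libraries` samples.
#'
#' @param fpkm FPKM matrix with gene rownames.
#' @param threshold FPKM floor (default 0.5).
#' @param min_libraries Minimum number of samples at/above the floor.
#' @return Character vector of expressed gene ids (in input row order).
#' @export
filter_expressed <- function(fpkm, threshold = 0.5, min_libraries = 1L) {
  stopifnot(!is.null(rownames(fpkm)))
  keep <- rowSums(fpkm >= threshold) >= min_libraries
  rownames(fpkm)[keep]
}

#' Percent-spliced-in from inclusion/skipping counts
#'
#' Length-normalised inclusion level
#' `PSI = (I/l_I) / (I/l_I + S/l_S)`, the rMATS-style estimator where `l_I`
#' and `l_S` are the effective lengths of the inclusion and skipping forms.
#' Returns `NA` where total junction coverage `I + S` is below `min_total`
#' (or where `I + S == 0`). Vectorised over events/cells.
#'
#' @param I Inclusion junction counts.
#' @param S Skipping junction counts.
#' @param l_I,l_S Effective lengths (> 0) of the inclusion and skipping
#'   isoforms.
#' @param min_total Coverage floor below which PSI is reported missing.
#' @return Numeric vector of PSI values in `[0, 1]` or `NA`.
#' @export
estimate_psi <- function(I, S, l_I, l_S, min_total = 10) {
  stopifnot(all(I >= 0), all(S >= 0))
  if (any(l_I <= 0) || any(l_S <= 0)) stop("effective lengths must be > 0")
  ni <- I / l_I; ns <- S / l_S
  psi <- ni / (ni + ns)
  psi[I + S < pmax(min_total, 1)] <- NA_real_
  psi
}

#' PSI matrix from an event-count table
#'
#' @param event_counts Data frame with columns `event_id`, `sample_id`,
#'   `inclusion_count`, `skipping_count`.
#' @param lengths Data frame with columns `event_id`, `l_I`, `l_S`.
#' @param min_total Coverage floor, see [estimate_psi()].
#' @return Event x sample matrix of PSI (rownames event ids).
#' @export
psi_matrix <- function(event_counts, lengths, min_total = 10) {
  stopifnot(all(c("event_id", "sample_id", "inclusion_count", "skipping_count")
                %in% names(event_counts)),
            all(c("event_id", "l_I", "l_S") %in% names(lengths)))
  ev <- unique(lengths$event_id)
  sm <- sort(unique(event_counts$sample_id))
  li <- stats::setNames(lengths$l_I, lengths$event_id)
  ls <- stats::setNames(lengths$l_S, lengths$event_id)
  if (!all(event_counts$event_id %in% ev))
    stop("event-count table contains events without effective lengths")
  out <- matrix(NA_real_, length(ev), length(sm), dimnames = list(ev, sm))
  i <- match(event_counts$event_id, ev)
  j <- match(event_counts$sample_id, sm)
  out[cbind(i, j)] <- estimate_psi(event_counts$inclusion_count,
                                   event_counts$skipping_count,
                                   li[event_counts$event_id],
                                   ls[event_counts$event_id],
                                   min_total = min_total)
  out
}
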