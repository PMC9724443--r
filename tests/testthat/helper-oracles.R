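# Independent oracles, deliberately written with different algorithms than
# the package implementations they check.

# Naive O(m^2) BH step-up: for each p_i, the minimum of m*p_j/rank_j over
# all p_j >= p_i, with max-rank tie handling.
bh_naive <- function(p) {
  m <- length(p)
  rk <- vapply(p, function(x) sum(p <= x), numeric(1))
  vapply(seq_len(m), function(i) {
    cand <- m * p[p >= p[i]] / rk[p >= p[i]]
    min(1, min(cand))
  }, numeric(1))
}

# Spearman rho via the classical rank-difference formula (tie-free input)
spearman_formula <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# RRACH scan via regex lookahead (overlaps allowed), 0-based positions
rrach_regex <- function(seq) {
  s <- toupper(chartr("uU", "tT", seq))
  m <- gregexpr("(?=[AG][AG]AC[ACT])", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# All-pairs interval overlap with half-open semantics and a flank rule
overlap_naive <- function(peaks, features, flank = 1000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(features))) {
    if (peaks$chrom[i] != features$chrom[j]) next
    ov <- min(peaks$end[i], features$end[j]) -
      max(peaks$start[i], features$start[j])
    if (ov >= 1) {
      rel <- if (peaks$start[i] >= features$start[j] &&
                 peaks$end[i] <= features$end[j]) "within-exon" else "spans-boundary"
      out[[length(out) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[i], feature_id = features$feature_id[j],
        overlap_bp = ov, relation = rel, stringsAsFactors = FALSE)
    } else {
      gap <- max(features$start[j] - peaks$end[i],
                 peaks$start[i] - features$end[j])
      if (gap <= flank)
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], feature_id = features$feature_id[j],
          overlap_bp = 0, relation = "flanking-1kb", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(peak_id = character(),
                                      feature_id = character(),
                                      overlap_bp = numeric(),
                                      relation = character()))
  do.call(rbind, out)
}

# ---- exhaustive AS-event enumeration over the exon universe ----------------
# A deliberately different formulation: enumerate candidate coordinate
# tuples from the union of all exons, then test membership conditions
# against the transcript set.

# does transcript ex contain these intervals as a consecutive run?
contains_run <- function(ex, run) {
  n <- nrow(ex); k <- nrow(run)
  if (n < k) return(FALSE)
  for (s in seq_len(n - k + 1L))
    if (all(ex[s:(s + k - 1L), ] == run)) return(TRUE)
  FALSE
}

has_exon <- function(ex, e) any(ex[, 1] == e[1] & ex[, 2] == e[2])

has_junc <- function(ex, donor, acceptor) {
  n <- nrow(ex)
  n >= 2 && any(ex[-n, 2] == donor & ex[-1, 1] == acceptor)
}

classify_oracle <- function(gene) {
  txs <- gene$transcripts
  U <- unique(do.call(rbind, txs))
  U <- U[order(U[, 1], U[, 2]), , drop = FALSE]
  nu <- nrow(U)
  keys <- character(0)
  add <- function(...) keys <<- c(keys, paste(..., sep = ":"))
  # SE: consecutive triple (u,c,d) in some transcript; junction u.end->d.start
  # in another
  for (iu in seq_len(nu)) for (ic in seq_len(nu)) for (id in seq_len(nu)) {
    u <- U[iu, ]; cc <- U[ic, ]; d <- U[id, ]
    if (!(u[2] <= cc[1] && cc[2] <= d[1])) next
    run_ok <- any(vapply(txs, contains_run, logical(1), rbind(u, cc, d)))
    if (!run_ok) next
    if (any(vapply(txs, has_junc, logical(1), u[2], d[1])))
      add("SE", cc[1], cc[2], u[2], d[1])
  }
  # RI: consecutive pair (x,y) in one transcript, single exon spanning both
  # in another
  for (ix in seq_len(nu)) for (iy in seq_len(nu)) {
    x <- U[ix, ]; y <- U[iy, ]
    if (x[2] >= y[1]) next
    if (!any(vapply(txs, contains_run, logical(1), rbind(x, y)))) next
    if (any(vapply(txs, has_exon, logical(1), c(x[1], y[2]))))
      add("RI", x[1], y[2], x[2], y[1])
  }
  # alternative donor/acceptor: exon pair sharing one boundary, with the
  # facing splice site of the adjacent exon shared
  for (il in seq_len(nu)) for (is in seq_len(nu)) {
    l <- U[il, ]; s <- U[is, ]
    if (l[1] == s[1] && l[2] > s[2]) {          # shared start, alt end
      for (id in seq_len(nu)) {
        d <- U[id, ]
        if (d[1] < l[2]) next
        okl <- any(vapply(txs, function(e) contains_run(e, rbind(l, d)),
                          logical(1)))
        # the short form may splice to any exon starting where d starts
        oks <- any(vapply(txs, function(e) {
          n <- nrow(e)
          n >= 2 && any(e[-n, 1] == s[1] & e[-n, 2] == s[2] & e[-1, 1] == d[1])
        }, logical(1)))
        if (okl && oks) {
          ty <- if (gene$strand == "+") "A5SS" else "A3SS"
          add(ty, l[1], l[2], s[1], s[2], d[1])
        }
      }
    }
    if (l[2] == s[2] && l[1] < s[1]) {          # shared end, alt start
      for (iu in seq_len(nu)) {
        u <- U[iu, ]
        if (u[2] > l[1]) next
        okl <- any(vapply(txs, function(e) contains_run(e, rbind(u, l)),
                          logical(1)))
        oks <- any(vapply(txs, function(e) {
          n <- nrow(e)
          n >= 2 && any(e[-1, 1] == s[1] & e[-1, 2] == s[2] & e[-n, 2] == u[2])
        }, logical(1)))
        if (okl && oks) {
          ty <- if (gene$strand == "+") "A3SS" else "A5SS"
          add(ty, l[1], l[2], s[1], s[2], u[2])
        }
      }
    }
  }
  # MXE: each of two non-overlapping exons flanked (as a consecutive triple)
  # by exons sharing the facing junctions; never co-occurring gene-wide
  for (ia in seq_len(nu)) for (ib in seq_len(nu)) {
    ea <- U[ia, ]; eb <- U[ib, ]
    if (ea[2] > eb[1]) next
    if (any(vapply(txs, function(e) has_exon(e, ea) && has_exon(e, eb),
                   logical(1)))) next
    for (iu in seq_len(nu)) for (id in seq_len(nu)) {
      u <- U[iu, ]; d <- U[id, ]
      oka <- any(vapply(txs, function(e) {
        n <- nrow(e)
        n >= 3 && any(e[-c(n - 1, n), 2] == u[2] &
                        e[-c(1, n), 1] == ea[1] & e[-c(1, n), 2] == ea[2] &
                        e[-c(1, 2), 1] == d[1])
      }, logical(1)))
      if (!oka) next
      okb <- any(vapply(txs, function(e) {
        n <- nrow(e)
        n >= 3 && any(e[-c(n - 1, n), 2] == u[2] &
                        e[-c(1, n), 1] == eb[1] & e[-c(1, n), 2] == eb[2] &
                        e[-c(1, 2), 1] == d[1])
      }, logical(1)))
      if (okb) add("MXE", ea[1], ea[2], eb[1], eb[2], u[2], d[1])
    }
  }
  sort(unique(keys))
}

# canonical keys for classify_as_events() output, comparable to the oracle
event_keys_canonical <- function(ev) {
  if (nrow(ev) == 0L) return(character(0))
  k <- vapply(seq_len(nrow(ev)), function(i) {
    r <- ev[i, ]
    switch(r$event_type,
      SE = paste("SE", r$e1_start, r$e1_end, r$flank_left_end,
                 r$flank_right_start, sep = ":"),
      RI = paste("RI", r$e1_start, r$e1_end, r$flank_left_end,
                 r$flank_right_start, sep = ":"),
      A5SS = ,
      A3SS = {
        # alt-start events carry the shared donor in flank_left_end (their
        # flank_right_end is NA); alt-end events carry the shared acceptor
        # in flank_right_start
        if (!is.na(r$flank_right_start) && is.na(r$flank_right_end))
          paste(r$event_type, r$e1_start, r$e1_end, r$e2_start, r$e2_end,
                r$flank_left_end, sep = ":")
        else
          paste(r$event_type, r$e1_start, r$e1_end, r$e2_start, r$e2_end,
                r$flank_right_start, sep = ":")
      },
      MXE = paste("MXE", r$e1_start, r$e1_end, r$e2_start, r$e2_end,
                  r$flank_left_end, r$flank_right_start, sep = ":"))
  }, character(1))
  sort(unique(k))
}
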