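# Programmatic fixtures.

# A minimal cassette-exon gene: t1 = e1,e2,e3; t2 = e1,e3.
toy_se_gene <- function(strand = "+") {
  gene_model("gSE", "1", strand, list(
    t1 = cbind(c(100, 400, 800), c(200, 500, 900)),
    t2 = cbind(c(100, 800), c(200, 900))))
}

# Random toy gene models with <= 4 transcripts over a variant exon universe
# (base chain, extended boundaries, merged pairs, intronic alternatives) --
# dense in all five event types for oracle comparison.
random_toy_gene <- function(seed) {
  set.seed(seed)
  k <- sample(3:5, 1)
  exlen <- sample(c(100, 150, 200), k, replace = TRUE)
  intlen <- sample(c(300, 500), k - 1, replace = TRUE)
  starts <- cumsum(c(1000, exlen[-k] + intlen))
  base <- cbind(starts, starts + exlen)
  make_tx <- function() {
    ex <- list()
    i <- 1L
    while (i <= k) {
      choice <- sample(c("base", "skip", "ext_end", "ext_start", "merge",
                         "alt"), 1,
                       prob = c(0.5, 0.2, 0.08, 0.08, 0.07, 0.07))
      if (choice == "merge" && i < k) {
        ex[[length(ex) + 1L]] <- c(base[i, 1], base[i + 1, 2])
        i <- i + 2L
      } else if (choice == "skip" && length(ex) + (k - i) >= 1) {
        i <- i + 1L
      } else if (choice == "ext_end" && i < k) {
        ex[[length(ex) + 1L]] <- c(base[i, 1], base[i, 2] + 60)
        i <- i + 1L
      } else if (choice == "ext_start" && i > 1) {
        ex[[length(ex) + 1L]] <- c(base[i, 1] - 60, base[i, 2])
        i <- i + 1L
      } else if (choice == "alt" && i < k) {
        # exon inside the intron after position i, replacing exon i
        ex[[length(ex) + 1L]] <- c(base[i, 2] + 80, base[i, 2] + 180)
        i <- i + 1L
      } else {
        ex[[length(ex) + 1L]] <- base[i, ]
        i <- i + 1L
      }
    }
    if (!length(ex)) return(NULL)
    m <- do.call(rbind, ex)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])) return(NULL)
    m
  }
  txs <- list()
  for (t in seq_len(sample(2:4, 1))) {
    m <- make_tx()
    if (!is.null(m)) txs[[length(txs) + 1L]] <- m
  }
  txs <- unique(txs)
  if (length(txs) < 2L) txs <- list(base, base[-2, , drop = FALSE])
  names(txs) <- paste0("t", seq_along(txs))
  gene_model(paste0("toy", seed), "1", sample(c("+", "-"), 1), txs)
}

# Small simulated count matrix for DE tests
nb_counts <- function(n_genes, mu0, lfc, cond, dispersion = 0.05) {
  mu <- outer(mu0, rep(1, length(cond))) *
    2^outer(lfc, as.integer(cond == levels(factor(cond))[2]))
  matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = n_genes,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         paste0("s", seq_along(cond))))
}
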