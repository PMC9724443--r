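test_that("Spearman rho: perfect ranks, reversal, hand value, oracle", {
  expect_equal(spearman_rho(1:6, 1:6)$rho, 1)
  expect_equal(spearman_rho(1:6, 6:1)$rho, -1)
  st <- spearman_rho(1:6, c(2, 1, 4, 3, 6, 5))
  expect_equal(round(st$rho, 4), 0.8286)
  expect_equal(st$rho, spearman_formula(1:6, c(2, 1, 4, 3, 6, 5)),
               tolerance = 1e-10)
  # tie-free random vectors match the rank-difference formula
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    expect_equal(spearman_rho(x, y)$rho, spearman_formula(x, y),
                 tolerance = 1e-10)
  }
  # invariance under strictly monotone transforms
  x <- c(3, 1, 8, 5, 9, 2); y <- c(0.2, 0.9, 0.4, 0.8, 0.1, 0.5)
  expect_equal(spearman_rho(exp(x), y)$rho, spearman_rho(x, y)$rho)
  expect_equal(spearman_rho(x, y^3)$rho, spearman_rho(x, y)$rho)
  # constant vector is skipped, not an error
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)$rho))
})

test_that("exact permutation p agrees with the permutation definition", {
  x <- 1:6; y <- c(2, 1, 4, 3, 6, 5)
  st <- spearman_rho(x, y, method = "exact")
  # brute force over all 720 permutations using R's own correlation
  perms <- combinat_perms <- NULL
  all_p <- t(sapply(seq_len(720), function(i) i))  # placeholder index
  ref <- {
    p0 <- abs(cor(rank(x), rank(y)))
    ge <- 0; tot <- 0
    idx <- seq_len(6)
    rec <- function(cur, rest) {
      if (!length(rest)) {
        tot <<- tot + 1
        if (abs(cor(idx, cur)) >= p0 - 1e-12) ge <<- ge + 1
        return(invisible())
      }
      for (r in seq_along(rest)) rec(c(cur, rest[r]), rest[-r])
    }
    rec(integer(0), y)
    ge / tot
  }
  expect_equal(st$p, ref)
})

test_that("noise-free couplings with distinct PSI profiles give the exact edge set", {
  set.seed(23)
  n_events <- 24; n_sf <- 6
  # event PSI profiles constructed pairwise rank-distinguishable
  profiles <- list()
  while (length(profiles) < n_events) {
    cand <- runif(6, 0.1, 0.9)
    ok <- all(vapply(profiles, function(p)
      abs(cor(rank(p), rank(cand))) < 0.85, logical(1)))
    if (ok) profiles[[length(profiles) + 1L]] <- cand
  }
  psi <- do.call(rbind, profiles)
  dimnames(psi) <- list(sprintf("ev%02d", 1:n_events), paste0("s", 1:6))
  cfg <- sim_config(sf_coupling_noise = 0, n_sf = n_sf, seed = 3)
  counts <- matrix(100, 2, 6,
                   dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  sf <- simulate_sf_coupling(counts, rownames(psi)[1:n_sf], psi, cfg)
  net <- build_sf_network(sf$counts[names(sf$sf_targets), , drop = FALSE], psi)
  got <- paste(net$edges$sf_gene_id, net$edges$event_id)
  want <- paste(names(sf$sf_targets), sf$sf_targets)
  expect_setequal(got, want)
  expect_true(all(abs(net$edges$rho) == 1))
  # slope signs: alternating couplings give rho = +1 / -1 exactly
  expect_equal(unname(sign(net$edges$rho[match(want, got)])),
               unname(sign(sf$sf_slopes)))
})

test_that("a multi-target SF is the top hub", {
  set.seed(29)
  hubs_ok <- replicate(20, {
    psi <- matrix(runif(6 * 30, 0.1, 0.9), 30, 6,
                  dimnames = list(sprintf("ev%02d", 1:30), paste0("s", 1:6)))
    sf_expr <- matrix(runif(5 * 6), 5, 6,
                      dimnames = list(sprintf("SF%02d", 1:5), paste0("s", 1:6)))
    # SF01 coupled to events 1..10, others left as noise
    for (e in 1:10) psi[e, ] <- rank(sf_expr["SF01", ]) / 7 +
      rnorm(6, 0, 0.01)
    net <- build_sf_network(sf_expr, psi, rho_min = 0.9)
    length(net$edges$sf_gene_id) > 0 &&
      names(net$hubs)[1] == "SF01"
  })
  expect_gte(mean(hubs_ok), 0.95)
})

test_that("null data retains no more edges than the permutation bound", {
  # at n = 6 only near-perfect rank agreement can survive BH at family
  # sizes in the hundreds; under exchangeability P(|rho| = 1) = 2/720 per
  # pair, so 4/720 is a generous ceiling on the retained fraction
  set.seed(37)
  frac <- replicate(10, {
    psi <- matrix(runif(6 * 100), 100, 6,
                  dimnames = list(sprintf("e%03d", 1:100), paste0("s", 1:6)))
    sf_expr <- matrix(runif(10 * 6), 10, 6,
                      dimnames = list(sprintf("SF%02d", 1:10), paste0("s", 1:6)))
    net <- build_sf_network(sf_expr, psi, rho_min = 0.9)
    nrow(net$edges) / net$n_tested
  })
  expect_lte(mean(frac), 4 / 720)
})

test_that("network export round-trips through GraphML and SIF", {
  edges <- data.frame(sf_gene_id = c("SF01", "SF01", "SF02"),
                      event_id = c("e1", "e2", "e3"),
                      rho = c(1, -0.95, 0.92), p = c(0, 1e-4, 2e-4),
                      padj = c(0, 3e-4, 4e-4), sf_de = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  gml <- tempfile(fileext = ".graphml"); sif <- tempfile(fileext = ".sif")
  g <- export_network(edges, gml, sif,
                      event_types = c(e1 = "SE", e2 = "SE", e3 = "RI"))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 3)
  expect_equal(igraph::vcount(back), 5)
  expect_setequal(igraph::E(back)$rho, edges$rho)
  expect_equal(sum(igraph::V(back)$role == "SF"), 2)
  expect_equal(length(readLines(sif)), 3)
  # empty edge list still yields a valid (empty) graph
  e0 <- edges[0, ]
  g0 <- export_network(e0, tempfile(fileext = ".graphml"))
  expect_equal(igraph::ecount(g0), 0)
  # degree sums equal twice the edge count on the bipartite node set
  expect_equal(sum(igraph::degree(g)), 2 * nrow(edges))
  expect_error(export_network(rbind(edges, edges[1, ])), "duplicate")
})
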