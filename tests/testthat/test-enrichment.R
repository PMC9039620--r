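test_that("hypergeometric tail matches the direct-summation oracle", {
  expect_equal(hypergeom_upper_tail(50, 10, 10, 0), 1.0)
  expect_equal(hypergeom_upper_tail(20, 5, 5, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:200) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k), tail_oracle(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_tail(10, 20, 5, 1), "invalid")
  expect_error(hypergeom_upper_tail(10, 5, 5, 6), "invalid")
})

test_that("log-space tail matches phyper for large counts", {
  set.seed(22)
  for (i in 1:50) {
    N <- sample(1e6:1e7, 1)
    K <- sample(1e3:1e5, 1)
    n <- sample(1e2:1e4, 1)
    k <- sample(0:min(n, 500), 1)
    lg <- hypergeom_upper_tail_log(N, K, n, k)
    ref <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
    expect_equal(lg, ref, tolerance = 1e-9)
  }
})

test_that("similarity_score follows the OC/Jaccard combination", {
  expect_equal(similarity_score(5, 5, 5), 1.0)   # identical sets
  expect_equal(similarity_score(5, 8, 0), 0.0)   # disjoint sets
  expect_equal(similarity_score(4, 8, 4), 0.75)  # OC=1, J=0.5, mean
  expect_equal(similarity_score(4, 8, 4, combine = "min"), 0.5)
  expect_equal(similarity_score(4, 8, 4, combine = "max"), 1.0)
  expect_error(similarity_score(0, 5, 0), "non-empty")
})

test_that("adjust_pvalues implements p0 * (m + n_le - 1) with clamping", {
  expect_equal(adjust_pvalues(0.03), 0.03)  # m = 1 reduces to identity
  p <- c(0.01, seq(0.1, 0.9, by = 0.1))
  adj <- adjust_pvalues(p)
  expect_equal(adj[1], 0.01 * (10 + 1 - 1))       # smallest: Bonferroni-like
  expect_equal(adj[10], min(1, 0.9 * (10 + 10 - 1)))  # largest: clamped
  p2 <- c(rep(0.2, 10))
  expect_equal(adjust_pvalues(p2), rep(1, 10))    # 0.2 * 19 clamped
  # order preserved, adjusted >= raw, ties inclusive
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1), 1e-6, 1)
    adj <- adjust_pvalues(p)
    m <- length(p)
    expect_true(all(adj >= p - 1e-15))
    manual <- pmin(1, vapply(p, function(p0) p0 * (m + sum(p <= p0) - 1),
                             numeric(1)))
    expect_equal(adj, manual)
  }
  expect_error(adjust_pvalues(numeric(0)))
  expect_error(adjust_pvalues(c(0.5, 0)))
})

test_that("enrich ranks a planted PAG first and applies filters before adjustment", {
  set.seed(24)
  universe <- sprintf("G%04d", 1:500)
  cand_core <- sample(universe, 25)
  planted <- pag("PLANTED", c(cand_core[1:20], sample(setdiff(universe, cand_core), 5)))
  nulls <- lapply(1:50, function(i)
    pag(sprintf("NULL%02d", i), sample(universe, 30)))
  res <- enrich(cand_core, c(nulls, list(planted)), min_overlap = 1,
                sim_cutoff = 0, neg_log2p_cutoff = 0)
  expect_equal(res$pag_id[1], "PLANTED")
  expect_equal(res$overlap_count[1], 20L)

  # adding a PAG that fails the overlap filter leaves adjusted values alone
  # (universe held fixed: by default it is the union of PAG genes and would
  # legitimately grow with the extra PAG)
  res2 <- enrich(cand_core,
                 c(nulls, list(planted), list(pag("TINY", "G0001"))),
                 min_overlap = 2, sim_cutoff = 0, neg_log2p_cutoff = 0,
                 universe = universe)
  res1 <- enrich(cand_core, c(nulls, list(planted)), min_overlap = 2,
                 sim_cutoff = 0, neg_log2p_cutoff = 0, universe = universe)
  expect_equal(res2[c("pag_id", "p_adjusted")], res1[c("pag_id", "p_adjusted")])
})

test_that("enrich handles exact-match candidates, empty survivors, order invariance", {
  universe_pags <- lapply(1:5, function(i)
    pag(sprintf("S%d", i), sprintf("G%02d", ((i - 1) * 8 + 1):((i - 1) * 8 + 10))))
  cand <- universe_pags[[2]]$genes
  res <- enrich(cand, universe_pags, neg_log2p_cutoff = 0)
  expect_equal(res$pag_id[1], "S2")
  expect_equal(res$similarity_score[1], 1.0)
  expect_equal(res$p_raw[1], min(res$p_raw))

  expect_warning(
    empty <- enrich(cand, universe_pags, min_overlap = 100),
    "no PAG")
  expect_equal(nrow(empty), 0L)

  shuffled <- enrich(cand, rev(universe_pags), neg_log2p_cutoff = 0)
  expect_equal(res, shuffled)
})

test_that("p_raw is non-increasing in overlap at fixed margins", {
  tails <- vapply(0:10, function(k) hypergeom_upper_tail(100, 20, 10, k),
                  numeric(1))
  expect_true(all(diff(tails) <= 1e-15))
  oracle <- vapply(0:10, function(k) tail_oracle(100, 20, 10, k), numeric(1))
  expect_equal(tails, pmax(oracle, .Machine$double.xmin), tolerance = 1e-12)
})
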