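test_that("m-type edges follow the BH hypergeometric rule with Jaccard weights", {
  set.seed(41)
  universe <- sprintf("G%04d", 1:1000)
  shared <- sample(universe, 20)
  pags <- list(pag("A", shared), pag("B", shared),
               pag("C", sample(setdiff(universe, shared), 20)))
  net <- build_mtype_network(pags, 1000)
  ab <- net$edges[net$edges$from == "A" & net$edges$to == "B", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$weight, 1.0)        # identical sets
  expect_false(any(net$edges$from == "C" | net$edges$to == "C"))  # disjoint

  # subset rule under the jaccard rule: |A|=5 inside |B|=10 -> weight 0.5
  sub <- list(pag("S", sprintf("G%04d", 1:5)), pag("T", sprintf("G%04d", 1:10)))
  net2 <- build_mtype_network(sub, 1000, rule = "jaccard", min_jaccard = 0.1)
  expect_equal(net2$edges$weight, 0.5)

  expect_error(build_mtype_network(sub, 4), "universe_size")
  expect_error(build_mtype_network(sub[1], 1000), "at least two")
})

test_that("network invariants: degree identity and input-order invariance", {
  set.seed(42)
  universe <- sprintf("G%04d", 1:500)
  pags <- lapply(1:12, function(i) pag(sprintf("P%02d", i),
                                       sample(universe, 40)))
  net <- build_mtype_network(pags, 500)
  g <- as_igraph(net)
  expect_equal(sum(igraph::degree(g)), 2L * nrow(net$edges))
  net_rev <- build_mtype_network(rev(pags), 500)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(key(net_rev$edges), key(net$edges))
})

test_that("louvain recovers the two-clique optimum and is seeded-deterministic", {
  tc <- two_clique_graph()
  cl <- louvain_cluster(tc$graph, seed = 7)
  exact <- best_partition_exhaustive(tc$adjacency)
  expect_equal(adjusted_rand_index(cl$membership, exact$membership), 1)
  expect_equal(cl$modularity, exact$modularity, tolerance = 1e-12)
  expect_identical(louvain_cluster(tc$graph, seed = 7)$membership,
                   cl$membership)

  # single clique: one community, modularity 0
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("k", 1:5)
  igraph::E(k5)$weight <- 1
  cl5 <- louvain_cluster(k5, seed = 1)
  expect_equal(length(unique(cl5$membership)), 1L)
  expect_equal(cl5$modularity, 0)

  expect_error(louvain_cluster(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("louvain modularity beats the all-in-one partition on a block graph", {
  pb <- planted_block_graph(seed = 43)
  cl <- louvain_cluster(pb$graph, seed = 43)
  one <- igraph::modularity(pb$graph, rep(1, igraph::vcount(pb$graph)),
                            weights = igraph::E(pb$graph)$weight)
  expect_gte(cl$modularity, one)
  expect_gte(adjusted_rand_index(cl$membership, pb$block), 0.9)
})

test_that("cluster word frequencies drop stop words, keep hyphens, conserve tokens", {
  wf <- cluster_word_frequencies(list(c1 = c("il-18 signaling pathway",
                                             "il-17 signaling pathway")))
  expect_mapequal(as.list(wf$c1), list(`il-18` = 1L, `il-17` = 1L))
  # names made only of stop words vanish
  wf2 <- cluster_word_frequencies(list(c1 = c("signaling pathway", "human")))
  expect_length(wf2$c1, 0L)
  # punctuation stripped from token edges only
  wf3 <- cluster_word_frequencies(list(c1 = "apoptosis, (intrinsic) route."))
  expect_mapequal(as.list(wf3$c1),
                  list(apoptosis = 1L, intrinsic = 1L, route = 1L))
  # accounting identity: kept counts = total tokens - removed tokens
  nm <- c("tnf signaling pathway alpha", "wnt pathway and apoptosis")
  wf4 <- cluster_word_frequencies(list(c1 = nm))
  toks <- tolower(unlist(strsplit(nm, "\\s+")))
  removed <- sum(toks %in% default_stop_words())
  expect_equal(sum(unlist(wf4$c1)), length(toks) - removed)
})

test_that("write_network exports GraphML and edge-list TSV", {
  pags <- list(pag("A", sprintf("G%02d", 1:10)),
               pag("B", sprintf("G%02d", 5:14)),
               pag("C", sprintf("G%02d", 50:59)))
  net <- build_mtype_network(pags, 100)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, tsv)
  expect_true(grepl("graphml", paste(readLines(gml, n = 3), collapse = "")))
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
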