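# Independent oracles: deliberately different algorithms from the package
# implementations they check.

# OSA distance by plain memoized recursion, transcribing the defining
# recurrence directly (deletion, insertion, match/substitution, adjacent
# transposition with no further edits inside the pair).
osa_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) {
      0
    } else {
      cands <- c()
      if (i > 0) cands <- c(cands, rec(i - 1, j) + 1)
      if (j > 0) cands <- c(cands, rec(i, j - 1) + 1)
      if (i > 0 && j > 0)
        cands <- c(cands, rec(i - 1, j - 1) + (av[i] != bv[j]))
      if (i > 1 && j > 1 && av[i] == bv[j - 1] && av[i - 1] == bv[j])
        cands <- c(cands, rec(i - 2, j - 2) + 1)
      min(cands)
    }
    memo[[key]] <- val
    val
  }
  rec(length(av), length(bv))
}

# Hypergeometric upper tail by direct summation of probability mass terms
# computed from binomial coefficients (no shared code with the package's
# log-space path).
tail_oracle <- function(N, K, n, k) {
  t <- max(0, n + K - N):min(n, K)
  t <- t[t >= k]
  if (length(t) == 0) return(0)
  min(sum(choose(K, t) * choose(N - K, n - t)) / choose(N, n), 1)
}

# AUC by brute-force concordant-pair counting: (concordant + 0.5 ties) /
# (n_true * n_false), with larger rank-score = more positive.
auc_oracle <- function(rank_score, truth) {
  pos <- rank_score[truth]
  neg <- rank_score[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive modularity maximization over every partition of the nodes of a
# small undirected graph given as an adjacency matrix.
best_partition_exhaustive <- function(A) {
  n <- nrow(A)
  m <- sum(A) / 2
  d <- rowSums(A)
  B <- A / (2 * m) - outer(d, d) / (4 * m^2)
  best <- -Inf
  best_memb <- NULL
  rgs <- integer(n)
  gen <- function(i, maxv) {
    if (i > n) {
      q <- sum(B[outer(rgs, rgs, "==")])
      if (q > best) {
        best <<- q
        best_memb <<- rgs
      }
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      gen(i + 1L, max(maxv, v))
    }
  }
  gen(1L, 0L)
  list(membership = best_memb, modularity = best)
}

# Two 5-cliques joined by a single bridge edge, as igraph + adjacency.
two_clique_graph <- function() {
  n <- 10
  A <- matrix(0, n, n)
  for (cl in list(1:5, 6:10)) for (i in cl) for (j in cl) if (i != j) A[i, j] <- 1
  A[5, 6] <- A[6, 5] <- 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("n", 1:10)
  igraph::E(g)$weight <- 1
  list(graph = g, adjacency = A)
}

# Planted 3-block random graph: 15 nodes per block, within-block edge
# probability 0.9, between-block 0.05.
planted_block_graph <- function(seed, n_per_block = 15, p_in = 0.9, p_out = 0.05) {
  set.seed(seed)
  n <- 3 * n_per_block
  block <- rep(1:3, each = n_per_block)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) p_in else p_out
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(n))
  igraph::E(g)$weight <- 1
  list(graph = g, block = block)
}

# Random term strings for matcher property tests.
random_strings <- function(n, max_len = 12, alphabet = letters[1:8]) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(1:max_len, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# Tiny PAG constructor for hand-built collections.
pag <- function(id, genes, name = id, source = "test") {
  list(pag_id = id, name = name, source = source, pag_type = "P",
       genes = toupper(genes))
}
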