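#' Build the m-type (co-membership) PAG-to-PAG network
#'
#' For every unordered pair of PAGs the shared-gene count s is tested with a
#' hypergeometric upper tail P(X >= s) given the universe size and the two
#' set sizes; Benjamini-Hochberg correction is applied across all pairs and
#' an edge is kept when the corrected p-value is at most `edge_p_cutoff`.
#' Edge weight is the Jaccard index of the two gene sets. Alternative edge
#' rules are available: "shared" keeps pairs with s >= `min_shared`,
#' "jaccard" keeps pairs with Jaccard >= `min_jaccard`.
#'
#' @param pags list of PAG records (>= 2)
#' @param universe_size background gene-universe size (>= the largest PAG)
#' @param edge_p_cutoff BH-corrected p-value cutoff (default 0.05)
#' @param rule edge rule: "hypergeom" (default), "shared" or "jaccard"
#' @param min_shared,min_jaccard thresholds for the alternative rules
#' @return list of class `pag_network`: `nodes` (character vector of pag
#'   ids) and `edges` (data frame from, to, shared, weight, p_adj)
#' @export
build_mtype_network <- function(pags, universe_size, edge_p_cutoff = 0.05,
                                rule = c("hypergeom", "shared", "jaccard"),
                                min_shared = 1, min_jaccard = 0.1) {
  rule <- match.arg(rule)
  if (length(pags) < 2L) stop_input("need at least two PAGs")
  sizes <- vapply(pags, function(p) length(p$genes), integer(1))
  if (universe_size < max(sizes))
    stop_input("universe_size (%d) smaller than the largest PAG (%d)",
               universe_size, max(sizes))
  ids <- vapply(pags, `[[`, character(1), "pag_id")
  np <- length(pags)
  pairs <- utils::combn(np, 2L)
  shared <- integer(ncol(pairs))
  jac <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    s <- length(intersect(pags[[i]]$genes, pags[[j]]$genes))
    shared[c] <- s
    jac[c] <- s / (sizes[i] + sizes[j] - s)
  }
  edges <- data.frame(from = ids[pairs[1L, ]], to = ids[pairs[2L, ]],
                      shared = shared, weight = jac, p_adj = NA_real_,
                      stringsAsFactors = FALSE)
  keep <- switch(rule,
    hypergeom = {
      p <- vapply(seq_len(ncol(pairs)), function(c) {
        i <- pairs[1L, c]; j <- pairs[2L, c]
        hypergeom_upper_tail(universe_size, sizes[i], sizes[j], shared[c])
      }, numeric(1))
      edges$p_adj <- stats::p.adjust(p, method = "BH")
      edges$p_adj <= edge_p_cutoff & shared > 0
    },
    shared = shared >= min_shared,
    jaccard = jac >= min_jaccard & shared > 0
  )
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges), class = "pag_network")
}

#' Convert a pag_network to an igraph graph
#'
#' @param net a `pag_network`
#' @return undirected weighted igraph graph including isolated nodes
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(match(net$edges$from, net$nodes),
                                    match(net$edges$to, net$nodes)))
    g <- igraph::set_edge_attr(g, "weight", value = net$edges$weight)
  }
  g
}

#' Export a pag_network as GraphML and edge-list TSV
#'
#' @param net a `pag_network`
#' @param graphml_path,edges_path output paths (either may be NULL to skip)
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  if (!is.null(edges_path))
    write_tsv(net$edges, edges_path)
  invisible(net)
}

#' Louvain community detection on a PAG network
#'
#' Greedy multilevel modularity optimization (Louvain) on the weighted
#' undirected graph. The vertex visit order is shuffled by `seed`, making
#' the partition deterministic for a given seed. The reported modularity is
#' the standard weighted Newman-Girvan modularity of the returned
#' membership; it always is at least the modularity of the all-in-one
#' partition (which is 0 for a connected simple graph).
#'
#' @param net a `pag_network` or an igraph graph
#' @param seed integer RNG seed controlling the vertex visit order
#' @param resolution Louvain resolution parameter (default 1.0)
#' @return list of class `cluster_assignment`: `membership` (named integer
#'   vector, pag_id -> cluster) and `modularity`
#' @export
louvain_cluster <- function(net, seed = 42L, resolution = 1.0) {
  g <- if (inherits(net, "pag_network")) as_igraph(net) else net
  if (igraph::vcount(g) < 1L) stop_input("empty graph")
  if (igraph::ecount(g) == 0L) {
    # no co-membership signal: every node is its own community; modularity
    # of an edgeless graph is defined here as 0
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(structure(list(membership = memb, modularity = 0),
                     class = "cluster_assignment"))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perm <- sample.int(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  cl <- igraph::cluster_louvain(gp, resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- memb[match(igraph::V(g)$name, names(memb))]
  mod <- igraph::modularity(g, memb,
                            weights = igraph::E(g)$weight)
  structure(list(membership = memb, modularity = mod),
            class = "cluster_assignment")
}

#' Stop words removed from PAG-name bags of words
#' @return character vector
#' @export
default_stop_words <- function() {
  c("pathway", "signaling", "human", "homo", "sapiens", "has", "or", "and")
}

#' Per-cluster keyword frequencies from PAG names
#'
#' Splits PAG names on whitespace, lower-cases tokens, strips leading and
#' trailing punctuation (commas, colons, parentheses, periods — hyphens are
#' kept, so "il-18" survives), removes stop words and counts occurrences
#' per cluster.
#'
#' @param names_by_cluster named list: cluster label -> character vector of
#'   PAG names
#' @param stop_words words dropped after lower-casing
#' @return named list: cluster label -> named integer vector of counts
#' @export
cluster_word_frequencies <- function(names_by_cluster,
                                     stop_words = default_stop_words()) {
  lapply(names_by_cluster, function(nm) {
    tokens <- tolower(unlist(strsplit(nm, "\\s+")))
    tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens,
                   perl = FALSE)
    # keep interior hyphens: only leading/trailing punctuation was stripped
    tokens <- tokens[nzchar(tokens) & !(tokens %in% stop_words)]
    if (length(tokens) == 0L) return(stats::setNames(integer(0), character(0)))
    tab <- table(tokens)
    stats::setNames(as.integer(tab), names(tab))
  })
}
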