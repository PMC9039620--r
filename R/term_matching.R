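#' Optimal string alignment (OSA) distance
#'
#' Restricted Damerau-Levenshtein edit distance: minimum number of
#' single-character deletions, insertions, substitutions and adjacent
#' transpositions turning `a` into `b`, where a transposed pair may not be
#' edited again. The restriction matters: osa_distance("ca", "abc") is 3,
#' whereas the unrestricted Damerau-Levenshtein distance is 2.
#'
#' @param a,b character vectors; recycled to a common length
#' @return integer vector of distances
#' @export
osa_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  .osa_distance_cpp(a, b)
}

#' OSA string similarity
#'
#' 1 - d / max(|a|, |b|) with d the OSA distance; in [0, 1], and 1 exactly
#' when the strings are equal. Two empty strings are defined as identical
#' (similarity 1).
#'
#' @param a,b character vectors; recycled to a common length
#' @return numeric vector of similarities in [0, 1]
#' @export
string_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- .osa_distance_cpp(a, b)
  len <- pmax(nchar(a), nchar(b))
  out <- ifelse(len == 0, 1, 1 - d / len)
  pmin(pmax(out, 0), 1)
}

#' Default patterns stripped from enrichment terms
#'
#' Species qualifiers and source identifiers commonly appended by enrichment
#' tools; matched case-insensitively and removed before comparison.
#' @return character vector of regular expressions
#' @export
default_strip_patterns <- function() {
  c("homo sapiens", "\\(human\\)", "\\bhuman\\b", "\\bhsa\\d+\\b",
    "\\bwp\\d+\\b", "\\br-hsa-\\d+\\b", "\\bgo:\\d+\\b",
    "\\[[^]]*\\]$", "\\([^)]*\\)$")
}

#' Normalize enrichment term strings
#'
#' Lower-cases, removes the configured strip patterns, drops stray
#' punctuation left behind by stripping (separator dashes and underscores
#' surrounded by space), collapses whitespace runs and trims. Duplicates
#' (terms with the same normalized form) are collapsed to the first
#' occurrence, mirroring the removal of redundant terms contributed by
#' multiple data sources.
#'
#' @param terms character vector of raw terms
#' @param strip_patterns regexes removed (case-insensitively) from the
#'   lower-cased terms; see [default_strip_patterns()]
#' @return data frame with columns `raw` and `normalized`, one row per
#'   distinct normalized form (first raw spelling retained)
#' @export
normalize_terms <- function(terms, strip_patterns = default_strip_patterns()) {
  norm <- tolower(terms)
  for (pat in strip_patterns) {
    norm <- gsub(pat, " ", norm, perl = TRUE)
  }
  norm <- gsub("\\s[-_/]+\\s", " ", norm)    # orphaned separators
  norm <- gsub("[-_:,]+\\s*$", " ", norm)    # trailing separators
  norm <- gsub("\\s+", " ", norm)
  norm <- trimws(norm)
  keep <- !duplicated(norm)
  data.frame(raw = terms[keep], normalized = norm[keep],
             stringsAsFactors = FALSE)
}

#' Best-match pairs between two normalized term lists
#'
#' For each term in `set_a`, the single highest-similarity partner in
#' `set_b` (row-wise maximum of the full OSA similarity matrix); ties go to
#' the lexicographically smallest partner. Pairs below `cutoff` are dropped.
#'
#' @param set_a,set_b character vectors of normalized terms
#' @param cutoff minimum similarity in [0, 1] (default 0.8)
#' @return data frame: term_a, term_b, similarity
#' @export
best_matches <- function(set_a, set_b, cutoff = 0.8) {
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop_input("best_matches requires two non-empty term lists")
  if (cutoff < 0 || cutoff > 1) stop_input("cutoff must be in [0,1]")
  d <- .osa_matrix_cpp(set_a, set_b)
  len <- outer(nchar(set_a), nchar(set_b), pmax)
  sim <- ifelse(len == 0, 1, 1 - d / len)
  # lexicographic tie-break: scan partners in sorted order, keep first max
  ord <- order(set_b)
  best_j <- apply(sim[, ord, drop = FALSE], 1L, which.max)
  best_j <- ord[best_j]
  out <- data.frame(term_a = set_a,
                    term_b = set_b[best_j],
                    similarity = sim[cbind(seq_along(set_a), best_j)],
                    stringsAsFactors = FALSE)
  out <- out[out$similarity >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus (Venn) partition of term lists from several tools
#'
#' Builds an undirected match graph on (tool, term) nodes whose edges are
#' the union of [best_matches()] over all ordered tool pairs at the cutoff
#' (the union makes the relation symmetric even though row-wise best match
#' is not). Connected components are consensus concepts; a component's
#' region is the set of tools it spans, and `region_counts` tallies
#' components per region — a component spanning all three tools counts once
#' in the triple region, not in any pairwise region.
#'
#' @param lists named list: tool id -> character vector of normalized terms
#' @param cutoff similarity cutoff in [0, 1] (default 0.8)
#' @return list with `components` (data frame tool, term, component, region)
#'   and `region_counts` (data frame region, count); regions are
#'   "+"-joined sorted tool ids
#' @export
consensus_partition <- function(lists, cutoff = 0.8) {
  if (length(lists) < 2L) stop_input("consensus needs at least two tools")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop_input("term lists must be named by tool id")
  tools <- sort(names(lists))
  nodes <- do.call(rbind, lapply(tools, function(t) {
    data.frame(tool = t, term = unique(lists[[t]]), stringsAsFactors = FALSE)
  }))
  node_key <- paste(nodes$tool, nodes$term, sep = "\r")
  edges <- list()
  for (ta in tools) for (tb in tools) {
    if (ta == tb) next
    mm <- best_matches(unique(lists[[ta]]), unique(lists[[tb]]), cutoff)
    if (nrow(mm) > 0L)
      edges[[length(edges) + 1L]] <- data.frame(
        from = paste(ta, mm$term_a, sep = "\r"),
        to = paste(tb, mm$term_b, sep = "\r"),
        stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_key), name = node_key)
  if (length(edges) > 0L) {
    ed <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(match(ed$from, node_key),
                                    match(ed$to, node_key)))
    g <- igraph::simplify(g)
  }
  comp <- igraph::components(g)$membership
  nodes$component <- as.integer(comp)  # vertices were added in node order
  region_of <- tapply(nodes$tool, nodes$component,
                      function(t) paste(sort(unique(t)), collapse = "+"))
  nodes$region <- as.character(region_of[as.character(nodes$component)])
  counts <- table(region_of)
  region_counts <- data.frame(region = names(counts),
                              count = as.integer(counts),
                              stringsAsFactors = FALSE)
  region_counts <- region_counts[order(region_counts$region), , drop = FALSE]
  rownames(region_counts) <- NULL
  list(components = nodes, region_counts = region_counts)
}
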