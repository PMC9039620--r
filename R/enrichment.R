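#' Hypergeometric upper-tail probability
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe_size, pag_size,
#' candidate_size): the chance of drawing at least `overlap` members of a
#' PAG when `candidate_size` genes are sampled without replacement from a
#' universe containing `pag_size` PAG members. Computed by log-space
#' summation of the probability mass terms (log-gamma binomial
#' coefficients), so large counts do not overflow.
#'
#' @param universe_size number of genes in the background universe
#' @param pag_size number of PAG genes present in the universe
#' @param candidate_size number of candidate genes present in the universe
#' @param overlap observed candidate/PAG intersection size
#' @return tail probability in (0, 1]
#' @export
hypergeom_upper_tail <- function(universe_size, pag_size, candidate_size,
                                 overlap) {
  N <- universe_size; K <- pag_size; n <- candidate_size; k <- overlap
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop_input("invalid hypergeometric configuration (N=%s, K=%s, n=%s, k=%s)",
               N, K, n, k)
  p <- exp(.hyper_tail_log(N, K, n, k))
  min(max(p, .Machine$double.xmin), 1)
}

#' Log of the hypergeometric upper tail
#'
#' Same tail as [hypergeom_upper_tail()] but returned on the natural-log
#' scale, for scores of very small probabilities.
#' @inheritParams hypergeom_upper_tail
#' @return log P(X >= overlap), a value <= 0
#' @export
hypergeom_upper_tail_log <- function(universe_size, pag_size, candidate_size,
                                     overlap) {
  N <- universe_size; K <- pag_size; n <- candidate_size; k <- overlap
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop_input("invalid hypergeometric configuration (N=%s, K=%s, n=%s, k=%s)",
               N, K, n, k)
  .hyper_tail_log(N, K, n, k)
}

#' Shared log-tail kernel: sums the smaller side of the support so tails
#' near 1 keep full relative precision in log space.
#' @noRd
.hyper_tail_log <- function(N, K, n, k) {
  supp_min <- max(0, n - (N - K))
  supp_max <- min(K, n)
  if (k <= supp_min) return(0)
  log_pmf <- function(t) lchoose(K, t) + lchoose(N - K, n - t) - lchoose(N, n)
  upper <- log_sum_exp(log_pmf(k:supp_max))
  if (upper <= log(0.5)) return(min(upper, 0))
  # tail is the bulk of the mass: sum the small complement instead
  lower <- log_sum_exp(log_pmf(supp_min:(k - 1)))
  min(log1p(-min(exp(lower), 1)), 0)
}

#' Set-similarity score between candidates and a PAG
#'
#' Combines the overlap coefficient OC = k / min(|A|, |B|) and the Jaccard
#' index J = k / (|A| + |B| - k). The combination convention is pluggable;
#' the default is the arithmetic mean (OC + J) / 2.
#'
#' @param candidate_size,pag_size set sizes (both > 0)
#' @param overlap intersection size
#' @param combine one of "mean", "min", "max"
#' @return score in [0, 1]
#' @export
similarity_score <- function(candidate_size, pag_size, overlap,
                             combine = c("mean", "min", "max")) {
  combine <- match.arg(combine)
  if (candidate_size <= 0 || pag_size <= 0)
    stop_input("similarity_score requires non-empty sets")
  if (overlap < 0 || overlap > min(candidate_size, pag_size))
    stop_input("overlap exceeds the smaller set")
  oc <- overlap / min(candidate_size, pag_size)
  j <- overlap / (candidate_size + pag_size - overlap)
  switch(combine, mean = (oc + j) / 2, min = min(oc, j), max = max(oc, j))
}

#' Rank-aware p-value adjustment
#'
#' For each raw p-value p0 among m tests, the adjusted value is
#' p0 * (m + n_le - 1), where n_le is the number of raw p-values <= p0
#' (inclusive of ties, so n_le >= 1 and the multiplier is always >= m).
#' Values are clamped to 1. With a single test the adjustment is the
#' identity. The multiplier interpolates between Bonferroni (for the
#' smallest p-value, n_le = 1 gives p0 * m) and 2m - 1 times the largest.
#'
#' @param p_raw numeric vector of raw p-values in (0, 1]
#' @return adjusted p-values, same order as the input
#' @export
adjust_pvalues <- function(p_raw) {
  if (length(p_raw) == 0L) stop_input("adjust_pvalues needs at least one p-value")
  if (any(p_raw <= 0 | p_raw > 1)) stop_input("raw p-values must lie in (0,1]")
  m <- length(p_raw)
  n_le <- vapply(p_raw, function(p0) sum(p_raw <= p0), integer(1))
  pmin(1, p_raw * (m + n_le - 1))
}

#' Over-representation analysis of candidates against a PAG collection
#'
#' Pipeline: (1) intersect candidates and each PAG with the universe (by
#' default the union of all PAG genes) and compute overlaps; (2) drop PAGs
#' whose overlap count or similarity score fails the filters; (3) compute
#' the hypergeometric upper-tail p-value for the m survivors; (4) adjust the
#' m raw p-values with [adjust_pvalues()] (m is the post-filter count, so
#' adding a PAG that fails the filters never changes any adjusted value);
#' (5) keep results with -log2(adjusted p) >= `neg_log2p_cutoff`. Results
#' are sorted by adjusted p ascending, ties broken by `pag_id`.
#'
#' @param candidates character vector of candidate gene symbols (case
#'   folded to upper on entry)
#' @param pags list of PAG records as from [read_gmt()]
#' @param min_overlap minimum overlap count to keep a PAG (default 1)
#' @param sim_cutoff minimum similarity score (default 0)
#' @param neg_log2p_cutoff minimum -log2(adjusted p) to report
#'   (default 4.32, approximately adjusted p <= 0.05)
#' @param universe optional explicit background gene universe; default is
#'   the union of all PAG gene sets
#' @param combine similarity combination convention, see [similarity_score()]
#' @return data frame: pag_id, name, source, universe_size, candidate_size,
#'   pag_size, overlap_count, overlap_genes (comma-joined), similarity_score,
#'   p_raw, p_adjusted, neg_log2_p
#' @export
enrich <- function(candidates, pags, min_overlap = 1, sim_cutoff = 0,
                   neg_log2p_cutoff = 4.32, universe = NULL,
                   combine = "mean") {
  if (length(pags) == 0L) stop_input("empty PAG collection")
  candidates <- unique(toupper(candidates))
  if (is.null(universe)) {
    universe <- unique(toupper(unlist(lapply(pags, `[[`, "genes"))))
  } else {
    universe <- unique(toupper(universe))
  }
  N <- length(universe)
  cand <- intersect(candidates, universe)
  n_cand <- length(cand)
  if (n_cand == 0L) stop_input("no candidate gene is present in the universe")

  rows <- lapply(pags, function(p) {
    genes <- intersect(p$genes, universe)
    ov <- intersect(cand, genes)
    list(pag_id = p$pag_id, name = p$name, source = p$source,
         pag_size = length(genes), overlap_count = length(ov),
         overlap_genes = paste(sort(ov), collapse = ","))
  })
  keep <- vapply(rows, function(r) {
    r$overlap_count >= min_overlap && r$pag_size > 0 &&
      similarity_score(n_cand, r$pag_size, r$overlap_count, combine) >= sim_cutoff
  }, logical(1))
  rows <- rows[keep]
  if (length(rows) == 0L) {
    warning("no PAG survives the overlap/similarity filters", call. = FALSE)
    return(empty_enrichment())
  }
  p_raw <- vapply(rows, function(r) {
    hypergeom_upper_tail(N, r$pag_size, n_cand, r$overlap_count)
  }, numeric(1))
  p_adj <- adjust_pvalues(p_raw)
  res <- data.frame(
    pag_id = vapply(rows, `[[`, character(1), "pag_id"),
    name = vapply(rows, `[[`, character(1), "name"),
    source = vapply(rows, `[[`, character(1), "source"),
    universe_size = N,
    candidate_size = n_cand,
    pag_size = vapply(rows, `[[`, integer(1), "pag_size"),
    overlap_count = vapply(rows, `[[`, integer(1), "overlap_count"),
    overlap_genes = vapply(rows, `[[`, character(1), "overlap_genes"),
    similarity_score = vapply(rows, function(r)
      similarity_score(n_cand, r$pag_size, r$overlap_count, combine), numeric(1)),
    p_raw = p_raw,
    p_adjusted = p_adj,
    neg_log2_p = -log2(p_adj),
    stringsAsFactors = FALSE
  )
  res <- res[res$neg_log2_p >= neg_log2p_cutoff, , drop = FALSE]
  if (nrow(res) == 0L) {
    warning("no PAG passes the -log2(p) cutoff", call. = FALSE)
    return(res)
  }
  res <- res[order(res$p_adjusted, res$pag_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @noRd
empty_enrichment <- function() {
  data.frame(pag_id = character(0), name = character(0), source = character(0),
             universe_size = integer(0), candidate_size = integer(0),
             pag_size = integer(0), overlap_count = integer(0),
             overlap_genes = character(0), similarity_score = numeric(0),
             p_raw = numeric(0), p_adjusted = numeric(0),
             neg_log2_p = numeric(0), stringsAsFactors = FALSE)
}
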