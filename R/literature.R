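#' Validate a co-citation count configuration
#' @noRd
check_citation_counts <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0)) stop_input("citation counts must be non-negative")
  if (K > N || n > N) stop_input("K and n may not exceed the background N")
  if (k > min(n, K)) stop_input("joint count k may not exceed min(n, K)")
  invisible(TRUE)
}

#' PubMed co-citation enrichment score
#'
#' -ln of the hypergeometric upper-tail probability of observing at least k
#' articles jointly mentioning the disease and the pathway keyword:
#' score = -ln sum_{t=k}^{min(n,K)} C(K,t) C(N-K,n-t) / C(N,n), where N is
#' the background citation count (the word "disease"), K the citations of
#' the specific disease, n the keyword citations and k the joint citations.
#' Computed in log space with log-gamma binomial coefficients, so PubMed-
#' scale counts (N ~ 1e7) do not overflow. k = 0 gives probability 1 and
#' score 0.
#'
#' @param N,K,n,k citation counts, see above; either pass the four scalars
#'   or a list with those fields in `N`
#' @return score >= 0
#' @export
pubmed_score <- function(N, K = NULL, n = NULL, k = NULL) {
  if (is.list(N)) { counts <- N; N <- counts$N; K <- counts$K; n <- counts$n; k <- counts$k }
  check_citation_counts(N, K, n, k)
  -hypergeom_upper_tail_log(N, K, n, k)
}

#' Co-citation odds ratio
#'
#' k/(K - k) divided by (n - k)/(N - K - n + k): the odds of a disease
#' citation mentioning the keyword against the odds of a non-disease
#' citation doing so. Degenerate conventions keep the ranking total:
#' k = 0 gives 0; K = k (every disease citation mentions the keyword) or
#' n = k with k > 0 gives +Inf, which sorts above all finite values.
#'
#' @inheritParams pubmed_score
#' @return odds ratio >= 0, possibly Inf
#' @export
odds_ratio <- function(N, K = NULL, n = NULL, k = NULL) {
  if (is.list(N)) { counts <- N; N <- counts$N; K <- counts$K; n <- counts$n; k <- counts$k }
  check_citation_counts(N, K, n, k)
  if (N - K - n + k <= 0)
    stop_input("degenerate 2x2 table: N - K - n + k = %d", N - K - n + k)
  if (k == 0) return(0)
  if (K == k || n == k) return(Inf)
  (k / (K - k)) / ((n - k) / (N - K - n + k))
}

#' Score a citation-count table
#'
#' Applies [pubmed_score()] and [odds_ratio()] to every keyword of a table
#' read with [read_citation_table()], under shared background counts N, K.
#'
#' @param counts data frame with columns keyword, n, k
#' @param N,K background and disease citation totals
#' @return data frame: keyword, n, k, odds_ratio, pubmed_score
#' @export
score_citations <- function(counts, N, K) {
  or <- vapply(seq_len(nrow(counts)), function(i)
    odds_ratio(N, K, counts$n[i], counts$k[i]), numeric(1))
  sc <- vapply(seq_len(nrow(counts)), function(i)
    pubmed_score(N, K, counts$n[i], counts$k[i]), numeric(1))
  data.frame(keyword = counts$keyword, n = counts$n, k = counts$k,
             odds_ratio = or, pubmed_score = sc, stringsAsFactors = FALSE)
}

#' Precision at co-citation cutoffs
#'
#' Fractions of pathways whose literature support passes each cutoff:
#' joint citations k > `k_min`, odds ratio > `or_min`, PubMed score >
#' `score_min`. Defaults mirror the benchmark cutoffs k > 0, OR > 0.1,
#' score > 1e-5.
#'
#' @param scores data frame from [score_citations()] (columns k,
#'   odds_ratio, pubmed_score)
#' @param k_min,or_min,score_min strict lower cutoffs
#' @return named numeric vector: precision_k, precision_or, precision_score
#' @export
precision_at_cutoffs <- function(scores, k_min = 0, or_min = 0.1,
                                 score_min = 1e-5) {
  if (nrow(scores) == 0L) stop_input("empty score table")
  c(precision_k = mean(scores$k > k_min),
    precision_or = mean(scores$odds_ratio > or_min),
    precision_score = mean(scores$pubmed_score > score_min))
}
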