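#' Label pathways against a topology-method ground truth
#'
#' The reference method's adjusted combined p-values define the labels:
#' "true" when adjusted p <= 0.05 (no overlap requirement); "false" when
#' adjusted p > 0.05 but at least one reference-pathway gene overlaps the
#' input gene list; "excluded" otherwise (not significant and no overlap) —
#' excluded pathways are dropped from downstream ROC analysis.
#'
#' @param reference data frame with columns `pathway_id`, `adjusted_p`,
#'   `overlap` (number of input genes overlapping the pathway)
#' @param p_cutoff significance cutoff for the "true" label (default 0.05)
#' @return data frame: pathway_id, adjusted_p, overlap, label
#' @export
label_ground_truth <- function(reference, p_cutoff = 0.05) {
  req <- c("pathway_id", "adjusted_p", "overlap")
  if (!all(req %in% names(reference)))
    stop_input("reference needs columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(reference$pathway_id))
    stop_input("duplicate pathway_id in reference: %s",
               paste(unique(reference$pathway_id[duplicated(reference$pathway_id)]),
                     collapse = ", "))
  if (any(reference$adjusted_p <= 0 | reference$adjusted_p > 1))
    stop_input("adjusted_p must lie in (0,1]")
  if (any(reference$overlap < 0)) stop_input("overlap must be >= 0")
  label <- ifelse(reference$adjusted_p <= p_cutoff, "true",
                  ifelse(reference$overlap >= 1, "false", "excluded"))
  data.frame(pathway_id = reference$pathway_id,
             adjusted_p = reference$adjusted_p,
             overlap = reference$overlap,
             label = label, stringsAsFactors = FALSE)
}

#' ROC curve and AUC of a tool's ranking against ground-truth labels
#'
#' Pathways are ranked by the tool's adjusted p-value (smaller = more
#' positive). Labeled pathways the tool did not retrieve are assigned
#' adjusted p = 1 so every tool is evaluated on the full label set.
#' "excluded" labels are dropped. The ROC steps through score thresholds
#' with tied scores handled as a single threshold, and the AUC (trapezoidal
#' rule) equals the Mann-Whitney U statistic normalized by
#' n_true * n_false, ties counting one half.
#'
#' @param scores named numeric vector: pathway_id -> the tool's adjusted p
#' @param labels data frame from [label_ground_truth()]
#' @return list of class `roc_result`: `points` (data frame fpr, tpr from
#'   (0,0) to (1,1)) and `auc`
#' @export
roc_auc <- function(scores, labels) {
  labels <- labels[labels$label %in% c("true", "false"), , drop = FALSE]
  if (length(unique(labels$label)) < 2L)
    stop_input("need at least one true and one false label")
  p <- scores[labels$pathway_id]
  p[is.na(p)] <- 1  # unretrieved pathways score worst
  rank_score <- -as.numeric(p)  # larger = more positive
  truth <- labels$label == "true"
  n_t <- sum(truth); n_f <- sum(!truth)
  # threshold sweep over distinct scores, descending
  ord <- order(rank_score, decreasing = TRUE)
  s <- rank_score[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))      # tie groups share a threshold
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / n_f), tpr = c(0, tp[last] / n_t))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' Welch two-sample t-test p-value with degenerate-variance conventions
#' @noRd
welch_p <- function(x, y, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- if (n1 > 1) stats::var(x) else 0
  v2 <- if (n2 > 1) stats::var(y) else 0
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    # both groups constant: equal means -> no evidence; unequal -> certain
    if (m1 == m2) return(1)
    if (alternative == "greater") return(if (m1 > m2) 0 else 1)
    return(0)
  }
  tstat <- (m1 - m2) / sqrt(se2)
  df_num <- se2^2
  df_den <- (if (n1 > 1) (v1 / n1)^2 / (n1 - 1) else 0) +
    (if (n2 > 1) (v2 / n2)^2 / (n2 - 1) else 0)
  df <- if (df_den == 0) Inf else df_num / df_den
  if (alternative == "greater") {
    stats::pt(tstat, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
}

#' Top-vs-bottom t-test curve over PubMed scores
#'
#' Scores must arrive in ascending adjusted-p order (best-ranked pathway
#' first; ties in adjusted p broken by pathway id upstream). For each
#' n = 10, 20, ..., 90 the list is split at position ceiling(n/100 * length)
#' into the top n% and bottom (100-n)% groups (a pathway never appears in
#' both), and a Welch two-sample t-test compares their PubMed scores.
#' Constant groups with equal means give p = 1. The summary statistic is
#' the arithmetic mean of the nine p-values.
#'
#' @param ranked_scores numeric vector of PubMed scores in ascending
#'   adjusted-p order, length >= 10
#' @param alternative "two.sided" (default) or "greater" (top > bottom)
#' @return list of class `ttest_curve`: `fractions` (10..90), `p_values`
#'   (length 9) and `average_p`
#' @export
ttest_curve <- function(ranked_scores, alternative = "two.sided") {
  len <- length(ranked_scores)
  if (len < 10L) stop_input("need at least 10 ranked scores")
  fractions <- seq(10L, 90L, by = 10L)
  p_values <- vapply(fractions, function(n) {
    cut <- ceiling(n / 100 * len)
    welch_p(ranked_scores[seq_len(cut)],
            ranked_scores[seq.int(cut + 1L, len)],
            alternative)
  }, numeric(1))
  structure(list(fractions = fractions, p_values = p_values,
                 average_p = mean(p_values)),
            class = "ttest_curve")
}
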