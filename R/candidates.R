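#' Volcano-plot threshold configuration
#'
#' Defaults follow the app's volcano rule: p-value <= 0.05 and absolute log2
#' fold change >= 1, both inclusive. `strict_fc` switches the fold-change
#' comparison to strict ">" (used by the shipped case-study presets, whose
#' published rule is "absolute logFC > 0.5").
#'
#' @param p_cutoff p-value threshold in (0, 1]
#' @param abs_log2fc_cutoff absolute log2 fold-change threshold, >= 0
#' @param strict_fc use strict ">" for the fold-change comparison
#' @return a `threshold_config` list
#' @export
threshold_config <- function(p_cutoff = 0.05, abs_log2fc_cutoff = 1.0,
                             strict_fc = FALSE) {
  if (p_cutoff <= 0 || p_cutoff > 1) stop_input("p_cutoff must be in (0,1]")
  if (abs_log2fc_cutoff < 0) stop_input("abs_log2fc_cutoff must be >= 0")
  structure(list(p_cutoff = p_cutoff,
                 abs_log2fc_cutoff = abs_log2fc_cutoff,
                 strict_fc = isTRUE(strict_fc)),
            class = "threshold_config")
}

#' Named case-study threshold presets
#'
#' "ms" mirrors the multiple-sclerosis configuration (adjusted p <= 0.01,
#' |logFC| > 0.5); "cd" and "uc" mirror the colonic-mucosa configurations
#' (adjusted p <= 0.05, |logFC| > 0.5). Both use a strict fold-change
#' comparison.
#'
#' @param name one of "default", "ms", "cd", "uc"
#' @return a `threshold_config`
#' @export
threshold_preset <- function(name = c("default", "ms", "cd", "uc")) {
  name <- match.arg(name)
  switch(name,
         default = threshold_config(),
         ms = threshold_config(0.01, 0.5, strict_fc = TRUE),
         cd = threshold_config(0.05, 0.5, strict_fc = TRUE),
         uc = threshold_config(0.05, 0.5, strict_fc = TRUE))
}

#' Select candidate genes by volcano thresholds
#'
#' A gene is a candidate when its p-value passes `p_cutoff` and its absolute
#' log2 fold change passes `abs_log2fc_cutoff` (inclusive comparisons unless
#' `strict_fc`). Every gene is additionally classified for plotting as
#' "over" (candidate, log2fc positive), "under" (candidate, log2fc negative)
#' or "not_significant".
#'
#' @param records data frame from [read_de_table()] (columns `gene_id`,
#'   `log2fc`, `pvalue`)
#' @param cfg a [threshold_config()]
#' @return list with `candidates` (character vector of gene ids, file order)
#'   and `classes` (data frame `gene_id`, `class`)
#' @export
select_candidates <- function(records, cfg = threshold_config()) {
  if (nrow(records) == 0L) stop_input("no DE records supplied")
  fc_pass <- if (cfg$strict_fc) {
    abs(records$log2fc) > cfg$abs_log2fc_cutoff
  } else {
    abs(records$log2fc) >= cfg$abs_log2fc_cutoff
  }
  pass <- records$pvalue <= cfg$p_cutoff & fc_pass
  cls <- ifelse(!pass, "not_significant",
                ifelse(records$log2fc > 0, "over", "under"))
  # a zero fold-change candidate (possible only when the cutoff is 0) counts
  # as "over" by the sign convention above; with default cutoffs it cannot occur
  if (!any(pass)) warning("no gene passes the volcano thresholds", call. = FALSE)
  list(candidates = records$gene_id[pass],
       classes = data.frame(gene_id = records$gene_id, class = cls,
                            stringsAsFactors = FALSE))
}
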