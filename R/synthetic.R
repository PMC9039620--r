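#' Specification of a synthetic fixture bundle
#'
#' Defaults describe the stated test world: a 2,000-gene universe, 50 PAGs
#' of 20-100 genes of which 3 are genuinely enriched, candidates covering
#' 60% of each enriched PAG with a 2 log2-unit effect, three tools whose
#' term lists paraphrase a shared truth at rate 0.3, PubMed-scale citation
#' backgrounds (N = 2e7, K = 1e5) with an 8-fold co-citation boost for true
#' pathways, and a two-normal ranking separation of 2.5 (implied AUC
#' pnorm(2.5/sqrt(2)) ~ 0.96, within the range reported for real studies).
#'
#' @param seed integer RNG seed
#' @param universe_size number of genes in the universe
#' @param n_pags number of PAGs in the collection
#' @param pag_size_range integer length-2 vector (min, max) PAG size
#' @param n_enriched number of genuinely enriched PAGs
#' @param candidate_fraction_of_enriched fraction of each enriched PAG's
#'   genes planted as candidates
#' @param de_effect_log2fc absolute log2 fold change planted on candidates
#' @param term_paraphrase_rate probability a tool's copy of a shared term is
#'   paraphrased
#' @param citation_background length-2 vector (N, K): background and
#'   disease citation totals
#' @param enriched_cocitation_boost joint-citation rate multiplier for true
#'   pathways
#' @param truth_auc_effect mean separation of the tool's ranking scores for
#'   true vs false pathways (two-normal model, unit variance)
#' @param n_true,n_excluded ground-truth composition: true pathways
#'   (enriched PAGs always included) and excluded reference rows
#' @param n_triple,n_pairwise,n_unique planted Venn-region concept counts:
#'   shared by all three tools, by each tool pair, unique to each tool
#' @param n_themes,theme_gene_fraction co-membership structure: PAGs are
#'   assigned to themes and draw this fraction of their genes from a shared
#'   theme pool, so the m-type network carries planted communities the way
#'   related pathways in real databases share components
#' @param tools tool ids (exactly three for the planted Venn design)
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(seed = 1L,
                         universe_size = 2000L,
                         n_pags = 50L,
                         pag_size_range = c(20L, 100L),
                         n_enriched = 3L,
                         candidate_fraction_of_enriched = 0.6,
                         de_effect_log2fc = 2,
                         term_paraphrase_rate = 0.3,
                         citation_background = c(N = 2e7, K = 1e5),
                         enriched_cocitation_boost = 8,
                         truth_auc_effect = 2.5,
                         n_true = 10L,
                         n_excluded = 5L,
                         n_triple = 30L,
                         n_pairwise = 10L,
                         n_unique = 10L,
                         n_themes = 5L,
                         theme_gene_fraction = 0.5,
                         tools = c("tool_a", "tool_b", "tool_c")) {
  spec <- list(seed = as.integer(seed), universe_size = as.integer(universe_size),
               n_pags = as.integer(n_pags),
               pag_size_range = as.integer(pag_size_range),
               n_enriched = as.integer(n_enriched),
               candidate_fraction_of_enriched = candidate_fraction_of_enriched,
               de_effect_log2fc = de_effect_log2fc,
               term_paraphrase_rate = term_paraphrase_rate,
               citation_background = citation_background,
               enriched_cocitation_boost = enriched_cocitation_boost,
               truth_auc_effect = truth_auc_effect,
               n_true = as.integer(n_true), n_excluded = as.integer(n_excluded),
               n_triple = as.integer(n_triple), n_pairwise = as.integer(n_pairwise),
               n_unique = as.integer(n_unique), n_themes = as.integer(n_themes),
               theme_gene_fraction = theme_gene_fraction, tools = tools)
  if (spec$n_enriched > spec$n_pags)
    stop_input("n_enriched (%d) exceeds n_pags (%d)", spec$n_enriched, spec$n_pags)
  if (spec$n_true > spec$n_pags || spec$n_true < spec$n_enriched)
    stop_input("n_true must lie between n_enriched and n_pags")
  if (spec$pag_size_range[1] < 1 || spec$pag_size_range[2] > spec$universe_size ||
      spec$pag_size_range[1] > spec$pag_size_range[2])
    stop_input("invalid pag_size_range")
  if (spec$candidate_fraction_of_enriched <= 0 ||
      spec$candidate_fraction_of_enriched > 1 ||
      spec$term_paraphrase_rate < 0 || spec$term_paraphrase_rate > 1)
    stop_input("fractions must lie in (0,1] / [0,1]")
  if (length(tools) != 3L) stop_input("the planted Venn design needs 3 tools")
  if (spec$n_themes < 1 || theme_gene_fraction < 0 || theme_gene_fraction > 1)
    stop_input("invalid theme structure")
  structure(spec, class = "fixture_spec")
}

#' @noRd
random_word <- function(len) paste(sample(letters, len, replace = TRUE),
                                   collapse = "")

#' Generate mutually dissimilar base terms
#'
#' Random three-word phrases (words of 5-8 letters), resampled until every
#' pair's OSA similarity is below `max_sim` so planted concepts can never
#' cross-match at the consensus cutoff.
#' @noRd
make_concept_terms <- function(n, max_sim = 0.6) {
  terms <- character(0)
  while (length(terms) < n) {
    cand <- paste(vapply(1:3, function(i) random_word(sample(5:8, 1)),
                         character(1)), collapse = " ")
    if (length(terms) == 0L ||
        all(string_similarity(rep(cand, length(terms)), terms) < max_sim))
      terms <- c(terms, cand)
  }
  terms
}

#' @noRd
paraphrase_term <- function(term, rate) {
  if (stats::runif(1) >= rate) return(term)
  op <- sample(c("suffix", "case", "typo"), 1L)
  if (op == "suffix") return(paste0(term, " - Homo sapiens (human)"))
  chars <- strsplit(term, "")[[1]]
  if (op == "case") {
    flip <- stats::runif(length(chars)) < 0.5 & chars %in% letters
    chars[flip] <- toupper(chars[flip])
    return(paste(chars, collapse = ""))
  }
  # typo: one substituted letter; a single edit keeps every variant of a
  # concept within OSA similarity 1 - 2/nchar >= 0.86 of every other
  idx <- which(chars %in% letters)
  i <- sample(idx, 1L)
  chars[i] <- sample(setdiff(letters, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Biology-flavored vocabulary for PAG names
#' @noRd
pag_name_vocab <- function() {
  c("apoptosis", "interferon", "chemokine", "cytokine", "kinase", "receptor",
    "adhesion", "migration", "proliferation", "differentiation", "immune",
    "response", "metabolism", "transport", "repair", "checkpoint", "cycle",
    "il-18", "il-17", "tnf", "mapk", "wnt", "notch", "jak-stat", "pi3k-akt",
    "tgf-beta", "nf-kb", "toll-like", "b-cell", "t-cell")
}

#' Generate a complete synthetic fixture bundle
#'
#' Produces, deterministically for a given seed, every input the toolkit
#' consumes: a DE table with candidates planted in the enriched PAGs, a GMT
#' PAG collection, three tool term lists that are noisy paraphrases of a
#' planted Venn design, a citation-count table with boosted joint counts
#' for true pathways, a ground-truth reference table, and a tool ranking
#' whose separation follows the two-normal model. The manifest records
#' every planted truth.
#'
#' @param spec a [fixture_spec()]
#' @return list of class `fixture_bundle` with elements `de_table`, `pags`,
#'   `term_lists`, `citation_table`, `truth`, `tool_scores`, `manifest`,
#'   `spec`
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  universe <- sprintf("G%05d", seq_len(spec$universe_size))

  ## PAG collection: each PAG draws part of its genes from a theme pool so
  ## related PAGs share members (the substrate of the m-type network)
  vocab <- pag_name_vocab()
  pag_ids <- sprintf("PAG%04d", seq_len(spec$n_pags))
  pool_size <- max(60L, ceiling(spec$universe_size / (4L * spec$n_themes)))
  theme_pools <- lapply(seq_len(spec$n_themes), function(t)
    sample(universe, min(pool_size, spec$universe_size)))
  theme_of <- sample(rep_len(seq_len(spec$n_themes), spec$n_pags))
  pags <- lapply(seq_len(spec$n_pags), function(i) {
    size <- sample(spec$pag_size_range[1]:spec$pag_size_range[2], 1L)
    n_theme <- round(spec$theme_gene_fraction * size)
    pool <- theme_pools[[theme_of[i]]]
    g <- c(sample(pool, min(n_theme, length(pool))),
           sample(setdiff(universe, pool), size - min(n_theme, length(pool))))
    nm <- paste(c(sample(vocab, 2L), "signaling pathway"), collapse = " ")
    list(pag_id = pag_ids[i], name = nm, source = "synthetic",
         pag_type = "P", genes = sort(unique(g)))
  })
  enriched_idx <- sort(sample(spec$n_pags, spec$n_enriched))

  ## DE table: candidates drawn from enriched PAGs
  planted <- unique(unlist(lapply(pags[enriched_idx], function(p) {
    sample(p$genes, ceiling(spec$candidate_fraction_of_enriched *
                              length(p$genes)))
  })))
  is_cand <- universe %in% planted
  log2fc <- stats::rnorm(spec$universe_size, 0, 0.5)
  pval <- stats::runif(spec$universe_size)
  sign_c <- sample(c(-1, 1), sum(is_cand), replace = TRUE)
  log2fc[is_cand] <- sign_c * (spec$de_effect_log2fc +
                                 abs(stats::rnorm(sum(is_cand), 0, 0.25)))
  pval[is_cand] <- stats::runif(sum(is_cand), 1e-8, 1e-3)
  de_table <- data.frame(gene_id = universe, log2fc = log2fc, pvalue = pval,
                         stringsAsFactors = FALSE)

  ## Planted Venn design over three tools
  tools <- spec$tools
  pair_regions <- utils::combn(sort(tools), 2L, paste, collapse = "+")
  regions <- c(paste(sort(tools), collapse = "+"),
               rep(pair_regions, each = spec$n_pairwise),
               rep(sort(tools), each = spec$n_unique))
  regions <- c(rep(regions[1], spec$n_triple), regions[-1])
  n_concepts <- length(regions)
  base_terms <- make_concept_terms(n_concepts)
  concept_df <- data.frame(concept = seq_len(n_concepts), term = base_terms,
                           region = regions, stringsAsFactors = FALSE)
  term_lists <- stats::setNames(lapply(tools, function(tl) {
    in_region <- vapply(strsplit(regions, "+", fixed = TRUE),
                        function(r) tl %in% r, logical(1))
    raw <- vapply(base_terms[in_region], paraphrase_term, character(1),
                  rate = spec$term_paraphrase_rate)
    ord <- sample(length(raw))
    data.frame(term = unname(raw[ord]),
               adjusted_p = sort(stats::runif(length(raw), 1e-6, 0.05))[ord],
               stringsAsFactors = FALSE)
  }), tools)

  ## Ground truth: enriched PAGs are always true; the rest of the true set
  ## is sampled; a few excluded rows exercise the labeling rule
  extra_true <- sample(setdiff(seq_len(spec$n_pags), enriched_idx),
                       spec$n_true - spec$n_enriched)
  true_idx <- sort(c(enriched_idx, extra_true))
  is_true <- seq_len(spec$n_pags) %in% true_idx
  ref_p <- ifelse(is_true, stats::runif(spec$n_pags, 1e-4, 0.05),
                  stats::runif(spec$n_pags, 0.051, 1))
  truth <- data.frame(pathway_id = pag_ids, adjusted_p = ref_p,
                      overlap = sample(1:20, spec$n_pags, replace = TRUE),
                      stringsAsFactors = FALSE)
  if (spec$n_excluded > 0L) {
    truth <- rbind(truth, data.frame(
      pathway_id = sprintf("PAGX%03d", seq_len(spec$n_excluded)),
      adjusted_p = stats::runif(spec$n_excluded, 0.051, 1),
      overlap = 0L, stringsAsFactors = FALSE))
  }

  ## Tool ranking under the two-normal separation model
  z <- stats::rnorm(spec$n_pags, mean = ifelse(is_true, spec$truth_auc_effect, 0))
  tool_scores <- stats::setNames(stats::pnorm(-z), pag_ids)

  ## Citation counts: binomial joint counts, boosted for true pathways
  N_bg <- unname(spec$citation_background[1])
  K_bg <- unname(spec$citation_background[2])
  base_rate <- K_bg / N_bg
  n_cit <- sample(200:5000, spec$n_pags, replace = TRUE)
  rate <- base_rate * ifelse(is_true, spec$enriched_cocitation_boost, 1)
  k_cit <- stats::rbinom(spec$n_pags, n_cit, rate)
  citation_table <- data.frame(keyword = pag_ids, n = n_cit, k = k_cit,
                               stringsAsFactors = FALSE)

  manifest <- list(
    seed = spec$seed,
    enriched_pags = pag_ids[enriched_idx],
    theme_of = stats::setNames(as.list(theme_of), pag_ids),
    planted_candidates = sort(planted),
    concepts = concept_df,
    region_counts = as.list(table(regions)),
    true_pathways = pag_ids[true_idx],
    citation_background = list(N = N_bg, K = K_bg)
  )
  structure(list(de_table = de_table, pags = pags, term_lists = term_lists,
                 citation_table = citation_table, truth = truth,
                 tool_scores = tool_scores, manifest = manifest, spec = spec),
            class = "fixture_bundle")
}

#' Write a fixture bundle to disk in the toolkit's standard formats
#'
#' DE table, GMT collection, per-tool term TSVs, citation TSV, ground-truth
#' TSV and a JSON manifest of the planted truths.
#'
#' @param bundle a `fixture_bundle`
#' @param outdir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_fixture <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(de = file.path(outdir, "de_table.tsv"),
             gmt = file.path(outdir, "pags.gmt"),
             citations = file.path(outdir, "citations.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             pag_names = file.path(outdir, "pag_names.tsv"),
             manifest = file.path(outdir, "manifest.json"))
  write_tsv(bundle$de_table, paths[["de"]])
  write_gmt(bundle$pags, paths[["gmt"]])
  write_tsv(data.frame(pag_id = vapply(bundle$pags, `[[`, character(1), "pag_id"),
                       name = vapply(bundle$pags, `[[`, character(1), "name"),
                       stringsAsFactors = FALSE),
            paths[["pag_names"]])
  write_tsv(bundle$citation_table, paths[["citations"]])
  write_tsv(bundle$truth, paths[["truth"]])
  for (tl in names(bundle$term_lists)) {
    p <- file.path(outdir, sprintf("terms_%s.tsv", tl))
    write_tsv(bundle$term_lists[[tl]], p)
    paths[[paste0("terms_", tl)]] <- p
  }
  jsonlite::write_json(bundle$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
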