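# pagsuite

Offline gene-set network and pathway analysis for PAG collections — PAGs
being Pathways, Annotated gene lists and Gene signatures, the unified term
for a named gene set with source metadata.

`pagsuite` is aimed at functional-genomics analysts who have a
differential-expression table and want, without any web services:

1. **Candidate selection** — volcano-plot thresholds (default
   p ≤ 0.05, |log2FC| ≥ 1) with over/under/not-significant classes.
2. **Over-representation analysis (ORA)** — for a candidate set *C* and a
   PAG *S* inside a universe of *N* genes, the hypergeometric upper tail

   P(X ≥ k) = Σ_{t=k}^{min(|C|,|S|)} C(|S|,t) · C(N−|S|, |C|−t) / C(N, |C|),

   a set-similarity score (mean of overlap coefficient k/min(|C|,|S|) and
   Jaccard k/(|C|+|S|−k)), and a rank-aware adjustment applied across the
   m PAGs that survive the overlap/similarity filters:

   p_adj = min(1, p₀ · (m + n_{pᵢ≤p₀} − 1)),

   where n_{pᵢ≤p₀} counts raw p-values at or below p₀.
3. **Cross-tool term reconciliation** — enrichment terms from different
   tools are normalized (lower-case, species/identifier suffixes stripped)
   and matched by optimal string alignment (OSA, restricted
   Damerau–Levenshtein) similarity 1 − d/max(|a|,|b|); connected components
   of the match graph give the three-way consensus (Venn) regions.
4. **m-type PAG-to-PAG networks** — co-membership edges kept when the
   pairwise hypergeometric sharing test passes Benjamini–Hochberg at 0.05,
   weighted by Jaccard; Louvain communities (seeded, deterministic) and
   per-community bag-of-words keyword frequencies.
5. **Literature co-citation validation** — PubMed score
   −ln P(X ≥ k | N, K, n) and odds ratio (k/(K−k)) / ((n−k)/(N−K−n+k))
   from a local citation-count table; ROC/AUC of a tool's ranking against a
   topology-method ground truth (true: adjusted p ≤ 0.05; false: adjusted
   p > 0.05 with ≥ 1 overlapping gene); the top-n% vs bottom-(100−n)%
   Welch t-test curve (n = 10…90); precision at cutoffs k > 0, OR > 0.1,
   score > 1e-5.

A seeded synthetic-fixture generator (`generate_fixture()`) produces every
input with planted, known structure, so the whole pipeline is testable
offline.

## Worked example

```r
library(pagsuite)

bundle <- generate_fixture(fixture_spec(seed = 42))

sel <- select_candidates(bundle$de_table, threshold_config())
length(sel$candidates)
#> [1] 127

res <- enrich(sel$candidates, bundle$pags, min_overlap = 2)
head(res[, c("pag_id", "overlap_count", "similarity_score", "p_raw", "p_adjusted")], 3)
#>    pag_id overlap_count similarity_score    p_raw p_adjusted
#> 1 PAG0038            59            0.488 6.15e-42   2.95e-40
#> 2 PAG0037            40            0.435 4.55e-27   2.23e-25
#> 3 PAG0047            30            0.424 4.24e-21   2.12e-19
bundle$manifest$enriched_pags   # the three planted PAGs, recovered on top
#> [1] "PAG0037" "PAG0038" "PAG0047"

norm <- lapply(bundle$term_lists, function(df) normalize_terms(df$term)$normalized)
consensus_partition(norm, cutoff = 0.8)$region_counts
#>                 region count
#> 1               tool_a    10
#> 2        tool_a+tool_b    10
#> 3 tool_a+tool_b+tool_c    30
#> 4        tool_a+tool_c    10
#> 5               tool_b    10
#> 6        tool_b+tool_c    10
#> 7               tool_c    10

net <- build_mtype_network(bundle$pags, universe_size = 2000)
cl  <- louvain_cluster(net, seed = 42)
c(edges = nrow(net$edges), clusters = length(unique(cl$membership)),
  modularity = round(cl$modularity, 3))
#>      edges   clusters modularity
#>    202.000      5.000      0.788

lit <- score_citations(bundle$citation_table, N = 2e7, K = 1e5)
roc <- roc_auc(bundle$tool_scores, label_ground_truth(bundle$truth))
round(roc$auc, 3)
#> [1] 0.97
ranked <- lit$pubmed_score[match(names(sort(bundle$tool_scores)), lit$keyword)]
round(ttest_curve(ranked)$average_p, 4)
#> [1] 0.0125
round(precision_at_cutoffs(lit), 2)
#>     precision_k    precision_or precision_score
#>            0.98            0.98            0.98
```

The planted truths behave as designed: the three enriched PAGs rank first
with vanishing adjusted p-values; the Venn regions reproduce the planted
30/10/10 design exactly; Louvain recovers the five gene-sharing themes; the
tool ranking separates true from false pathways (AUC near the designed
0.96) and pathways it ranks highly carry significantly higher PubMed
scores (small t-test curve average p).

## Command line

```sh
Rscript inst/cli/pagsuite simulate --seed 1 --outdir fixtures
Rscript inst/cli/pagsuite select   --de-table fixtures/de_table.tsv --out candidates.txt
Rscript inst/cli/pagsuite enrich   --candidates candidates.txt --gmt fixtures/pags.gmt --out results.tsv
Rscript inst/cli/pagsuite match    --terms fixtures/terms_tool_*.tsv --cutoff 0.8 --out pairs.tsv --venn venn.tsv
Rscript inst/cli/pagsuite network  --gmt fixtures/pags.gmt --seed 42 --out net.graphml --clusters clusters.tsv --words words.tsv
Rscript inst/cli/pagsuite litscore --citations fixtures/citations.tsv --N 2e7 --K 1e5 --out scores.tsv
Rscript inst/cli/pagsuite validate --labels fixtures/truth.tsv --results results.tsv --scores scores.tsv --out validation.tsv --roc roc.tsv
```

(After installation the launcher also lives at
`system.file("cli", "pagsuite", package = "pagsuite")`.)

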