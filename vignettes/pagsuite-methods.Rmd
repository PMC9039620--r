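---
title: "Methods: enrichment, term reconciliation, co-membership networks and literature validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment, term reconciliation, co-membership networks and literature validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagsuite)
```

# Scope and model

`pagsuite` analyses a candidate gene list against a collection of PAGs
(Pathways, Annotated gene lists, Gene signatures). Its statistical core is
classical over-representation analysis: conditioned on a universe of $N$
genes of which $|S|$ belong to a PAG, the number of PAG members among $|C|$
candidates is hypergeometric, and the evidence for enrichment is the upper
tail $P(X \ge k)$. Everything else in the package — the rank-aware p-value
adjustment, the string-similarity reconciliation of enrichment terms across
tools, the co-membership network, and the literature co-citation framework
— is post-processing of that core, in each case with the exact formula
documented on the function it implements.

This vignette records the modelling assumptions, defaults, numerical
choices and open design decisions. It states no empirical result that the
test suite or the acceptance script does not itself compute.

# Candidate selection

A gene is a candidate when $p \le p_{\text{cutoff}}$ and
$|\log_2 FC| \ge \text{fc}_{\text{cutoff}}$ (defaults 0.05 and 1.0, both
inclusive — boundary genes are candidates). Thresholds are applied to the
raw columns, never to the $-\log$ display transform of a volcano plot. The
shipped case-study presets (`threshold_preset("ms")`, `"cd"`, `"uc"`) use a
*strict* fold-change comparison (> 0.5) because that is how those published
configurations are worded; the flag `strict_fc` exposes the distinction.
Duplicate gene symbols in an uploaded table are collapsed to the row with
the smallest p-value, with a warning — a choice, since upstream pipelines
disagree on whether duplicates are meaningful.

# Enrichment

**Universe.** No background is universally correct; the default is the
union of all genes in the loaded PAG collection, with the candidate list
intersected into it. A user-supplied universe is accepted and is what the
"filters never change other PAGs' adjusted values" invariant strictly
assumes (with the union default, adding a PAG can legitimately grow the
universe and move every p-value).

**Filters before adjustment.** PAGs failing the minimum-overlap or
similarity-score filter are removed *before* p-values are computed, so the
number of tests $m$ in the adjustment is the survivor count. The adjustment

$$p_{\text{adj}} = \min\!\bigl(1,\; p_0 \,(m + n_{p_i \le p_0} - 1)\bigr)$$

counts ties inclusively ($n_{p_i\le p_0} \ge 1$, so the multiplier is at
least $m$ and $p_{\text{adj}} \ge p_0$; for $m = 1$ it is the identity).
The clamp to 1 is ours: the multiplier can exceed $1/p_0$.

**Similarity score.** The published description combines the overlap
coefficient $k/\min(|C|,|S|)$ and the Jaccard index $k/(|C|+|S|-k)$ without
printing the combination; we default to the arithmetic mean and expose
`combine = "mean" | "min" | "max"`.

**Reporting cutoff.** The shipped $-\log_2 p_{\text{adj}}$ cutoff is 4.32
($\approx p = 0.05$); the application's own default is unpublished, so the
value is a flag.

**Numerics.** Tails are computed by log-space summation of
$\log$-gamma binomial terms. When the tail holds more than half the mass,
the small complement is summed instead and combined with `log1p`, keeping
full relative precision for tails near 1 (a naive big-side sum loses
several digits there). Ties in $p_{\text{adj}}$ are broken by `pag_id` for
deterministic output.

# Term reconciliation

Terms are lower-cased, stripped of species/identifier decorations
(`default_strip_patterns()`: "homo sapiens", "(human)", KEGG/WikiPathways/
Reactome accessions, trailing bracketed suffixes), whitespace-collapsed,
and de-duplicated. Distance is optimal string alignment (OSA): unit-cost
deletion, insertion, substitution and adjacent transposition, with no
further edits inside a transposed pair — so `osa_distance("ca","abc")` is
3 where unrestricted Damerau–Levenshtein gives 2. Similarity is
$1 - d/\max(|a|,|b|)$; two empty strings are defined as identical
(avoiding 0/0).

Row-wise best match (each term of list A keeps its single best partner in
B, ties to the lexicographically smallest) is asymmetric; the consensus
partition takes the union of best matches over all *ordered* tool pairs,
making the relation symmetric, and then counts connected components per
region. A component spanning all three tools counts once in the triple
region. The default cutoff 0.8 is a design choice: published match tables
show similarities of 0.86–1.00, and the application's own cutoff is
user-set and unpublished; it is exposed as a flag everywhere.

# Co-membership networks

The m-type edge rule is a documented decision (the original construction
lives in earlier database work): for every unordered PAG pair, a
hypergeometric test of the shared-gene count against the universe,
Benjamini–Hochberg across all pairs, edges kept at adjusted $p \le 0.05$
with Jaccard weights. Alternative rules (`shared`, `jaccard`) are
pluggable. Louvain clustering is delegated to igraph (as the original
application does); we add the determinism contract — the vertex visit
order is shuffled by a caller-supplied seed, and the reported modularity is
recomputed from the returned membership, so it is exactly the standard
weighted modularity regardless of igraph version. An edgeless network
yields singleton communities with modularity defined as 0. Keyword
extraction splits PAG names on whitespace, strips leading/trailing
punctuation only (interior hyphens survive: "il-18"), lower-cases, and
drops the stop list `pathway, signaling, human, homo, sapiens, has, or,
and`.

# Literature co-citation framework

With background counts $N$ (all "disease" citations), $K$ (the specific
disease), $n$ (the keyword) and $k$ (joint), the PubMed score is
$-\ln P(X \ge k)$ under the hypergeometric, computed in log space so
$N \sim 10^7$ is routine, and the odds ratio is
$(k/(K-k)) / ((n-k)/(N-K-n+k))$. Degenerate conventions keep the ranking
total: $k=0 \mapsto 0$; $K=k$ or $n=k$ (with $k>0$) $\mapsto +\infty$,
which sorts above all finite values; a non-positive $N-K-n+k$ is an error.
Counts always come from a local table — live citation queries are out of
scope by design, so analyses are hermetic and repeatable. Precision at
cutoffs defaults to $k > 0$, $\text{OR} > 0.1$, score $> 10^{-5}$; the
published table header ("10e-5") is ambiguous between $10^{-4}$ and
$10^{-5}$ and since the score is nonnegative either reading passes almost
everything — the cutoff is a flag with no claim about intent.

# Validation framework

Ground truth follows the reference rule exactly: **true** when the
topology method's adjusted combined $p \le 0.05$ (no overlap requirement),
**false** when $p > 0.05$ with at least one gene overlapping the input
list, **excluded** otherwise (excluded rows leave the ROC). For ROC/AUC
the ranking score is $-p_{\text{adj}}$; labeled pathways a tool did not
retrieve get $p = 1$, so all tools are compared on the same label set.
Tied scores form one threshold step, and the trapezoidal AUC equals the
Mann–Whitney statistic with half-weight ties.

The t-test curve ranks pathways by adjusted p (ties broken by id), splits
at $\lceil n/100 \cdot L \rceil$ for $n = 10,\dots,90$, and compares the
two groups' PubMed scores with Welch's two-sample test (the published
variant is unstated; `alternative = "greater"` gives the one-sided top >
bottom version). Conventions: both groups constant with equal means
$\mapsto p = 1$; a single-element group contributes zero variance, so the
statistic degenerates to a comparison against the other group's spread
(this arises only at $L < 20$ for $n = 10$ or $90$).

# The synthetic world

`generate_fixture()` emulates the statistical structure the analyses
assume, with planted truths recorded in a manifest:

- **DE table / enrichment**: 2,000 genes, 50 PAGs of 20–100 genes, 3
  enriched; candidates are 60% of each enriched PAG with
  $|\log_2 FC| \ge 2$ and $p \le 10^{-3}$; null genes have
  $\log_2 FC \sim N(0, 0.5)$, $p \sim U(0,1)$ — so a handful of null genes
  pass the volcano thresholds by chance, as in real tables.
- **Co-membership**: each PAG draws half its genes from one of 5 theme
  pools (~100 genes each), the rest from the whole universe. This is what
  makes the m-type network non-trivial: fully independent random PAGs
  share genes only at chance level and the BH-corrected network is empty.
  Related pathways sharing components is exactly the signal the m-type
  concept models.
- **Term lists**: a planted Venn design (30 triple-shared concepts, 10 per
  tool pair, 10 unique per tool = 60 terms/tool) over mutually dissimilar
  three-word phrases (the generator verifies pairwise OSA similarity
  < 0.6 and resamples collisions). Paraphrasing (rate 0.3) uses species-
  suffix insertion, case randomization, and single-character typos — edits
  the normalization + OSA pipeline is designed to absorb. Token shuffling
  is deliberately absent from the default operation set: shuffled
  multi-word phrases fall below any reasonable OSA cutoff, which would
  make planted regions unrecoverable by *any* string method, telling us
  nothing about this one. With one-edit typos on ≥15-character terms,
  within-concept variants stay above similarity 0.86 and cross-concept
  pairs below 0.75, so exact region recovery is a structural property.
- **Ground truth / ranking**: 10 designated true pathways (the enriched 3
  always included), reference adjusted p drawn below/above 0.05
  accordingly, plus 5 excluded rows; the evaluated tool's ranking scores
  follow the two-normal model with separation 2.5, implying AUC
  $\Phi(2.5/\sqrt2) \approx 0.96$ — the same range the motivating studies
  report (0.85–0.99).
- **Citations**: $n \sim U\{200,\dots,5000\}$, $k \sim
  \text{Binom}(n, K/N \cdot b)$ with boost $b = 8$ for true pathways,
  $K/N = 10^5/2\times10^7$ matching the order of real disease-term counts.

What a green test does **not** establish: recovery of any published
pathway list (real databases have heavy-tailed set sizes, hierarchical
redundancy and annotation bias absent here); robustness of term matching
to semantic paraphrase (synonyms share no characters — OSA is a string
method, and the package makes no ontology claims); calibration of the
rank-aware adjustment as a FWER/FDR procedure (it is reproduced as
specified, not derived).

# Known limitations

- The rank-aware multiplier $m + n_{\le} - 1$ is neither Bonferroni nor
  Benjamini–Hochberg; its error-rate properties are inherited from the
  original application, not established here.
- OSA-based matching cannot see synonymy ("programmed cell death" vs
  "apoptosis"); the consensus counts are lower bounds on conceptual
  agreement.
- The m-type edge rule is our reconstruction of behaviour the original
  system delegates to its database; the rule is pluggable for that reason.
- `precision_at_cutoffs` measures literature coverage, not correctness:
  a heavily cited wrong pathway passes every cutoff.
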