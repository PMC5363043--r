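---
title: "Consensus clustering of co-expression modules across datasets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of co-expression modules across datasets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miccnet)
```

## The problem

Rare multi-organ diseases are typically studied through many small expression
cohorts, each profiling a different tissue on a different platform with its
own probe universe. No single cohort is powered to define a disease
signature, and gene-level meta-analysis is confounded by platform and tissue
differences. miccnet takes a different route: it clusters each dataset into
co-expression modules independently, then asks which modules *recur* across
datasets — the consensus signal — using an information-theoretic overlap
score. Recurrent disease-associated module communities are distilled into
tissue consensus gene sets, which in turn become queries against
tissue-specific weighted functional networks to expose tissue-specific
biology (hubs, bridges, and interactions present in one tissue but not
another).

This vignette explains each model, its assumptions, the tunable parameters,
and the numerical choices the package makes where the procedure was
genuinely open.

## Per-dataset preprocessing

Probes mapping to the same gene are collapsed to the gene mean and each gene
row is median-centered (`collapse_duplicates()`). Genes missing in more than
20% of samples are removed (`filter_missingness()`, boundary kept). For
gene-set scoring the matrix is standardized per gene, `z = (x - mean) / sd`
(`zscore_genes()`). Two conventions are deliberate:

* the standard deviation uses the n−1 denominator, matching the defaults of
  the statistical stacks this workflow descends from;
* zero-variance genes are dropped with a warning rather than raising an
  error, so constant probes and synthetic edge cases do not halt a pipeline.

Missing values are ignored (pairwise-complete) in means, medians, standard
deviations and correlations; imputation is out of scope.

## Signed co-expression modules

`detect_modules()` builds the signed adjacency

$$a_{ij} = \left(\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right)^{\beta},
\qquad \beta = 12,$$

so perfectly anti-correlated genes get weight 0 and uncorrelated genes
$2^{-\beta}$ — anti-correlated gene sets therefore land in *different*
modules. The adjacency is converted to a topological overlap dissimilarity
(shared-neighbor smoothing of the raw adjacency), clustered by
average-linkage hierarchical clustering, and cut at a fixed height. Modules
smaller than `min_module_size` (default 20) are labeled `"unassigned"`, and
modules whose eigengenes correlate above `1 - merge_height` (default 0.15)
are merged.

**Cut height.** A fixed quantile of the merge-height distribution turned out
to be unusable as a default: the fraction of unstructured background genes
directly shifts the upper tail of average-linkage merge heights, and a
high-quantile cut then swallows the between-module merges, collapsing
everything into one module. The default is instead gap-based: within-module
merges are tight and between-module/background merges are loose, so the cut
belongs in a large gap between consecutive merge heights. Among the three
largest gaps, the candidate cut that yields the most clusters of at least
`min_module_size` genes wins (ties to the larger gap), which guards against
a single stray outlier merge capturing the largest gap. An explicit
`cut_height` override is available.

**Eigengenes.** The module eigengene is the first right singular vector of
the gene-standardized module submatrix — a unit-norm, per-sample summary.
Singular vectors have arbitrary sign, so the package orients each eigengene
to correlate positively with the module's mean standardized profile. This is
a documented convention, not an inference: any downstream direction (e.g.
"increased in disease") is stated relative to it.

**Phenotype association** (`associate_phenotypes()`): two-class phenotypes
are tested with a two-sided Mann–Whitney U on the eigengene, continuous
phenotypes with a Spearman correlation test; p-values are
Bonferroni-corrected across modules within each phenotype. The Mann–Whitney
wrapper uses the exact null distribution whenever the data are tie-free and
a normal approximation with tie and continuity corrections otherwise; the
exact path is what lets the implementation agree with brute-force
enumeration oracles on all small inputs.

## The module overlap network

For modules $C_i$, $C_j$ from two datasets sharing $N$ measured genes,

$$W_{ij} = \frac{|C_i \cap C_j|}{N}\,
\log_2 \frac{N\,|C_i \cap C_j|}{|C_i|\,|C_j|},$$

positive/zero/negative when the overlap exceeds/equals/falls short of the
random expectation. Summed over all module pairs this is exactly the mutual
information (in bits) of the two partitions — the package's primary internal
oracle, checked to 1e-9 on random fixtures. Base 2 is a display choice; it
rescales scores without changing any sign or ranking.

`build_overlap_network()` computes $W_{ij}$ for every cross-dataset module
pair and retains edges that are positive *and* (default policy) survive a
Bonferroni-corrected one-sided hypergeometric overlap test at
$\alpha = 0.05$ within each dataset pair; a `positive_only` policy is also
provided, and the thresholded network is always a subgraph of the
positive-score network. Genes labeled `unassigned` are excluded from modules
but kept in the shared universe $N$ (configurable): they were measured, so
they inform how surprising an overlap is.

Significance of the consensus structure itself is assessed by permutation:
`mi_permutation_test()` permutes the gene labels of one partition over the
shared universe (preserving both module-size distributions) and reports the
fraction of null MI values at or above the observed MI, along with an
add-one-corrected p-value for reporting zero counts.

## Hierarchical communities and their annotation

Top-level communities come from greedy (fast-greedy) modularity maximization
on the weighted overlap network; bottom-level sub-communities from
spin-glass (Potts model) optimization within each top-level community, with
$\gamma = 1$, at most 10 spins, and the best modularity over 5 seeded
restarts. Labels are hierarchical — numerals for top-level communities by
decreasing size, letters for sub-communities — and the bottom level never
crosses a top-level boundary by construction. Disconnected components are
handled independently at both levels; sub-networks below 3 nodes are single
sub-communities without annealing. `modularity_permutation_test()` compares
the achieved modularity against size-preserving random relabelings.

**Phenotype enrichment** (`phenotype_enrichment()`): per top-level community
and phenotype, a two-sided Fisher exact test on community membership ×
phenotype-association flag (modules associated in either direction count),
Bonferroni-corrected across communities within the phenotype. Two choices
are deliberate. First, the test is two-sided because depletion of
disease-associated modules is as interpretable as enrichment. Second, only
communities with at least two nodes are tested (`min_nodes = 2`): with a
handful of datasets, modules lacking any significant cross-dataset overlap
become singleton components, and counting those as "communities" both
misrepresents the test (a singleton's enrichment is just its own flag) and
inflates the Bonferroni factor to the point where no real community can
reach $\alpha$ regardless of the data.

**Pathway annotation** works through *edge gene sets*: each retained edge
encodes the intersection $E_{ij} = C_i \cap C_j$ of its two modules over the
dataset pair's shared universe. For a pathway $P$, the Jaccard similarity
$J(E, P) = |E \cap P| / |E \cup P|$ is computed for every edge, and a
community is annotated to $P$ when its within-community edges score higher
than outside edges (two-sided Mann–Whitney, Bonferroni across pathways
within the community).

## Tissue consensus gene sets

Disease-enriched communities are selected by an explicit rule
(`select_disease_communities()`): top-level communities with a Bonferroni
p ≤ α for at least one phenotype, restricted to bottom-level children that
contain phenotype-increased modules. A manual override reproduces
analyst-driven choices. Then (`derive_tissue_consensus()`), per dataset the
*union* of its selected-module genes, per tissue the *intersection* of those
unions across the tissue's datasets, and across tissues the union of the
tissue consensus sets. A tissue with a single dataset contributes its union
directly. Intersections are computed over each tissue's common measured
universe — a gene absent from one platform cannot be consensus for that
tissue.

Two validation operations accompany the set algebra:
`consensus_centrality_test()` checks that consensus genes sit closer to
their module eigengenes (Pearson correlation, Mann–Whitney against
non-consensus genes), and `consensus_de_enrichment()` checks one-sided
Fisher enrichment of consensus genes among upregulated genes at q < 0.05
from the permutation d-statistic below.

## Querying functional networks

`query_network()` extracts the induced subgraph of a weighted functional
network on a query gene set, prunes edges below an interaction probability
of 0.5 (the conventional cutoff for these networks; configurable), keeps the
largest connected component (ties broken toward the component containing the
lexicographically smallest gene ID), and partitions it with the shared
spin-glass engine. The notions of hub and bridge are verbal in the
literature, so the package fixes explicit operational rules:

* **hubs** (`find_hubs()`): per module, the top `ceil(0.05 × module size)`
  genes (minimum one) by weighted within-module degree, ties lexicographic;
* **bridges** (`find_bridges()`): genes with participation coefficient
  $P = 1 - \sum_s (k_s/k)^2 \ge 0.5$ whose total weighted degree reaches the
  component median. $P$ is 0 for a gene confined to one module and is
  bounded by $1 - 1/m$ over $m$ modules.

Both thresholds are parameters, not claims. Module annotation against
gene-set collections is a one-sided hypergeometric test over a stated
universe (default: the query subnetwork's genes) with Benjamini–Hochberg
adjustment within module.

## Differential network analysis

For a focal tissue against a comparator tissue and a global baseline on a
common node set,

$$A_{\mathrm{diff}} = \max\!\big(A_{\mathrm{focal}} -
\max(A_{\mathrm{comp}}, A_{\mathrm{global}}),\, 0\big),$$

elementwise, with missing edges read as weight 0. Only interactions strictly
stronger in the focal tissue survive; for any pair, the focal→comparator and
comparator→focal differentials cannot both be positive, and raising any
comparator weight can only shrink the differential. The single-comparator
variant (baseline-only subtraction) is the same operation with the
comparator set to the baseline. No re-pruning is applied after subtraction:
the differential weights are already residuals, and a second absolute
cutoff would conflate the two scales. Communities of the differential
network come from the spin-glass engine on its largest connected component.

`community_weight_permutation()` classifies each community's total internal
weight against a null built by permuting node labels of the adjacency
(simultaneous row/column permutation — the weight multiset and the degree
structure of the matrix are preserved per draw). Communities above the
97.5th null percentile are labeled `more`, below the 2.5th `less`, otherwise
`none`; the symmetric 95% band is a reporting convention for the three-way
outcome.

## Gene-set scoring

`score_genesets()` summarizes a gene set in a sample as the mean z-score of
its measured member genes; a set with less than half its genes measured
(`min_coverage = 0.5`) is flagged rather than scored, since a thin sample of
a large set no longer represents it. Group comparisons per set use the
two-sided Mann–Whitney test with raw p-values by default (mirroring how such
panels are conventionally reported) and optional Benjamini–Hochberg
adjustment.

## Permutation differential expression

`sam_like_de()` computes a moderated d statistic per gene,
$d = (\bar{x}_1 - \bar{x}_2)/(s + s_0)$, with pooled standard error $s$ and
fudge factor $s_0$ set to the median of the per-gene $s$ — a simplification
of the original quantile-optimization that keeps the statistic's intent
(damping the inflated d of low-variance genes) while staying fully
testable. The null distribution comes from label permutations (exhaustive
enumeration when the requested count exceeds the number of distinct
arrangements); the per-gene q-value is the median null count of |d| values
at or above the gene's |d| divided by the observed count, capped at 1 and
made monotone non-increasing in |d|.

## The synthetic-data generator

`generate_compendium()` emulates the structure the pipeline is designed to
find: several cohorts measuring partially overlapping subsets of a master
gene list, each with planted co-expression modules built as rank-one blocks
(a per-sample eigengene times per-gene loadings uniform in [0.5, 1]) plus
Gaussian noise, with a subset of modules — the shared processes — planted in
*every* dataset and shifted upward by `effect_size` standard units in
disease samples. The disease effect is applied to the eigengene, not to
individual genes, so the planted signal is a coherent module-level shift. A
continuous severity covariate tracks the mean shared-process eigengene.
Background genes are independent standard normal. Because real cohort
modules overlap without coinciding, each dataset pads its copy of a shared
process with a fraction (default 20%) of dataset-private genes that ride the
same eigengene at weaker loadings: the shared core is the module's center,
private members its periphery. This is what makes the union-then-intersect
consensus algebra non-trivial and gives the centrality validation an actual
contrast to detect. The reference conditions (the package defaults) are 4
datasets, a 1200-gene master list with 80% per-dataset coverage, 60 samples
per dataset (half disease), 8 modules of 20–40 genes per dataset, 3 shared
processes of 30 genes, effect size 2, and noise SD 0.3 — sized so the whole
recovery suite runs in minutes on one CPU while keeping per-dataset sample
counts and module counts in the range of real compendia.

`generate_network_triple()` emits two tissue networks plus a global baseline
on a common node set: dense backbone communities present in all three
networks, tissue-specific communities whose internal edges are elevated in
exactly one tissue network, and a small fraction (5%) of strong "linker"
edges between communities shared by all three networks. Linkers are what
keep the pruned high-probability graph connected — as real functional
networks are — and they cancel exactly in the differential adjacency, so
they do not contaminate the planted differential structure. Per-network
Gaussian edge noise is clipped back to [0, 1] with the clipping fraction
reported.

What the generator does *not* emulate: probe-level artifacts, batch
effects, dye channels, correlated noise between modules, overlapping
modules, or realistic degree distributions in the functional networks.
Passing the recovery suite therefore shows the algorithms are correct and
calibrated on data matching their own assumptions — not that any particular
biological claim holds on real data.

## Determinism and numerics

Every stochastic step (spin-glass restarts, permutation tests, generators)
takes an explicit seed; `run_pipeline()` fans a single global seed out to
deterministic per-stage child seeds so any stage can be rerun in isolation,
and reruns are checksum-identical. Degenerate inputs are handled
explicitly: zero-variance genes are dropped with warnings, ties in
Mann–Whitney fall back to the corrected normal approximation, `0·log 0` in
the overlap score is 0 by convention, empty consensus intersections warn
rather than error, and all-zero differential networks return empty results
with a warning.

## Known limitations

* The tree-cut heuristic assumes a bimodal merge-height distribution; data
  with a continuum of module tightness may need an explicit `cut_height`.
* The fudge factor $s_0$ is a median, not the variance-stabilizing quantile
  search of the original method; q-values are conservative on small designs.
* Spin-glass optimization is stochastic; with few restarts on large flat
  modularity landscapes, sub-community labels can vary between seeds even
  though the recovery metrics are stable.
* The hub/bridge thresholds are conventions; rankings are robust but set
  membership near the cutoffs is not.
* Tissue consensus sets inherit every upstream thresholding decision;
  reporting precision/recall against planted truth is only possible on
  synthetic data.
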