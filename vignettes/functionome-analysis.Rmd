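---
title: "Functionome analysis with gene set regularity indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functionome analysis with gene set regularity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`funcgsr` quantifies each biological function — represented by a gene set —
by how well a sample conserves the *ordering* of that set's member genes
relative to healthy tissue. For a set with $G$ members measured on the
platform, the control samples define a **rank template**: for each of the
$\binom{G}{2}$ unordered gene pairs, the template records which gene sits
above the other in the majority of control samples. A sample's **gene set
regularity (GSR) index** is then the fraction of template pairs whose
ordering the sample reproduces:

$$\mathrm{GSR}(s, \mathcal{S}) \;=\; \frac{1}{\binom{G}{2}}
\sum_{i<j \in \mathcal{S}} \mathbf{1}\!\left[\,\mathrm{sign}(x_{si}-x_{sj})
= \tau_{ij}\,\right],$$

where $\tau_{ij}$ is the template ordering. The index is 1 when regulation
is fully conserved and 0 when fully reversed; when the template is a total
order it equals one minus the normalised Kendall distance between the
sample's within-set ranking and the template ranking. This is the
rank-conservation construction of the DIRAC family, reduced to its
control-template variant: templates are learned from controls only, never
per phenotype.

Working on orderings rather than levels is what makes multi-platform
integration tractable: monotone platform effects cancel, so cohorts
assembled from different series can be concatenated after restriction to
their common genes (`integrate_common_genes()`, with a configurable
minimum-common-genes guard defaulting to 8000 for genome-scale platforms).
The price is information loss — a mean shift that preserves within-set
ordering is invisible to the index.

Two template conventions are deliberately pinned down because the
construction leaves them open:

* **"Most common ordering" is per-pair majority**, not the modal total
  ordering. The per-pair majority is well defined for any number of
  controls, maximises the mean control matching score pair by pair (a
  property the test suite checks against random alternative templates),
  and is the standard DIRAC construction. The modal total ordering is
  ill-defined for small control counts.
* **Ties.** Within a sample, a tied gene pair satisfies neither ordering
  (strict inequality), so ties always count against the score; this is
  deterministic and symmetric. An exactly even control vote is resolved
  towards the lexicographically earlier gene and reported via a message —
  with continuous expression values this occurs only for even control
  counts, and determinism across runs matters more than the direction of
  an evidence-free bit.

Sets reduced below 2 surviving members on a platform are dropped
(`prune_gene_sets()`); orderings are undefined below two genes, which is
also why the nominal collection shrinks slightly from platform to
platform.

## Downstream stages

**Deregulation.** Per term, a two-sided Mann–Whitney U test compares case
and control GSR values; p values are Benjamini–Hochberg adjusted and terms
are ranked by ascending p with lexicographic tie-breaks for determinism.
The test is exact (full enumeration) when $n_1 n_2 \le 400$ and the pooled
values are tie-free, otherwise the tie-corrected, continuity-corrected
normal approximation is used. Significance defaults to the *adjusted*
value below 0.01 — the stricter reading of "FDR-corrected, significance
< 0.01" — with `on = "p"` available. Direction is reported as
`delta = mean_case - mean_control` (deregulation depresses regularity, so
planted effects have negative `delta`). The top-10% selection uses the
floor rule with a `top_k` override; Venn partitions are computed as exact
exclusive regions.

**Pattern recognition.** Informativeness of the functionome is measured by
stratified 5-fold cross-validation repeated 10 times with linear-kernel
soft-margin classifiers. The margin cost `C = 1` is the common default of
the underlying toolkit; the task is near-separable when the functionome
carries signal, making the result insensitive to `C`. Sensitivity,
specificity and accuracy are computed per repeat from the cumulative
confusion matrix (mean and SD across repeats); AUC is the exact rank-based
concordance of the held-out decision values pooled over all folds and
repeats, matching the "cumulative" protocol. Decision values are oriented
with the model's own training predictions, never the test labels. Folds
are stratified because tiny class imbalances otherwise destabilise
small-cohort splits; `stratify = FALSE` restores plain random folds.
Group-mean profiles are clustered with Euclidean distance and complete
linkage (the conventional defaults of the underlying tools, recorded in
the output).

**Factor structure.** Significantly deregulated terms (the `q < 0.01`
column of the deregulation table) enter exploratory factor analysis on the
samples-by-terms GSR submatrix of the disease's cohort (cases and
controls: the case/control contrast is itself the dominant correlated
structure among deregulated terms). The factor count comes from parallel
analysis — observed correlation eigenvalues against the 95th percentile of
eigenvalues from 100 same-shape standard-normal resamples, counting until
the first observed eigenvalue fails its null quantile. The leading-run
stopping rule matters: a plain exceedance count trips over trailing
eigenvalue noise and reports spurious factors on null data roughly 40% of
the time at 30 variables. Extraction is iterated principal-axis factoring
(communalities initialised at squared multiple correlations, convergence
at max change $< 10^{-4}$ or 100 iterations, Heywood communalities clipped
with a warning), followed by promax rotation (power 4, the method's
default), whose factor-correlation matrix is recovered so that the
reproduced correlation matrix $\Lambda \Phi \Lambda'$ is exactly
rotation-invariant. Terms are assigned to every factor with
$|\mathrm{loading}| \ge 0.4$ — the conventional salient-loading cutoff;
nothing in the method pins the value, so it is exposed as a parameter.
Factor elements of all factors are merged before ontology mapping (the
per-factor view is available by calling `map_to_dag()` per factor).

**Ontology summarisation.** "Clustering offspring under common ancestors"
is formalised as: build the ancestor closure of the mapped terms in the
`is_a` DAG, take weakly connected components of the induced subgraph as
clusters, and label each cluster by its minimal common ancestors — the
lowest closure nodes that are ancestors-or-self of every member. This is
deterministic, reduces to "label by the shared parent" for siblings and to
self-labelling for singletons, and every member is verifiably a descendant
of its label (`check_cluster_summary()`).

**Progression ranking.** A term is progressively deregulated along the
precursor-to-carcinoma transition when (1) it is significant in all three
diseases; (2) its two carcinoma ranks differ by less than 100; (3) their
mean is below 300; (4) its precursor rank exceeds *both* carcinoma ranks;
and (5) its case-mean GSR is lower in both carcinomas than in the
precursor. All inequalities are strict. Criterion 4's "ES and CCC or EC"
wording is ambiguous between a conjunction and a disjunction over the two
carcinomas; the conjunction is the default because the narrative of
progressive deregulation requires movement into *both* carcinoma lists,
and `upward = "or"` provides the other reading. Criterion 5 appears in the
results narrative rather than the formal criterion list, so it is a
default that can be toggled (`require_depression`). Criterion 1 is
evaluated on the same scale as the pipeline-wide significance decision
(adjusted values by default) for consistency. The core transformation
functions are the intersection of the passed terms with the terms
coexisting in all three diseases' factor elements, sorted by mean rank.

**Network reconstruction.** The merged-carcinoma network recomputes GSR on
the union of the two carcinoma cohorts against templates from their pooled
(same-tissue) controls, then estimates pairwise mutual information between
gene-set GSR vectors across the merged *case* samples with the first
Kraskov–Stögbauer–Grassberger (KSG) estimator, $k = 3$ neighbours,
max-norm neighbourhoods, in nats, clipped at zero. Cases-only is the
default because the network models disease pathogenesis; controls can be
included. GSR values are discrete-ish (pair-match fractions), so a
deterministic seeded jitter of magnitude $10^{-10}$ breaks ties — the
standard remedy for KSG on tied data; without jitter, tied inputs are an
error rather than a silent degeneracy. The edge floor defaults to the 95th
percentile of MI over 100 randomly chosen column pairs with one column
permuted (a permutation null), since no absolute MI threshold is portable
across sample sizes. ARACNE's data processing inequality is applied
multiplicatively: edge $(i,j)$ is removed when some third node $k$ gives
$\mathrm{mi}(i,j) < \min(\mathrm{mi}(i,k), \mathrm{mi}(j,k))(1 -
\varepsilon)$ with tolerance $\varepsilon = 0.05$; all removals are
decided against the original matrix and applied simultaneously, so the
result is independent of edge order. A removed edge is therefore always
the strict weakest of some triangle — no triangle's strongest edge is ever
removed on that triangle's account, and the globally strongest edge always
survives.

## The synthetic study design

The generator exists so that every stage of the pipeline is exercisable
and testable end to end. It emulates exactly the statistical features the
method consumes, and nothing else:

* every gene draws one continuous baseline level (fixing a canonical
  within-set ordering; continuity makes ties probability-zero events, and
  tie handling is tested through explicit fixtures instead);
* a sample is baseline plus Gaussian noise (`noise_sd`, default 0.5
  against baselines of unit spread — enough to keep control GSR realistic
  rather than saturated at 1);
* deregulation scrambles orderings: for each case sample and planted set,
  a random $\lceil f \cdot G \rceil$-subset of the member values is
  permuted within the sample. Because the statistic is ordering-based,
  scrambling is the direct effect dial — $f = 0$ leaves cases exchangeable
  with controls, and $f = 1$ with zero noise yields the uniform-permutation
  expectation of 1/2;
* each case sample carries one severity multiplier (uniform on 0.6–1.4)
  shared across its deregulated sets. This induces the correlated factor
  structure and the MI co-deregulation signal among planted sets that the
  factor-analysis and network stages are meant to detect; without it,
  fixed per-set fractions make deregulated sets statistically independent
  across samples;
* per-disease platforms cover random subsets of the gene universe,
  forcing common-gene integration downstream.

The default study (`default_eaoc_design()`) mirrors a tissue-matched
endometriosis / clear-cell / endometrioid design at half scale: 40 cases
and 100 controls per disease, 200 sets of 5–15 genes over 2000 genes. The
planted architecture has 20 precursor-only sets ($f = 0.7$), 8 sets shared
by the two carcinomas ($f = 0.6$), and 6 three-way "transformation" sets
graded from $f = 0.4$ in the precursor to $f = 0.85$ in the carcinomas.
The asymmetry is deliberate: progressive deregulation is only *observable*
when a term's precursor rank sits below a buffer of terms that are more
strongly deregulated in the precursor. The precursor-only block is
therefore stronger than the transformation block within ES (pushing
transformation terms to middling ES ranks), while the transformation block
tops the carcinoma rankings — and the transformation fraction in ES is
large enough to keep those terms significant there. Sets drawn from a
2000-gene universe also share genes occasionally, so scrambling one set
weakly perturbs its neighbours — as real ontology collections do; tests
that need perfectly isolated sets construct them explicitly.

What the generator does **not** model: probe-level effects, batch
structure, control-group heterogeneity across series (a single `noise_sd`
stands in for all of it), library-size or distributional artefacts, and
any biological correlation between gene *levels* beyond the planted
ordering structure. Passing tests on these cohorts therefore establishes
that the statistics recover planted ordering structure at realistic sizes
and noise — not that any particular real-data result would reproduce.

## Problem sizes used by the tests

The test suite runs the full default study (40/100 per disease, 200 sets)
across 20 seeds for the recovery, clustering-topology and progression
properties; null-calibration uses 50 seeds of a 200-set, 20/30-sample
single-disease design; estimator oracles use 1000 random template
instances, 2000-sample Gaussian pairs for the KSG closed form, and
300-sample, 30-variable, 3-factor loadings for factor recovery. Module
tests use a 3-disease design at 400 genes / 50 sets / 20 + 30 samples,
where the same architecture is identifiable but individual properties are
checked with proportionally looser bounds.

## Known limitations

* The GSR index discards level information; order-preserving shifts are
  invisible by construction.
* Per-pair majority templates need not be a consistent total order
  (Condorcet cycles are possible with few controls); the index remains
  well defined, but the Kendall-distance interpretation then holds only
  approximately.
* With strong effects and moderate cohorts, Mann–Whitney p values
  saturate, and ranks *within* the saturated block are noise-driven; the
  progression criteria are designed around rank differences of order
  50–100 for this reason.
* The permutation-null MI floor admits ~5% of null pairs by construction;
  on dense functionomes this is enough for a giant connected component, so
  component sizes are best read relative to the floor quantile.
* The edge-list GO dialect cannot represent isolated terms; use OBO
  stanzas when those matter.
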