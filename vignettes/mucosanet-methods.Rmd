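---
title: "Methods: from cervicovaginal omic layers to a consensus network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cervicovaginal omic layers to a consensus network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mucosanet` analyzes multi-omics cohorts of cervicovaginal samples: cytokine
panels, immune-cell percentages, host and bacterial proteomes, metabolites,
and the derived taxa and functional-pathway layers. This vignette is the
package's own account of the statistical machinery: the models and their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical and design choices made where the methodology was genuinely open.

## Preprocessing model

Panel assays censor values below a per-feature limit of detection (LOD).
The package treats censoring as missingness flagged in a mask, and applies
the field's standard rules:

* **Detection-rate filter** (`filter_by_detection_rate`, default threshold
  0.40): a feature missing in ≥ 40% of samples is removed. The comparison
  is deliberately `≥`, so a feature censored in exactly 40% of samples is
  dropped.
* **Half-LOD imputation** (`impute_half_min_lod`): censored cytokine
  entries become LOD/2 — the usual single-value imputation for immunoassay
  panels. It biases low-concentration variance downward; because all
  downstream group tests are rank-based this affects only the ranks among
  censored samples, which are tied anyway.
* **Metabolite zero replacement** (`impute_zero_replacement`): the named
  convention says only that censored metabolites are replaced; the package
  uses half the feature's minimum observed positive value, mirroring the
  cytokine rule and keeping values strictly positive for log2 transforms.
  Literal zeros and a global half-minimum are available as options for
  users who need a different convention.
* **Technical-variability filter** (`filter_by_technical_cv`, default
  0.25): "average covariance < 25%" in proteomics practice is read here as
  the per-protein coefficient of variation (replicate SD / replicate mean)
  across repeated runs of one reference standard; proteins at or above the
  cutoff, absent from the reference runs, or with zero replicate mean are
  dropped (the last with a warning). The boundary setting `max_cv = 1`
  disables the cutoff and keeps every feature with a positive replicate
  mean.

Filters never alter retained values; imputation is idempotent. Both
properties are enforced by tests.

## Inflammation stratification

Participants are stratified on a curated panel of ten pro-inflammatory
cytokines and chemokines (IFN-α2, IL-1α, IL-1β, IL-6, IL-8, IP-10, MCP-1,
MIP-1α, MIP-1β, RANTES), matched through an alias table so that gene
symbols (CCL5, CXCL10, ...) resolve to the panel names. The clustering
stack is not uniquely determined by common practice, so the defaults are
the most widely used heatmap stack — log2 values, per-feature z-score,
Euclidean distance, Ward (D2) linkage, tree cut at k = 3 — and all four
choices are arguments. Tests therefore assert *recovery of planted groups
on synthetic data* (≥ 95% of seeds at a ±2 SD separation), not the exact
membership of any particular cohort.

Cluster indices from a dendrogram are arbitrary, so group labels are
assigned by ranking clusters on their mean **upper-quartile cytokine
count**: for each cytokine the cohort 75th percentile is computed with the
linear-interpolation sample quantile (type 7), and a participant's count is
the number of cytokines strictly above it. "Strictly above" and the
quantile type are both switches, since the convention differs between
software packages. This ranking makes labels deterministic and gives the
low → medium → high groups non-decreasing median counts by construction.

Bacterial vaginosis is called positive at ≥ 3 of the 4 Amsel criteria;
records with a missing criterion are flagged indeterminate rather than
guessed.

## Metaproteome summarization

Spectral counts are normalized to total protein detected per participant
before any summing. Taxa abundance is the per-genus sum of normalized
counts, renormalized to proportions; proteins whose peptides match more
than one genus go to an `"undistinguishable"` bin, which is included in
the denominator by default (a flag excludes it). Species-level bins
(*L. crispatus*, *L. iners*) are kept separate where given; the
*Lactobacillus*-dominance call sums every species- and genus-level
*Lactobacillus* bin and is strict: a participant at exactly 50% is not LD.
Functional profiles sum counts of KEGG-annotated proteins per ko-level
pathway, with unannotated proteins excluded from the denominator so the
functional layer describes the annotated fraction only.

## Group statistics

Per-feature contrasts use the tie-corrected Kruskal–Wallis statistic with
a chi-square reference (`stats::kruskal.test` behind the module surface)
and Benjamini–Hochberg correction across each layer's features. Dunn's
post hoc z statistic uses the pooled-variance form with the Kruskal–Wallis
tie correction; the default multiplicity adjustment is Šidák across the
k(k−1)/2 pairs, matching the joint "Dunn's multiple comparison" behavior of
mainstream statistics software, with Bonferroni, BH, and none selectable —
the exact variant differs between implementations, so the package does not
claim p-value-exact agreement with any one of them. Monte-Carlo Fisher
tests simulate tables with fixed margins by Patefield's algorithm and use
the add-one estimator (1 + hits)/(iterations + 1), which never returns an
exact zero; the seed is a required argument and is logged in the result.
Pathway over-representation is a one-sided upper-tail hypergeometric test
per pathway with BH across pathways.

**Calibration.** The permutation-level type-I error of the
chi-square-referenced Kruskal–Wallis test is a fixed number for a given
sample size and group split. At balanced sizes of 40 per group it is
0.0498 — effectively nominal — and that is the configuration at which the
suite asserts calibration. At a small unbalanced split such as 6/25/12 the
same test's true level is ≈ 0.0465: the chi-square approximation is mildly
conservative there, a known property of the standard test rather than of
this implementation, and worth remembering when interpreting borderline
p-values at small cohort sizes.

## The Bayesian network workflow

### Screening and discretization

Each layer is reduced to its `n_top = 5` most informative features by a
random-forest classifier of the 3-level inflammation label, ranked by mean
decrease in Gini impurity with lexicographic tie-breaking (deterministic
given the seed). Screening operates on the continuous values by default —
discretization is treated as a network-construction step, not a screening
step — with a switch to screen on discretized values instead, since the
order of the two operations is a genuine ambiguity. Screened features are
discretized at the cohort median (1 = strictly above); features with more
than 90% of values tied at the median are excluded as degenerate. Seven
layers × 5 features + the 3-state inflammation variable gives the 36-node
input.

### Scoring

The BDeu score is the log marginal likelihood of the complete discrete
data under a Dirichlet prior that spreads the imaginary sample size `ess`
uniformly: α_ijk = ess/(q_i·r_i) per cell and α_ij = ess/q_i per parent
configuration, where r_i is the arity of node i and q_i its number of
parent configurations. The score is decomposable into per-family terms
(computed in C++ and memoised per (node, parent-set) pair) and likelihood
equivalent: all DAGs encoding the same conditional-independence structure
score identically, which the suite verifies exhaustively on 3-node
problems to 10⁻⁹. Mixed arities need no special casing — the 3-state
inflammation variable simply has r_i = 3.

The default `ess` for a full pipeline run is estimated by maximizing the
empty-graph score over a log-spaced grid (2⁻⁵ … 2¹⁰, 64 points) refined by
golden-section search. The estimate can be large on near-uniform binary
data, which smooths the score surface and admits denser graphs; the
parameter is exposed everywhere and the planted-recovery checks use
`ess = 1` (the conventional uniform unit prior) so that recovery is
measured under a neutral smoothing choice.

### Search

Hill climbing applies the best admissible single-edge addition, deletion,
or reversal while the score strictly improves (tolerance 10⁻¹²,
lexicographically first move on exact ties), with acyclicity checked
through a transitive-closure matrix and a `max_parents = 4` cap — 39
participants of binary data cannot estimate denser parent sets, and the
cap also guards the parent-configuration count. Greedy search can stall:
in particular, a v-structure (collider) whose parents are marginally
independent cannot be reached from the empty graph by single improving
moves. On 3-node datasets drawn from the model class itself (random DAGs
with noisy-OR conditionals) the stall rate is ~3%; on adversarial datasets
drawn from arbitrary random joint distributions, collider-shaped optima
are common and only restarts recover them. Both regimes are covered by
tests.

Restarts follow the perturb-the-incumbent scheme: restart 1 climbs from
the empty graph; each later restart applies `perturb` random valid edge
operations to the best network found so far and climbs again, keeping the
best score. The perturbation kernel draws the *operation type* first
(add/delete/reverse uniformly among feasible kinds): on sparse incumbents
a uniformly random node pair is almost always a non-edge, and a kernel
biased toward additions keeps every restart in the same basin. `perturb`
defaults to 8 — on planted 6-node benchmarks (15 DAGs × 4 seeds, 20
restarts), recovery of a structure scoring at least the true DAG rose from
92% at 5 operations to 98% at 8 — and is exposed as an argument.

### Bootstrap consensus

`bootstrap_arc_strengths` resamples participants with replacement B times,
learns each resample with R restarts, and records the undirected skeleton
of each winner; a pair's strength is the fraction of the B skeletons
containing it. Directionality is deliberately discarded — the consensus
graph is a hypothesis-generating map of dependence, not a causal claim.
Resamples that leave a variable single-valued are redrawn (capped at 100
tries). The reading of "B bootstraps averaged over R restarts" is: R
restarts *inside* each bootstrap, strengths over the B winners; B and R
are independent arguments so the alternative composition is also runnable,
and the provenance records B × R, the total number of hill-climbing
invocations.

The consensus threshold is the estimator used by averaged-network
consensus methods: choose the CDF level minimizing the L1 distance between
the empirical strength CDF and the ideal noiseless step CDF (every arc
strength 0 or 1) — the weighted median of the empirical CDF — and keep
pairs strictly above the corresponding strength quantile; the returned
threshold is the smallest retained strength, and edges are included at
`strength ≥ threshold`. Degenerate inputs (all strengths equal) return
that value and keep every pair.

Desk-scale defaults are B = 200, R = 10; the study-scale preset (B = 1000,
R = 1000, i.e. 10⁶ learned networks) sits behind
`run_config(scale = "paper")`.

## The synthetic cohort generator

`generate_cohort` draws the structure the analysis assumes, with defaults
describing a 43-participant cohort split 6/25/12 across low/medium/high
inflammation: log-normal positive abundances whose log2 means shift by
+1 (medium) and +2 (high) on designated differential features
(a monotone dose–response; the curated cytokines, APCs, 20 host proteins,
11 metabolites); LOD censoring at the 0.15 marginal quantile for cytokines
and metabolites; logistic-normal immune-cell percentages; a Dirichlet
mixture of *Lactobacillus*-heavy and *Gardnerella*/*Prevotella*-heavy
communities with group-wise LD probabilities 1.00/0.64/0.58 (expected LD
fraction 29/43 ≈ 0.674); and multinomial bacterial-protein counts within
taxa, ~55% of proteins carrying a ko-pathway tag across 33 pathways. Taxa
concentrations were chosen once to reproduce the qualitative community
structure (*L. crispatus*, *L. iners*, *Gardnerella* dominant;
*Prevotella*, *Ruminococcus* rare) — no quantitative fidelity is claimed.

Planted networks (`random_planted_bn`) use **noisy-OR** conditionals:
roots are fair coins and each active parent independently pushes the child
on (leak 1 − strength, default strength 0.9). Noisy-OR guarantees strong
marginal parent–child dependence, which is what "planted strong
dependencies" should mean for a recovery benchmark; parity (XOR)
conditionals were considered and rejected because a parity child is
marginally independent of each single parent, making the planted edges
invisible to any marginal-dependence-driven search — a pathological, not a
typical, regime.

What the generator does **not** emulate: batch and plate effects, assay
drift, compositional coupling between layers beyond the taxa/protein
hierarchy, realistic inter-feature correlation within a layer (features
are independent given the group), menstrual/menopausal covariates, and
measurement error models specific to mass spectrometry. Passing tests on
this generator therefore demonstrate that the pipeline recovers structure
it is designed to recover under its own assumptions — not that those
assumptions hold for any particular clinical cohort.

## Problem sizes used by the test suite

The suite and the acceptance script run at desk scale, chosen so a full
pass stays comfortably within a coffee break on one core: 100-dataset
sweeps for the 3-node exhaustive checks, a 10-node planted network at
n = 200 with B = 200 and R = 10 for consensus recovery (skeleton F1 ≥ 0.8),
10,000 label permutations for rank-test calibration, 50 seeds for
screening, and 200-feature null cohorts for p-value uniformity. The
study-scale preset (B = R = 1000) is available but not exercised by tests.

## Known limitations

* Consensus edges are undirected by design; no causal ordering is
  reported even though the underlying learner is a DAG search.
* The BDeu score assumes complete discrete data; participants are
  complete-case filtered before learning, which can bias toward
  participants with full assay coverage.
* Median discretization throws away within-half variation; features whose
  signal is confined to one tail lose power.
* The alpha-star-style `ess` estimate can be large on near-uniform data
  and densify the learned graphs; when the goal is conservative structure
  recovery, fix `ess = 1`.
* Dunn's post hoc p-values follow one of several software conventions
  (Šidák joint adjustment); exact agreement with other tools' adjusted
  p-values is not guaranteed and not claimed.
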