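---
title: "Integrative directed random-walk pathway activity: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative directed random-walk pathway activity: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pathway-level summaries of tumour omics profiles predict clinical outcomes
more robustly than individual genes, but most summaries (means, medians,
first principal components of member genes) ignore two things: the topology
of the gene–gene interaction network, and the interplay between regulatory
layers — in particular DNA methylation, which predominantly represses the
expression of its target gene. `idrw` implements an integrative method that
addresses both. It builds a *two-layer* directed gene–gene graph in which
every gene can appear once as an expression node and once as a methylation
node, runs a random walk with restart seeded by per-gene differential
evidence, and converts the stationary node weights into one pathway-activity
number per pathway per patient. Those activities are the features of a
survival-group classifier (good: > 3 years; poor: ≤ 3 years).

## The model, step by step

**Preprocessing.** Expression genes with zero counts in strictly more than
half the samples are removed. Missing methylation values are imputed with the
median of the same *sample* (column); the per-gene alternative is exposed as
an option. Each gene is then z-scored across samples (sample-sd convention,
n − 1; configurable), yielding the profiles $z(g_i)$ used later.

**Per-gene differential statistics.** Expression counts get a negative-
binomial Wald test (poor vs good): median-of-ratios size factors, per-gene
method-of-moments dispersion floored at $10^{-8}$, and a Wald test on the
log2 ratio of normalised group means. Methylation values get a two-tailed
Welch t-test. Each (gene, layer) pair thus carries a p-value $w_g$ and an
effect (log2 fold change for expression; the t statistic for methylation).
The NB Wald test is deliberately a compact, self-contained surrogate for a
full count-model package — no shrinkage, no outlier replacement, no
independent filtering — and `load_external_stats()` accepts a standard
results table (gene, log2FoldChange, pvalue) whenever users prefer an
external fit. No multiple-testing correction is applied anywhere: the method
gates on raw p < 0.05 throughout, so the p-values act as evidence weights,
not as inference.

**Integrated graph.** Within each layer, the directed edges of a base
gene–gene interaction graph (supplied as an edge list, e.g. a KEGG-derived
network) are restricted to the genes present in that layer. Cross-layer
edges connect the expression and methylation nodes of the same gene, in both
directions, either for every gene present in both layers (`mode = "all"`) or
only where the two profiles are significantly anti-correlated
(`mode = "anti"`: Pearson r < 0 and two-sided p < 0.05 via
$t = r\sqrt{(n-2)/(1-r^2)}$). The anti mode encodes the biological prior
that methylation represses expression; its cross-edge set is always a subset
of the all mode's.

**Walk.** Initial weights are $W_0 = -\log(w_g + \epsilon)$ with
$\epsilon = 2.2\times10^{-16}$, min–max scaled to [0, 1] *within each layer*
(so neither layer dominates merely because its test is better powered), then
L1-normalised globally. The walk iterates

$$W_{t+1} = (1-r)\,M^{T} W_t + r\,W_0,$$

with $M$ the row-normalised adjacency matrix and restart probability
$r = 0.7$, until the L1 change falls below $10^{-10}$. Convergence is
geometric with ratio at most $1-r$, and an exact solver
(`stationary_solve()`) provides an independent reference on small graphs.

**Pathway activity.** For pathway $P_j$ with differential member nodes
$g_1,\dots,g_{n_j}$ (members of the gene set, present in the graph, with
$w_g < 0.05$ in their layer),

$$a(P_j) = \frac{\sum_{i=1}^{n_j} W_\infty(g_i)\, \mathrm{score}(g_i)\, z(g_i)}
               {\sqrt{\sum_{i=1}^{n_j} W_\infty(g_i)^2}},$$

where score is the log2 fold change for expression nodes and
$\mathrm{sign}(t)$ for methylation nodes, and $z(g_i)$ is the member's own
layer's z-profile. A gene differential in both layers contributes two terms.
The statistic is degree-0 homogeneous in $W_\infty$, linear in $z$, and
flips sign when all member scores do — properties the test suite asserts
exactly.

**Feature ranking and evaluation.** Pathways are ranked either by Welch
t-tests of their activities between the groups, or by a single-hidden-layer
tied-weight denoising autoencoder trained on the activity profile: inputs
are masked to zero independently with probability 0.1, encoded as
$y = s(W\tilde{x} + b)$ and decoded as $z = s(W^{T}y + b_{dec})$, with mean
squared reconstruction error $\lVert x - z\rVert^2/2$; each pathway is then
scored by the mean of its encoder-weight column. Ranked features pass
through a greedy forward selection (a feature is kept only if it strictly
improves the mean AUC of a logistic regression under an inner 3-fold
stratified CV on the training fold), and performance is measured by
stratified 5-fold cross-validation repeated 10 times — AUC and accuracy on
each held-out fold. Features selected in more than 3 of the 50 fold-level
sets form the consolidated list.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `restart_prob` | 0.7 | probability of jumping back to $W_0$ each step; higher values keep $W_\infty$ closer to the differential evidence, lower values diffuse further along the topology |
| `tol` | 1e-10 | L1 convergence threshold of the walk |
| `alpha` | 0.05 | significance gate for differential membership and anti-correlation edges |
| `eps` | 2.2e-16 | offset inside $-\log(w_g+\epsilon)$, keeps $p = 0$ finite |
| `hidden` | 200 | autoencoder width; rankings are insensitive over 50–200 on our synthetic profiles |
| `corruption` | 0.1 | masking rate of the denoising autoencoder |
| `lr`, `epochs`, `batch` | 0.01, 500, 32 | plain minibatch SGD with Glorot-uniform init (seeded) |
| `repeats`, `folds`, `max_n` | 10, 5, 10 | evaluation protocol; `max_n` caps the greedy set |
| `min_count` | 4 | consolidation threshold, i.e. "more than 3 of 50" |

## Numerical and design choices

- **Log base in $W_0$.** Natural log; any base gives identical weights
  because min–max scaling is scale-invariant (asserted by test).
- **Degenerate layers.** If a layer's transformed weights are all equal
  (e.g. every p = 1), min–max scaling is undefined; the layer is set to the
  constant 0.5 — the midpoint of the scaled range — and the global L1 step
  then makes it uniform. Any constant yields the same within-layer
  distribution; the choice only affects the cross-layer mass split.
- **Dangling nodes.** Rows of $M$ with no outgoing edge are left all-zero,
  and the mass that would leak each step is re-injected proportionally to
  $W_0$. This keeps every iterate a probability distribution (mass
  conservation is asserted to 1e-10) and preserves the geometric
  contraction. The exact solver folds the same correction into its linear
  system, so the two routes agree to machine-level accuracy.
- **Convergence norm.** L1, matching the mass-conservation bookkeeping.
- **Sigmoid decoder with MSE.** The activity matrix is not confined to
  (0, 1), so a sigmoid decoder cannot reconstruct it exactly; the
  autoencoder here is a feature scorer, not a generative model, and the
  encoder weights are what matter. The loss still decreases monotonically in
  expectation on our data (asserted on 10-epoch moving averages).
- **Decoder bias.** An independent bias vector of length d; tying it to the
  encoder bias is dimensionally impossible for $p \neq d$.
- **Ranking sign.** Pathways are ordered by |mean encoder weight| with the
  signed score reported; a `signed = TRUE` flag switches to the signed
  ordering.
- **Greedy acceptance.** The inner criterion (3-fold stratified CV AUC on
  the training fold, strict improvement, first-ranked wins ties) is a design
  choice; nothing in the procedure's definition fixes it, and it is the one
  knob that most affects selected-set size.
- **Information leakage.** Gene-level statistics, the graph, and the walk
  are computed once on the full cohort; only feature *ranking and selection*
  are re-run inside each training fold. Likewise z-scoring is global. Both
  mirror the original procedure but mean the CV estimates are optimistic for
  truly prospective use; fold-internal re-weighting would close the gap at
  considerable cost.

## What the synthetic generator emulates — and what it does not

`simulate_pathways()` draws 50 overlapping gene sets of 10–20 genes from a
500-gene pool and wires directed edges densely within pathways (0.15) and
sparsely between them, mimicking the local density of a curated
pathway-derived interaction network. `simulate_cohort()` generates
negative-binomial counts (dispersion 0.1, log-normal baseline means around
100) modulated by a per-gene-per-sample latent factor; methylation is a
continuous value that loads negatively (−0.8) on the same latent for a
configurable fraction of genes, producing the expression–methylation
anti-correlation the integrated graph exploits. Genes of planted pathways
get a 2^1.5-fold expression increase and a +1.0 methylation shift in the
poor group; labels are balanced Bernoulli draws.

These choices were fixed once, as plausible bulk-RNA-seq-like conditions,
before any downstream result was inspected. The generator does **not**
emulate: survival times with censoring (labels are directly binary), CpG
spatial structure or beta-value boundedness (z-scoring downstream makes the
marginal scale immaterial), batch effects, library-size gradients beyond
what NB sampling induces, or realistic hub-dominated degree distributions.
Passing the end-to-end recovery test therefore shows the pipeline recovers
planted signal under idealised noise — not that it would rank real tumour
pathways correctly.

A consequence worth knowing: at the planted effect sizes above with n = 300,
*any* reasonable pathway summary separates the groups — the acceptance
script reports cross-validated AUC 1.0 for both the integrated-walk profile
and the mean-summary baseline. The ordering between methods is therefore
asserted non-strictly; distinguishing the methods' power would require much
weaker planted effects, where ranking recovery itself becomes unstable.

## Problem sizes used in validation

The test suite and the acceptance script work at deliberately modest scale,
chosen as the smallest sizes at which every asserted property is stable:
50 random graphs of 20–100 nodes for the walk-vs-solve comparison; 1,000
null genes at 30 + 30 samples for type-I calibration; and 10 replicates of
the full pipeline at 500 genes / 50 pathways / 300 samples for planted-
pathway recovery and the baseline comparison.

## Known limitations

- The NB Wald surrogate is slightly anti-conservative at small sample sizes
  (method-of-moments dispersion is noisy); with tens of samples per group it
  calibrates within the binomial band asserted in the tests. For production
  differential analysis, inject results from a dedicated count-model package
  via `load_external_stats()`.
- Walk weights use uniform out-degree transition probabilities; no edge
  confidence weighting.
- The greedy search is sequential and first-ranked-greedy; it does not
  revisit rejected features.
- Methylation enters the activity only through the *sign* of its t
  statistic, so the magnitude of differential methylation is used for node
  weighting but not for activity scaling — a property of the method, not an
  implementation choice.
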