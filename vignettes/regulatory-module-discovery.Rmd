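---
title: "Condition-specific regulatory module discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific regulatory module discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmodule)
```

## The problem

Some clinically important genes — telomerase reverse transcriptase (*TERT*)
in prostate cancer is the motivating case — are expressed too weakly to be
useful markers themselves, yet their regulation carries the biological
signal of interest. `regmodule` asks: given bulk expression profiles from
two sample conditions (e.g. tumour and normal tissue) and a generic
regulator-to-target network distilled from promoter-binding resources,
which transcription factors (TFs) drive the target gene's expression in one
condition specifically, and which co-factors form a coherent regulatory
module around them?

The package treats this as three coupled problems:

1. estimating per-sample **TF activities** from the expression of each TF's
   target genes;
2. selecting a small set of **direct regulators** whose activities best
   explain the target's expression (an exact cardinality-constrained
   regression);
3. expanding the selection to a **module** of direct plus indirect
   regulators that is densely connected in an activity-correlation network,
   via a Newman-modularity objective coupled to the regression.

## Preprocessing

`preprocess_expression()` applies the filters a practitioner would use on
log-scale RNA-seq summaries: genes with more than 25% missing values are
dropped, genes whose standard deviation (sample SD, n−1 denominator,
computed on non-missing entries before any rescaling) is at or below 0.5
are dropped as uninformative, the remaining genes are z-scored per gene
across all samples of both conditions jointly, and samples lacking a value
for the target gene are removed. The target gene is exempt from the filters
(it must survive to be modelled), and `keep_genes` lets the analyst rescue
specific genes whose unfiltered values should be retained — low-variance
TFs of a-priori interest, for example. Input values are taken to be on
their final (log) scale already; the package applies no count
normalisation.

## TF activity (the regulator statistic)

A TF's protein-level activity is only partially reflected by its own
transcript, so activity is estimated from the TF's *targets*: for regulator
$t$ with target genes $i$ carrying aggregated edge scores $es_{ti}$,

$$\mathrm{act}_{tk} \;=\; \frac{\sum_i es_{ti}\, g_{ik}}{\sum_i es_{ti}},$$

the edge-score-weighted mean of the targets' z-scored expression in sample
$k$. The modelled target gene itself is excluded from every activity sum so
the response never leaks into the predictors. Missing target values are
dropped pairwise from numerator and denominator per sample — this keeps
activities defined for as many samples as possible. A regulator with no
scored target in the filtered matrix has undefined activity and is excluded
downstream (with a message). Activities are convex combinations of z-scores
and inherit their scale; multiplying one regulator's edge scores by any
positive constant leaves its activity unchanged.

Edge scores are consumed from a source-level edge list (regulator, target,
source, weight ≥ 0); evidence for the same pair from several resources is
summed. The package does not rebuild such networks from ChIP databases.

## Direct-regulator selection (exact best-subset L1 regression)

The target's expression is modelled as

$$\hat g_{k} \;=\; \beta_0 + \sum_{t} \beta_t \; es_{t}\; \mathrm{act}_{tk},
\qquad \#\{t: \beta_t \neq 0\} \le \text{size},$$

minimising the **sum of absolute residuals**. The L1 loss is linearised in
the usual way ($e_k \ge \pm(g_k - \hat g_k)$), and the cardinality
constraint makes the problem a mixed-integer program. `fit_regulators()`
solves it **exactly** by branch and bound:

* for a fixed support the problem is plain least-absolute-deviations (LAD)
  regression, solved by the Barrodale–Roberts simplex
  (`quantreg::rq.fit.br`, median regression at $\tau = 0.5$);
* the optimal L1 error never increases when a column is added, so the LAD
  fit on (chosen ∪ undecided) columns is an admissible lower bound for
  every completion of a search node;
* search is depth-first, include-branch first, on columns ordered by their
  coefficient magnitude in the full relaxation, seeded with a greedy
  forward pass; incumbents are shared across all size caps so one tree
  serves the whole size grid.

Ties between equally optimal subsets are broken deterministically by
perturbing the objective with $10^{-9} \times$ the sum of the selected
columns' alphabetical ranks — the smaller, alphabetically earlier subset
wins, making results reproducible across platforms. Solutions are exact up
to this perturbation and the $10^{-12}$ pruning slack, far inside the
$10^{-6}$ gap the solvers are tested against.

Coefficients are left unbounded in the subset solver; the conventional
big-M box constraint on $\beta$ is retained as a diagnostic (`big_m`,
default 100): a fitted coefficient at or beyond it triggers a bound-active
warning, which on z-scored data indicates a degenerate design rather than a
real solution. The empty model (`size = 0`) fits the L1-optimal constant,
the median.

## Cross-validation and dual-condition comparison

`cross_validate()` repeats the paper-protocol ensemble: the samples are
randomly divided into 3 folds, 10 times; for every repeat, fold and size
cap in 1..10 a model is fitted on two thirds and scored by Pearson
correlation between predicted and measured expression on the held-out
third — 300 models per condition. Fold sizes differ by at most one; all
randomness flows through one integer seed.

Selection frequencies — in how many of the models each regulator appears —
are the stability statistic. `compare_conditions()` contrasts two such
ensembles per regulator with a two-sided Fisher exact test on
$[c_A, n_A - c_A; c_B, n_B - c_B]$ and adjusts across regulators with
Benjamini–Hochberg. Fisher's exact test is used rather than a chi-square
because per-regulator counts can be small; the BH adjustment uses the full
candidate set as its multiplicity.

## The modularity stage

Pairwise regulator weights combine co-activity with network support:

$$w_{t_1 t_2} = \mathrm{cor}(\mathrm{act}_{t_1}, \mathrm{act}_{t_2})
  \cdot es_{t_1 t_2},$$

with Pearson correlation, averaged over both edge directions because the
directed network need not score both (a missing direction contributes 0).
Constant activity profiles get correlation 0 with a warning. The Newman
null model is subtracted,

$$\tilde w_{t_1 t_2} = w_{t_1 t_2} - \frac{d_{t_1} d_{t_2}}{2m},
\qquad d_t = \sum_{t'} w_{t t'},\; m = \tfrac12 \sum_t d_t,$$

so that connections expected from degree alone score zero; summed over all
ordered pairs (self-pairs included, with $w_{tt}=0$) the corrected weights
add to exactly zero, a conservation identity the tests assert.

`solve_module()` maximises $\sum_{t_1 \ne t_2} \tilde w_{t_1 t_2}\,
y_{t_1 t_2}$ subject to the linking constraints that force
$y_{t_1 t_2} = x_{t_1} x_{t_2}$ and a module-size limit. Because *every*
within-module pair counts — negative corrected weights penalise — the
optimum is a genuinely coherent module, not merely a collection of good
edges. The solver is again exact branch and bound, with an optimistic bound
that adds, for the remaining budget, the largest per-node potentials
(positive ties to chosen nodes plus half the positive ties among remaining
nodes; halving makes the bound admissible since each remaining pair can be
counted at most once per endpoint).

The objective uses the *corrected* weights by default. The weight appearing
in the stated objective could also be read as the uncorrected $w$; since
only the corrected quantity makes the null model meaningful, $\tilde w$ is
the default and `corrected = FALSE` exposes the other reading.

## The combined model and λ

`solve_combined()` couples the two stages in one exact optimisation:

$$\min \;\; \sum_k e_k \;-\; \lambda \sum_{t_1 \ne t_2}
\tilde w_{t_1 t_2} y_{t_1 t_2},$$

where the regression part runs over the selected *direct* candidates, the
modularity part over *all* selected candidates, a candidate in both pools
carries a single selection variable, and the total number of selected
regulators is capped by one shared budget (this shared budget is what makes
the published slot identity come out: sizes 2..20 over 30 cross-validation
models give $30 \times \sum_{s=2}^{20} s = 6270$ selection slots per λ).
At $\lambda = 0$ the model provably reduces to pure best-subset regression —
the lexicographic tie-break keeps zero-cost indirect nodes out — and for
$\lambda$ large it reduces to the pure modularity module; both reductions
are asserted in the tests.

**Indirect candidate pre-selection** (`preselect_indirect()`) mirrors the
two-stage protocol: each direct regulator's coding gene is itself
cross-validated as a regression target, and regulators appearing in at
least 20% of those models (inclusive threshold) form the indirect pool. A
direct regulator without expression values contributes no candidates and is
reported.

**Tuning λ** (`sweep_lambda()`): for each λ on the logarithmic grid 0.001,
0.01, 0.1, 0.3, 1, 3, 10, 100, 1000, a full combined cross-validation is
run and the total selected direct and indirect regulators are counted
(membership in the direct candidate pool decides which side a selection
counts for). The tuned λ* is where the two curves cross, interpolated
linearly in $\log_{10}\lambda$ between the adjacent grid points where the
sign of (direct − indirect) flips — the grid is logarithmic, so
interpolation belongs on the log scale, and a crossing strictly between
grid points is the expected outcome. An exact tie at a grid point is
returned as is; if the curves never cross, the closest-balance grid value
is returned with a warning.

**Final module** (`extract_final_module()`): across all combined models at
λ*, the most frequent exact combination of direct regulators wins (ties
broken by higher mean held-out performance, then lexicographically); the
module's indirect set is the regulators selected in more than half of the
models carrying that winning combination. "More than half" operationalises
"the corresponding modularity regulators": majority co-selection is the
simplest stability notion consistent with the frequency machinery used
everywhere else.

## The synthetic-data generator

`simulate_regulation()` plants known structure so every stage is testable
without external data. Latent activities $a_t$ are standard normal; a
planted module shares a common factor at loading
$\sqrt{\text{module\_correlation}}$; each TF's target genes are $a_t$ plus
independent noise, so the activity statistic approximately inverts the
generative model by construction — this is what makes the regression stage
identifiable. The target gene follows the planted linear model per
condition with Gaussian noise. Two further choices make the *module* stage
identifiable and mirror how such modules look in real networks: the planted
indirect TFs regulate each other and the planted direct TFs (network edges
within the module — co-activity without edges is invisible to the weight
$w = \mathrm{cor} \cdot es$), and a fraction `indirect_drive` of each
planted direct TF's activity variance comes from the module factor (the
mechanistic path by which indirect regulation reaches the target). Every
TF gets an edge onto the target gene, as promoter-binding databases would
report, so all TFs are direct candidates; only planted ones carry signal.

What the generator does *not* emulate: RSEM/count noise distributions,
batch structure, correlated missingness, or TFs sharing target genes.
Passing recovery tests therefore show the method identifies planted linear
structure under Gaussian noise at realistic sample sizes — not that it is
robust to the full messiness of tumour expression data.

## Reference experiment sizes

The recovery experiments shipped in the tests and acceptance script use:
200 samples per condition, noise SD 0.5, 20 candidate TFs, two planted
direct regulators with coefficient 1 — and, for module recovery, a planted
4-TF module at within-module correlation 0.85 with `indirect_drive` 0.3, a
fixed 4-TF direct candidate pool, pre-selection over sizes 1..5 with 2
repeats, and a λ sweep over sizes 2..8 with 2 repeats. The direct pool is
deliberately smaller than the largest model size so that large models must
draw on the indirect pool at every λ — the same geometry as the reference
protocol (12 direct candidates, sizes up to 20), and the reason the two
count curves cross mid-grid. Dual-condition discrimination uses the full
300-model protocol per condition. Unit tests run the same machinery at
smaller sizes (6–10 TFs, 40–80 samples) chosen so each file completes in
seconds.

## Numerical choices and degenerate inputs

* LAD fits on rank-deficient designs (duplicated or collinear columns) fit
  a maximal independent column set and report zero for the dependent
  coefficients.
* Pearson correlation of a constant vector is undefined: performance
  returns `NA` with a warning, pair weights use 0 with a warning.
* A module graph with total weight $m = 0$ has no null model and is
  rejected.
* `counts_from_percentages()` rounds each cell and assigns any residual to
  the largest cell, so reconstructed rows sum exactly to their printed
  totals.
* Chi-square association tests apply no continuity correction by default
  (large clinical tables); `correct = TRUE` enables Yates for 2×2.
* All stochastic steps (fold divisions, simulations) draw from one integer
  seed via `withr::with_seed`, so identical calls are bit-identical.

## Known limitations

* Activities are linear summaries; saturating or combinatorial regulation
  is outside the model class.
* The branch-and-bound solvers are exact but exponential in the worst
  case; they are comfortable at the tens-of-candidates scale of the
  intended workflow, not at thousands of candidates.
* The λ tuning assumes the direct/indirect count curves cross on the grid;
  flat near-ties produce an unstable λ* (the sweep object reports
  `crossed` so the analyst can tell).
* Dual-condition analysis is realised as independent per-condition
  ensembles compared post hoc; the two conditions are not coupled inside
  one optimisation.
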