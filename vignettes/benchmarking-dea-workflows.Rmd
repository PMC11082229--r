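---
title: "Benchmarking proteomics DEA workflows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking proteomics DEA workflows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deabench)
library(dplyr)
```

## The problem

Detecting differentially expressed proteins from bottom-up proteomics data
involves a chain of choices after quantification: which protein-level
expression matrix to use (spectral counts, topN peptide intensities,
MaxLFQ, directLFQ, or TMT abundance/ratio/reporter summaries), how to
normalize it, how to impute missing values, and which statistic to test
with. Each 4-tuple of choices inside a quantification setting (platform x
acquisition type, e.g. FragPipe on label-free DDA) is a *workflow*, and
workflows differ wildly in how well they recover known differential
proteins from gold-standard spike-in data. `deabench` provides the
machinery to run such workflows, score them against ground truth,
aggregate scores into rankings, mine the rankings for recurrent option
patterns, validate transferability, and combine several workflows'
evidence by ensemble inference.

## Benchmark metrics

On spike-in data the truth is known per protein, so a DEA result can be
scored as a classifier. A protein is *called* DE when
$|\log_2 FC| \ge \log_2(1.5)$ and $q < 0.05$ (weak and strict
inequalities respectively; `call_de()`). Five metrics are computed per
workflow and contrast:

* **pAUC(c)** for $c \in \{0.01, 0.05, 0.1\}$: the raw (unstandardized)
  trapezoidal area under the ROC restricted to false-positive rate
  $\le c$, using $1 - q$ as the confidence score. A perfect classifier
  scores $c$; a random one $c^2/2$. Tied confidences traverse the ROC
  diagonally (simultaneous step), so permuting equal-confidence proteins
  cannot change the area.
* **nMCC** $= (\mathrm{MCC} + 1)/2$, with the convention MCC $= 0$
  whenever a denominator factor is zero.
* **G-mean** $= \sqrt{\mathrm{specificity} \times \mathrm{recall}}$, with
  a zero-denominator term contributing 0.

The pAUC is threshold-free while nMCC/G-mean score the actual calls at the
working thresholds; together they penalize both bad ordering and bad
calibration.

## Ranking and performance levels

Per workflow, each metric is averaged across benchmark datasets first and
then converted to a descending-performance rank (average-tie convention).
The final rank is the arithmetic mean of the five per-metric ranks, the
ranking position is its order (ties broken lexicographically by workflow
spec so output is reproducible), and the ranking score is
$N - \mathrm{position}$. Averaging metrics before ranking (rather than
ranking per contrast and averaging ranks) follows from treating the
cross-dataset mean as the workflow's performance estimate; it also keeps
the ranking invariant to duplicating a dataset's contrasts.

Performance levels bin positions into H (top 5%), RH (5–25%), RL
(25–50%) and L (bottom 50%). Bin edges use the *ceiling* rule:
$\mathrm{H} \iff \mathrm{position} \le \lceil 0.05N \rceil$, and likewise
at 25% and 50%. The ceiling rule is forced by consistency with the
published H-counts for the full workflow spaces (393 of 7852 and 80 of
1584 are ceilings, not roundings) and guarantees every bin is non-empty
for $N \ge 1$.

```{r}
table(label_levels(100))
sum(label_levels(7852) == "H")
```

## Normalization operators

All scaling normalizations are column-wise (per sample): normalization
targets cross-sample acquisition bias, while protein-level (row) effects
are the biology under test. Centering (`center.mean`, `center.median`)
and regression methods operate on log2 intensities; ratio scalings
(`div.*`, `total`, `max`) on raw intensities. Quantile normalization maps
each observed value through its average-tie rank onto a reference
distribution (column mean of sorted values; the robust variant uses the
median), interpolating where missingness makes column depths differ;
`MBQN` then restores each sample's original mean so that quantile
flattening cannot erase global abundance differences. The regression
methods fit each sample against the row-median reference profile — a
robust line (`Rlr`, M-estimation) or a lowess curve (`lossf`) — and
remove the fitted systematic component *while retaining the reference
profile* (output $= y - \hat{f}(r) + r$). Subtracting the fit alone would
return residuals and flatten the very protein effects the DEA step is
meant to test; adding back the reference keeps only the sample-specific
distortion removed. No normalization ever creates or destroys a missing
value.

## Imputation operators

Proteomics missingness is predominantly left-censored: low-abundance
proteins drop out. `MinDet` (per-sample low quantile, default
$q = 0.01$) and `MinProb` (seeded draws from a normal centred on that
quantile with spread equal to the median per-protein observed sd, floored
at $10^{-6}$ to avoid degenerate zero-variance draws) model that
mechanism directly. `knn` imputes from the $K = 10$ nearest proteins by
root-mean-square distance over jointly observed samples; scaling by the
shared-sample count keeps distances comparable when missingness varies.
Ties in neighbour selection break toward the smaller protein index so
results are deterministic. `SeqKNN` and `Impseq` process proteins in
ascending missing-rate order and let previously imputed proteins serve as
neighbours/regressors, which propagates information into heavily censored
rows; `Impseq` replaces the neighbour mean by a least-squares regression
of the target sample on the protein's observed samples. A protein with no
observed values falls back to `MinDet` and the fallback is recorded.
Observed values are never altered.

Methods whose internals are defined by external packages (`bpca`,
`missForest`, `GMS`, `QRILC`, `MLE`, `mice`, `nbavg`, `Impseqrob`, and
`vsn` for normalization) are plugin slots: the registry knows their
names, `register_plugin()` supplies an implementation, and
`registry_options()` reports them unavailable until one is registered.
The framework's claims are all testable without them.

## DEA statistics

The built-in statistics are the Welch t-test (robust default for
spike-in designs with small replicate counts, where equal-variance
assumptions are unnecessary risk), the classic one-way F (which at two
groups equals the pooled t-test, a property the tests verify to 1e-12),
and an empirical-Bayes moderated t. The moderated t shrinks each
protein's pooled residual variance $s^2_g$ (with $d_g$ residual df)
toward a prior: on the null model $s^2_g \sim s_0^2 \chi^2_{d_g}/d_g$
scaled by an inverse-chi-square prior with $d_0$ df, the posterior
variance is $s^2_{post} = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ and the
moderated statistic gains $d_0$ df. The prior $(d_0, s_0^2)$ is fitted by
method of moments on $\log s^2$ using digamma/trigamma corrections;
proteins with zero residual df are excluded from the fit, and if fewer
than 10 proteins have a finite variance the function falls back to the
plain t-test with a warning. When the observed $\log s^2$ dispersion does
not exceed its sampling expectation the estimator returns $d_0 = \infty$
(complete shrinkage), the correct boundary behaviour for homoscedastic
panels.

Untestable proteins (fewer than two observations in a group) keep a
record with $p = 1$ and a flag, so every protein appears in every result
and downstream padding is consistent. q-values are Benjamini-Hochberg
throughout.

## Frequent-pattern mining

Workflows are encoded as transactions of `step=option` items (the matrix
item is dropped for settings with a single registered matrix type, where
it is uninformative). `fp_growth()` is a full FP-tree implementation:
items are ordered in a header table by support (descending, name
ascending for determinism), transactions compressed into a prefix tree,
and patterns grown recursively through conditional trees. The support
ratio of a pattern mined from a performance level is computed within that
level's workflows — the natural reading of "fraction of workflows
containing the pattern" when mining H or L workflows separately.
Singleton patterns are reported (option-level enrichments are the main
readout); the empty itemset is not. The test suite proves exact
equivalence against power-set enumeration on hundreds of random
transaction sets.

## Validation: LODOCV, instrument sensitivity, option comparison

Leave-one-dataset-out cross-validation asks whether rankings transfer:
rank workflows on all datasets but one, rank them on the held-out dataset
alone, and report the Spearman correlation of the two final-rank vectors.
Correlations near 1 mean the pooled benchmark predicts unseen data.
Instrument sensitivity is assessed with a tie-corrected Kruskal-Wallis
test on a workflow's per-contrast ranks grouped by instrument class;
groups below $N = 5$ are refused since the chi-square approximation and
the comparison itself become meaningless.

Option effects within one step are isolated by matched-pair comparison:
for options A and B of a step, all workflow pairs identical in every
other step are formed, the per-metric differences are averaged, and A
wins when the mean difference is positive. Options are ordered per metric
by win count (ties broken by median performance), and the final option
rank averages the five per-metric ranks — the same aggregation used for
whole workflows.

Cross-setting comparisons merge all proteins reported under any setting,
remove multi-protein groups (delimiter `;`; ambiguous groups cannot be
matched across search engines), and pad proteins absent from a setting
with $\log_2 FC = 0$, $q = 1$. Padding makes coverage differences
visible: a truly DE protein a setting never quantified counts against it
as a false negative.

## Ensemble inference

Two strategies integrate member workflows' per-protein statistics:
`ens_multi_quant()` combines the best workflow per expression-matrix type
(complementary quantification views of the same samples), and
`ens_topk()` combines the global top-$k$ workflows. Sub-p-values are
combined by one of five methods; with $t$ of $K$ members present for a
protein:

* **hurdle**: $z_i = \Phi^{-1}(1 - p_i)$, statistic $\sum_i z_i^2$
  referred to the upper tail of $\chi^2_t$. Under independent uniform
  nulls each $z_i$ is standard normal, giving exact calibration (the
  suite verifies uniformity by KS test at $n = 5000$). With $t = 1$ the
  combined p-value *is* the single existing one, bit-for-bit. The
  one-sided transform direction is chosen because it is the unique choice
  that makes $z$ standard normal under the null; note the statistic is
  large for both very small and very large sub-p-values, so members that
  confidently report "null" also contribute evidence of heterogeneity.
* **fisher**: $-2\sum_i \ln p_i \sim \chi^2_{2t}$ (natural logarithm —
  the chi-square calibration holds for no other base).
* **min / max / median voting**: order statistics of the present
  p-values (median of an even count is the midpoint). For any fixed
  input, min $\le$ median $\le$ max, so DE-call sets are nested across
  the three modes at every threshold — a structural invariant the tests
  check end-to-end.

Raw p-values (not q-values) are combined and a single BH adjustment is
applied to the combined vector: adjusting twice would double-penalize,
and combining already-adjusted values has no distributional theory. The
ensembled $\log_2 FC$ is the sub-value of maximum magnitude (the most
sensitive view typically measures the largest uncensored fold change);
exact magnitude ties break toward the earlier member, the one documented
order-dependence. p-values of exactly 0 are clipped to $10^{-300}$ with
a warning before the log/quantile transforms.

## The spike-in simulator

`simulate_spikein()` emulates the structure of gold-standard spike-in
benchmarks at desk scale: a latent log2 abundance per protein
(`Normal(20, 2.5)`, typical of log2 LFQ intensities), a DE fraction
(default 10%) shifted in group A by $\pm$`lfc_value` (default 1), shared
per-replicate noise (sd 0.3 log2 units, a typical technical-replicate
CV), and one matrix per requested view equal to the latent replicate
matrix plus view-specific noise (default sd $0.3 \times$ replicate sd,
making views correlated but not identical — the regime in which
multi-view ensembles can help). The `counts` view applies a Poisson draw
to the scaled linear intensities so count-based plugins are exercisable;
it is not calibrated to any real instrument. Missingness is
missing-not-at-random through a logistic link
$P(\text{missing}\mid x) = \mathrm{logit}^{-1}((\tau - x)/s)$ with
steepness $s = 0.5$ on the log2 scale; $\tau$ is calibrated by bisection
so the expected missing rate matches the per-view target within $10^{-4}$
(defaults 0.17, the platform-typical DDA rate; DIA-like data is near
0.03 and TMT-like near 0.002). `simulate_collection()` draws related
datasets with $\pm 20\%$ jitter on noise and effect size for LODOCV-style
experiments. All randomness derives from one master seed via
per-component child seeds, so adding a view or dataset never perturbs the
others, and identical configs and seeds are bit-reproducible.

What the simulator does **not** emulate: peptide-level structure and
roll-up artifacts, interference/ratio compression in TMT, retention-time
drift, correlated (batch) noise, heavy-tailed intensity error, or
realistic protein-group ambiguity. Tests passing on simulated data
therefore demonstrate the correctness and calibration of the machinery
under its stated model, not workflow performance claims on any real
platform.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than by NA propagation:
constant observations give $p = 1$; MCC with a zero denominator is 0;
single-class truth is an error for pAUC; constant rank vectors are an
error for Spearman; a protein absent from all ensemble members is
excluded. Grid execution records per-cell failures as data and excludes
them from means, since brute-force grids always contain degenerate
combinations. The trigamma inversion in the moderated-t prior uses
damped Newton iterations with a positivity guard.

The shipped test and example problem sizes — hundreds to a few thousand
proteins, 3 to 20 datasets, grids of a handful of workflows, 20 seeds for
recovery checks — are the package's chosen desk-scale defaults: large
enough for the statistical checks (KS uniformity at $n \ge 2000$,
binomial concentration of realized missing rates at $n = 5000$) and small
enough to iterate quickly. The full published workflow spaces
(7852/6284/4720/1584 per setting, 34,576 experiments in total) depend on
a compatibility matrix across third-party tools that is wider than the
built-in registry; the registry is declarative precisely so those grids
can be reconstructed by registering the corresponding plugins.

## Known limitations

Only two-group contrasts are supported (no covariates, batch factors or
paired designs). The built-in DEA statistics are intensity-based;
count-based testing requires a plugin. The hurdle combiner's two-tailed
character (large sub-p-values also inflate the statistic) is inherent to
the z-square construction and should be kept in mind when members
disagree strongly. Ensemble q-values are BH over the union protein list,
so member sets with very different coverage shift each other's
adjustment.
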