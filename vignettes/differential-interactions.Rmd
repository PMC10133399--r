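---
title: "Group-specific differential gene-gene interactions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific differential gene-gene interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deggs)
```

## The model

For one interaction between a predictor gene (expression $x$) and a
response gene (expression $y$) across samples $i = 1,\dots,n$ carrying a
group factor $g_i$ with $k$ levels (treatment coding, reference level =
first requested subgroup):

$$y_i = \beta_0 + \beta_1 x_i + \beta_2 g_i + \beta_3\, x_i g_i + \varepsilon_i$$

$\beta_1$ is the gene–gene slope in the reference group; the $\beta_3$
block (one coefficient per non-reference group) carries the slope
*differences*. Differential co-expression of the link is the F-test of the
full model against the reduced model without the interaction block, with
df $(k-1,\; n-2k)$. For $k=2$ this is the squared Wald $t$ of the single
interaction coefficient; for $k>2$ it is the joint, one-way-ANOVA-style
test over all slope offsets. The test assumes approximately linear
gene–gene relationships on a variance-stabilized (log-scale) expression
scale with roughly Gaussian residuals; curved or threshold-like
relationships are invisible to it, and that is an accepted limitation of
the approach.

Inputs are therefore assumed normalized and variance stabilized (e.g.
voom-style log-CPM). The loader only checks plausibility — a matrix that is
almost entirely non-negative integers with a maximum above 1000 triggers a
raw-counts warning — and never rescales data itself.

## Robust fitting

`fit_robust_interaction()` (the default path) fits the same design by Huber
M-estimation: iteratively reweighted least squares with weights
$w_i = \min(1,\, c\,s/|r_i|)$, tuning constant $c = 1.345$ (≈95% Gaussian
efficiency), scale $s$ = normalized MAD of the residuals re-estimated every
iteration, convergence when the largest coefficient change falls below
$10^{-8}$, at most 50 iterations (on non-convergence the OLS result is
returned flagged `converged = FALSE`). Inference on the interaction block
is a Wald-type F using the M-estimator's asymptotic covariance

$$\widehat{V} = \frac{\sum_i \psi_i^2 / (n-p)}{\bar{\psi'}^2}\,(X'X)^{-1},$$

with $\psi$ the Huber score at the final scale. When no residual exceeds
$c\,s$ every weight is 1, $\psi_i = r_i$, $\bar{\psi'} = 1$, and the
statistic reduces *exactly* to the OLS F — the OLS path is therefore both a
user-facing mode and the oracle-testable special case of the robust path.
The denominator df is kept at $n - 2k$ in both paths. With ~10%
gross outliers the Huber slope-difference estimate is closer to the truth
than OLS in the large majority of replicates, at a small (<5% of the
coefficient scale) cost on clean data; both facts are measured by the test
suite rather than assumed.

Degenerate inputs never produce a fake p-value: an edge whose group drops
below `min_samples_per_group` (default 5) complete cases, whose predictor
has zero variance within a group, or whose residual df $n-2k$ is not
positive gets a missing p plus a machine-readable reason
(`insufficient_n`, `zero_variance`, `insufficient_df`). Missing expression
values are excluded pairwise per edge, keeping the maximum usable $n$.

## The network pipeline

1. **Restriction.** The prior edge list is canonicalized (undirected edges
   stored with lexicographically ordered endpoints; self-loops dropped with
   a counted warning; duplicates collapsed) and restricted to genes present
   in the expression matrix before any weighting. Identifier translation
   (Entrez to symbol) keeps edges with unmapped endpoints under their
   original ids and reports them — silently dropping them would corrupt the
   significant-link count the optimizer maximizes.
2. **Node weights.** Per group, each node is weighted by the mean
   expression of its gene over the group's samples (missings excluded; an
   all-missing gene gets $-\infty$ so any positive cut-off removes it).
3. **Percolation filter.** Nodes below a percentile cut-off of *that
   group's own* node-weight distribution are removed (nearest-rank
   convention, retention rule weight ≥ cut-off); an edge survives iff both
   endpoints survive. The cut-off is a percentile, not an absolute
   expression value, so the filter is invariant to affine changes of the
   expression scale. The percentile is chosen over a grid (default
   0, 10, …, 90 — coarse enough to bound fitting cost, fine enough to
   straddle realistic dropout fractions) to maximize the number of
   significant differential links, the smallest percentile winning ties
   (it retains the most nodes).
4. **Common-interaction removal.** An edge is kept for a group iff it
   appears in that group's filtered network and no other's (strict
   specificity; for two groups the group-specific sets are provably
   disjoint). Significance is counted *after* this removal — the maximized
   quantity is the number of differential group-specific links.
5. **Scoring.** Every group-specific edge is fitted once; results are
   memoized across grid percentiles keyed by the canonical gene pair, since
   the fit depends only on the pair, not on the threshold. The final table
   reports raw p-values (significance is declared on raw p < α, default
   0.05, matching the method's convention) with BH-adjusted values always
   alongside; the BH step-up is computed over the actually performed tests
   (missing p-values stay missing and do not count toward $m$).

Edge orientation is deterministic: for directed prior edges the source is
the predictor (the regulator explains the target); for undirected edges the
lexicographically smaller gene id is the predictor. The whole pipeline has
no internal randomness — rerunning with identical inputs gives
byte-identical output tables.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` exists so every stage is testable with known ground
truth. It draws a random DAG over the gene ordering; for each edge the
predictor is $N(\mu_g, 1)$ per group and the target follows
$m_g + b_g (x - \mu_g) + N(0, \sigma)$, with $b_g$ differing by
`beta3_effect` between groups on the planted differential edges only.
Centring the predictor keeps planted means and planted slopes independent,
so the percolation mechanism and the regression mechanism can be tested in
isolation. Defaults (100 genes, 40 samples per group, 90 edges, 10
differential with a slope difference of 2, noise sd 0.5 on the log scale)
are of the order of a small two-arm cohort study on a focused pathway
panel.

Two structural choices matter:

* **Differential targets are leaves with a single parent**, and null edges
  may not touch them. Without this, a null edge whose target shares
  ancestry with a differential edge inherits group-dependent covariance
  through the chain and becomes *truly* differential, silently corrupting
  the ground-truth labels. Null-edge targets may combine several parents
  additively; their per-edge slopes remain group-invariant.
* **Dropout is planted by role.** At percentile 0 every edge exists in
  every group and is removed as common — group-specific links can only
  arise from group-dependent node dropout. The generator therefore plants
  the differential-edge regulators as low-expression genes in the
  non-reference group (mean shifted down by `low_expression_offset`,
  default 3 log units, the size of a strong silencing event), and the
  remaining planted genes (up to `low_expression_fraction`, default 0.3) as
  low in the reference group, so both groups lose their own nodes to the
  filter and both A-specific and B-specific null edges exist for
  false-positive accounting.

Per-gene noise streams are derived from the master seed by a counter
scheme, so outputs are pure functions of the spec and enlarging one part of
the spec does not reshuffle unrelated draws.

The generator deliberately does **not** emulate count-level properties of
RNA-seq — library-size variation, mean–dispersion trends, zero inflation —
nor correlated biological covariates (age, batch) or signed
miRNA-style repressive interactions. Passing tests therefore demonstrate
the statistical machinery (calibration, power, robustness, filter and
optimizer correctness) under the model's own assumptions; they do not
certify behaviour on un-normalized or confounded real data.

## Numerical and design notes

* OLS fits go through QR (`lm`); the test suite compares them to an
  independent normal-equations oracle at $10^{-10}$.
* Nearest-rank percentiles avoid interpolation ambiguity: the cut-off is an
  actually observed weight at rank $\lceil p/100 \cdot N\rceil$, and
  percentile 0 retains everything.
* Tie-breaks are all deterministic: smallest maximizing percentile;
  lexicographic predictor for undirected edges; significant-pair table
  sorted by p, then source, then target.
* The optimizer's memoization is verified against a cache-free brute-force
  grid search (exact agreement of per-percentile counts and chosen
  threshold).
* Problem sizes in the shipped tests (100-gene pipelines, 2000-replicate
  null calibrations, 200-replicate robustness comparisons) were chosen as
  the smallest sizes at which the Monte-Carlo bands are tight enough to be
  meaningful.
* An empty result (no group-specific edge at the chosen threshold) is
  legal everywhere: the object prints, the report renders with an explicit
  "no significant links" banner, and `extract_sig_deggs()` returns an
  empty table.

## Known limitations

* Linear-only detection, by construction of the model.
* Strict specificity for $k>2$ groups (an edge present in two of three
  filtered networks is discarded everywhere) is one defensible reading of
  "group-specific"; the alternative (present-in-all removed) would retain
  more edges. Only $k=2$ has a canonical behaviour.
* The percolation optimizer maximizes a count of raw-p discoveries; it is a
  tuning device, not an error-controlled selection, which is why BH-adjusted
  p-values are always reported for the final table.
* A single percentile is applied to all groups (each on its own weight
  distribution); group-specific percentiles would add a dimension to the
  grid search and are not implemented.
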