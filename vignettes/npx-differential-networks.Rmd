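---
title: "Differential abundance and differential co-expression for NPX panel proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential abundance and differential co-expression for NPX panel proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxnet)
```

# The setting

Targeted panel immunoassays (proximity extension assays) report relative
protein abundance as NPX, a log2-scale unit: a difference of 1 NPX
corresponds to roughly a two-fold concentration difference. A typical
two-group body-fluid study — the motivating case is synovial fluid from
end-stage knee osteoarthritis (OA) versus non-OA donor knees — measures a
few hundred proteins on a handful of 92-assay panels in 10–15 persons per
group, sometimes at several sample dilutions per panel.

`npxnet` implements the full analysis chain for such data:

1. **Quality control**: dilution selection within each assay's dynamic
   range, exclusion of assays with non-linear dilution behaviour, and
   exclusion/masking of below-LOD measurements.
2. **Differential abundance**: one hierarchical linear mixed model across
   all proteins, reported as fold changes with confidence intervals.
3. **Differential co-expression**: all-pairs interaction regressions giving
   group-specific co-expression slopes, with explicit rules for selecting
   enrichment inputs and network edges.
4. **Differential networks**: group-specific Gaussian graphical models via
   a fused joint graphical lasso, tuned by AIC/BIC.
5. **Pathway enrichment**: hypergeometric over-representation against the
   detected-panel background.

Every stage is validated by parameter recovery on data from the package's
own synthetic generator, which plants known effects, conditional-dependence
edges, censoring and corrupted dilution series.

# Quality control

**Dilution selection.** When an assay is run at several dilutions, only one
can enter the analysis. The reliable window is the dynamic range
`[LOD, ULOQ]`; we pick the dilution minimizing the *median* over samples of
`|NPX − (LOD + ULOQ)/2|`. The original practice in this field is visual
inspection of dilution plots; a median-distance statistic replaces that
judgment with something testable, and the median (rather than the mean) is
used so one aberrant sample cannot drag the choice. Ties break toward the
smaller dilution factor (more analyte, better signal). An assay with no
in-range value at any dilution is flagged rather than silently dropped.

**Dilution linearity.** Diluting by a factor `d` relative to the reference
dilution should shift NPX by `−log2(d/d_ref)`. For each sample and each
adjacent dilution pair the deviation between the observed and predicted
shift is recorded; the assay's score is the mean absolute deviation, in
log2 units. Assays scoring above 1.0 log2 unit (a two-fold departure from
prediction; configurable) are excluded as non-linear — the statistic-based
counterpart of discarding assays whose dilution plots are "far from
predicted", e.g. saturated or hook-affected assays. Assays at a single
dilution get an `NA` score and are retained.

**Below-LOD rule.** An assay is excluded when more than two samples *within
either group* fall below its LOD; in retained assays, individual below-LOD
cells become missing values. They are **not** imputed at LOD/2 — the models
downstream all tolerate missingness, and imputation at an arbitrary point
inside the censored region would bias both means and slopes. LOD and ULOQ
are treated as per-assay constants on the NPX scale; per-plate LOD
variation is out of scope.

# Differential abundance

All proteins enter one linear mixed model:

```
NPX ~ protein + group + protein:group + age + sex + bmi + (1 | person)
```

with `group = control` as reference and age/BMI mean-centered so the group
contrast is evaluated at average covariates. The random person intercept
absorbs person-level offsets shared across the panel (pipetting, total
protein content, biology), which is what makes a *single* model across
hundreds of proteins sensible. The per-protein contrast is
`delta_log2 = group effect + that protein's interaction`, reported with a
Wald 95% CI using normal critical values, then exponentiated:
`FC = 2^delta_log2`. A protein is called up- or down-regulated when its CI
excludes 0; the "high magnitude" subset additionally has
`max(FC, 1/FC) >= 1.5`. **No multiplicity correction is applied anywhere**
— the design intent is exploratory, a single joint model is fitted, and
the outputs carry plain nominal CIs. Simulations at the study's sample
size (12 + 12) show mean absolute bias ~0.03 log2 units, CI coverage ~95%,
and a ~5–6% false-call rate under the global null, so the nominal
machinery is well calibrated there; with 274 proteins one still expects a
dozen false calls per run, which readers of the output tables must keep in
mind.

Two details are deliberately configurable because the parameterization of
"protein-specific group effect" is genuinely open:

* `pooling_mode = "fixed_interaction"` (default) estimates every
  protein × group interaction as a fixed effect — the literal reading of
  the model statement above.
* `pooling_mode = "shrunken_interaction"` treats the protein-specific group
  effect as a random slope over proteins, partially pooling all contrasts
  toward the panel average (borrowing strength across proteins). Its
  per-protein standard error combines the fixed group-effect variance with
  the BLUP conditional variance and is approximate (the cross term is
  ignored).
* `heteroscedastic = TRUE` allows per-protein residual variances through a
  variance-function GLS fit; off by default since the shared-variance model
  is the base specification and the GLS fit is markedly slower.

Missing (below-LOD) cells are dropped from the likelihood — the model is
fitted on the observed unbalanced data.

# Differential co-expression

For every ordered pair of proteins (outcome `y`, predictor `x`, both
standardized to pooled mean 0 / SD 1 so slopes are comparable across
pairs), ordinary least squares fits

```
y = b0 + b1 x + b2 g + b3 x g,     g = 1 for OA
```

so `b1` is the control-group slope, `b1 + b3` the OA slope and `b3` their
difference. CIs are t-based with `n − 4` degrees of freedom and a residual
variance shared between groups. Both directions of each unordered pair are
fitted, because OLS slopes are not symmetric in `x` and `y`; wherever one
result per unordered pair is needed, the direction with the larger
`|slope difference|` is kept — a deterministic tie-break. Missing values
are handled pairwise-complete to maximize the n available to each pair.

Implementation note: the full panel yields `274 × 273 = 74,802` ordered
models. These are computed in closed form from per-group sufficient
statistics (cross-product matrices), not by 75k `lm()` calls — the whole
sweep runs in under a second, and the test suite verifies exact agreement
(1e−10) with a naive normal-equations implementation.

Standardization is pooled across groups, not per group: re-standardizing
within groups would rescale the two group slopes by different factors and
change what the interaction coefficient measures.

**Selection rules.** Two separate consumers apply two different filters:

* *Enrichment input*: a pair qualifies when `|slope difference| >= 1` and
  the difference CI excludes 0. Qualifying proteins are split into a
  control-dominant and an OA-dominant set by which group shows the larger
  absolute slope; those two sets feed enrichment analyses B and C.
* *Network edges*: additionally, the group claiming the edge must itself
  show `|slope| >= 1` with its CI excluding 0; the edge is signed by that
  slope and placed in that group's network (possibly both). Each clause is
  independently toggleable in `edge_rule()` because the two published
  criteria ("difference CI" vs "group-slope CI") are stated ambiguously in
  this literature; the default requires both, the stricter reading.

No multiplicity correction is applied over the ~75k pair tests, matching
the exploratory stance; the output metadata says so prominently. At
n = 12 + 12 the edge rule recovers a median 7 of 8 planted differential
pairs with a median of 2 false edges (see the test suite), so its output
should be read as a hypothesis-generating shortlist, not inference.

# Differential networks: fused joint graphical lasso

Pairwise slopes measure marginal association. To ask which dependencies
are *conditional* — direct given all other proteins — we estimate one
sparse precision matrix per group by minimizing

```
sum_k  n_k ( tr(S_k Θ_k) − logdet Θ_k )
     + λ1 Σ_k Σ_{i≠j} |Θ_k,ij|  +  λ2 Σ_{i,j} |Θ_1,ij − Θ_2,ij|
```

`λ1` controls density (sparsity, off-diagonals only — the diagonal is
never penalized), `λ2` fuses the two groups toward a shared structure. The
solver is ADMM: an eigen-decomposition primal step per group, a closed-form
two-group fused soft-threshold, and a dual update. The ADMM coupling
parameter `rho` defaults to the mean group sample size — the likelihood
term scales with `n_k`, and matching `rho` to it cuts iteration counts by
an order of magnitude; the objective trace is monotone at this scaling and
is exposed (and tested) per fit. Convergence is declared when both primal
and dual residuals fall below tolerance; hitting `max_iter` returns the
fit flagged `converged = FALSE`.

Group covariances use within-group means, denominator `n_k`, and
pairwise-complete cells; because pairwise-complete covariance need not be
positive semi-definite, eigenvalues are clipped at 1e−8 (a nearest-PSD
repair). This is a pragmatic choice the data force on us once below-LOD
cells are masked; it is exact when there is no missingness.

**Tuning.** A grid of `(λ1, λ2)` is scored by AIC and BIC, defined per
group as `n_k tr(S_k Θ_k) − n_k logdet Θ_k + penalty × E_k` with `E_k` the
nonzero upper-triangle off-diagonals and penalty 2 (AIC) or `log n_k`
(BIC), summed over groups. Three models of increasing complexity are
marked: the BIC optimum, the AIC optimum, and a denser alternative (the
best-AIC point with strictly more edges than the AIC optimum). The default
grids are coarse and log-spaced; plain BIC for graphical models
over-selects on fine grids at moderate n, and a coarse ladder spanning
clearly under- to clearly over-penalized models is both cheaper and
better-behaved (on planted 20-protein structures at n = 100/group the
BIC pick recovers ~95% of edges at ~20% false-discovery proportion).

**Clusters.** Group-distinct edges (present in one adjacency, absent in
the other) are split into connected components per group and reported
sorted by size — the "clusters more prominent" in one condition. Edge
presence uses `|Θ_ij| > 1e−5` on the standardized scale.

The analysis is hypothesis-generating by design: no stability selection,
no bootstrap, no inference on individual partial correlations.

# Pathway enrichment

Over-representation of a query set against a pathway annotation (GMT
format; the description field carries the top-level category) is tested
with the hypergeometric upper tail: for a pathway with `m` members in the
background and `q` in the query, `p = P(X >= q)` where X counts pathway
members among `|query|` draws without replacement from the background. The
background is **the detected panel** — all proteins that survived QC — not
the genome; panel composition is highly non-random, and a genome background
would manufacture enrichment. Rows with `m < 5` are suppressed, rows are
ordered by `ratio = q/m` (descending) then p, and p-values are raw. Symbol
matching is by uppercased gene symbol. Three analyses share one background:
(A) differentially abundant proteins, (B) control-dominant and (C)
OA-dominant co-expression proteins. The hosted pathway services used in
the applied literature implement variations of this test with their own
backgrounds, so p-values from this package are not expected to reproduce
any particular service's numbers; the q, m and ratio columns are exact set
arithmetic and are tested against exhaustive enumeration.

# The synthetic-data generator

`simulate_npx_dataset()` is first-class, tested code: it is the source of
ground truth for every validation in the package. On the log2 scale each
cell is

```
baseline(protein) + effect(protein)·[case] + covariate terms
 + person intercept + noise
```

with defaults emulating the motivating study design: 13 controls vs 11
cases; three 92-assay panels, two of them at dilution series (1, 200,
1000) and (1, 20, 200); 105 proteins shifted up (to +3.4 log2 units ≈
fold change 10.6) and 35 down (to −5.06 ≈ fold change 0.03); age, sex and
BMI effects of 0.01/yr, 0.25 and 0.02 per kg/m² (weak realistic
confounding); person-intercept SD 0.5 and residual SD 1.0 log2 units —
within-group variability is essentially never published for such panels,
so these are the package's own choices of a plausible signal-to-noise
regime, stated once here. A 30-protein subset carries correlated noise
drawn per group from configurable precision matrices (the planted
conditional-dependence structure; control and case share some edges and
differ in others by default). LOD and ULOQ are set as the 2% and 99.5%
quantiles of each assay's marginal distribution; one designated
low-abundance assay is forced below LOD for four control samples (so the
below-LOD exclusion rule has a planted positive), and two designated assays
get corrupted dilution series — a saturation/hook artifact in which ideal
values above a cap fold back beneath it, so the observed inter-dilution
shift contradicts the predicted one and the linearity score flags them.

Randomness is organized as named substreams derived from one master seed,
so e.g. adding proteins does not perturb the sampled covariates, and a
fixed seed fixes every generated cell bit for bit.

What the generator does **not** emulate: plate/batch effects, counts-to-NPX
normalization chemistry, heavy-tailed or skewed residuals, missingness
mechanisms other than LOD censoring, and correlation between covariates
and group beyond sampling noise. Passing recovery tests on this generator
therefore demonstrates the *estimators and rules are correct and
calibrated under the stated model*, not that real synovial-fluid data meet
that model.

# Numerical choices and degenerate inputs

* Standardization requires ≥ 2 non-missing values and nonzero variance per
  protein; violations are named errors.
* Pairs with fewer than 4 complete rows in a group, or a constant
  predictor within a group, are flagged unestimable and excluded from
  selection rather than erroring mid-sweep.
* `select_dilution` ties break toward the smaller dilution factor;
  assays with no in-range values are flagged.
* ADMM tolerances default to 1e−8 (primal and dual, scaled by dimension);
  the reported precision matrices come from the thresholded iterate (exact
  zeros) unless it is not positive definite, in which case the PD
  eigen-step iterate is returned.
* PCA mean-imputes missing cells per protein for the overview only; every
  inferential stage keeps its own missing-data rule. Zero-variance input
  or fewer than 3 samples are errors.
* The pipeline is a pure function of (inputs, config, seed): rerunning
  with the same config gives byte-identical TSV/JSON/GraphML outputs, which
  the test suite asserts at full study scale.

# Problem sizes used in the tests

The suite exercises: the OLS oracle on 100 random 24-sample fixtures;
mixed-model recovery and null calibration at 12 + 12 persons × 5 proteins
over 500 simulations each; planted-edge recovery at 12 + 12 over 100
simulations; JGL planted-structure selection at p = 20, n = 100/group over
50 replicates; enrichment exactness against exhaustive enumeration of all
C(20,10) draws; and the full pipeline twice at study scale (276 assays,
24 samples, 74k+ ordered pairs, JGL on a 50-protein subset, 100-pathway
GMT) for byte-identity. These sizes were chosen so each claim is tested at
the scale where it is scientifically meaningful while the whole suite stays
comfortably interactive.

# Known limitations

* The Wald/normal CIs in the mixed model are nominal; with ~20 effective
  degrees of freedom for the group contrast they are mildly anti-
  conservative (measured coverage ~95.1% at the study size, but this is
  size-dependent).
* The shrunken-interaction SE ignores the BLUP/fixed-effect covariance.
* Pairwise-complete covariance plus PSD repair is ad hoc under heavy
  missingness; with > ~20% censoring per protein the JGL input becomes
  questionable.
* The edge-selection thresholds (|slope| ≥ 1 on the standardized scale)
  are conventions inherited from the applied literature, not optimized
  quantities; at n = 24 they admit a small number of false edges by
  construction.
* No plate normalization, bridging or batch correction: inputs are assumed
  already NPX-normalized.
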