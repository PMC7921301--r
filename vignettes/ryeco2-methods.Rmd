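---
title: "Methods: from A-Ci curves to trait inference in ryegrass under elevated CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from A-Ci curves to trait inference in ryegrass under elevated CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryeco2)
```

`ryeco2` is a pipeline for asking a specific ecophysiological question:
when ryegrass genotypes differ in biomass productivity under ambient and
elevated CO2, is that variation driven by leaf-level photosynthesis or by
canopy construction — tillering and leaf area? The package provides the
three layers needed to study this reproducibly: leaf biochemistry (FvCB
A-Ci fitting), whole-plant trait algebra, and the statistical inference
chain, driven by a synthetic-data generator that emulates the
genotype x treatment x chamber structure of a growth-room experiment.

## The FvCB model and A-Ci fitting

Net CO2 assimilation of a C3 leaf is modelled as the minimum of a
Rubisco-limited rate and an RuBP-regeneration-limited rate:

$$A_C = V_{Cmax}\,\frac{C_i - \Gamma^*}{C_i + K_C\,(1 + O/K_O)} - R_d,
\qquad
A_J = J_{max}\,\frac{C_i - \Gamma^*}{4C_i + 8\Gamma^*} - R_d.$$

Both branches pass through $(\Gamma^*, -R_d)$, rise strictly and
concavely in $C_i$, and saturate at $V_{Cmax}-R_d$ and $J_{max}/4 - R_d$
respectively. The kinetic constants ($K_C$, $K_O$, $\Gamma^*$) default to
the widely used tobacco-derived values at 25 C and are Arrhenius-scaled
to leaf temperature; all constants live in one editable block
(`kinetic_constants()`, `default_arrhenius()`) so a user can substitute a
different temperature-response parameterization — the published
literature contains more than one $J_{max}$ temperature function, and
the choice is deliberately exposed as configuration rather than baked
in.

**Phase assignment.** Assigning measured points to the $A_C$ or $A_J$
phase is often done by eye. `fit_aci()` automates it by exhaustive
search: every contiguous low-$C_i$ prefix (at least 2 points per side,
plus the two one-phase degenerate assignments) is a candidate split.
This is deterministic and auditable — the per-split error surface is
returned in `$candidates`.

**Exact per-split estimation.** For a *fixed* split the model is linear
in $(V_{Cmax}, J_{max}, R_d)$: each branch is a scalar multiple of a
known transform of $C_i$ minus a shared intercept. Each candidate is
therefore solved by ordinary least squares in closed form, with an
active-set step pinning $R_d$ at 0 if the unconstrained solution goes
negative (respiration in the light cannot be negative). No iterative
optimizer, no starting values, no convergence tolerance: on noiseless
data the fit is exact to machine precision, and the selected split
provably minimizes the SSE among all candidates. Ties are broken toward
the smaller transition $C_i$. A solution whose branches cross sides
(the Rubisco branch should underlie the prefix and the RuBP branch the
suffix, within 0.5 umol m^-2 s^-1) or with an unidentifiable branch
(one-phase data) is flagged `converged = FALSE` rather than discarded.

**Preprocessing.** Leak correction is a linear adjustment in the
cuvette-to-room CO2 gradient with coefficient 0 by default (leak
coefficients are instrument specific; 0 is the identity).
Triose-phosphate-use limitation appears as a plateau/decline at very
high $C_i$; `exclude_tpu_points()` operationalizes "evident at very high
Ci" as: drop trailing points at $C_i \ge$ 800 umol mol^-1 whose $A$
falls more than 0.5 umol m^-2 s^-1 below the retained maximum, never
leaving fewer than 5 points. Both thresholds are arguments.

## Whole-plant traits

The derived traits are deliberate, unit-checked algebra
(`derive_traits()`):

* `LMA = leaf dry mass / leaf area` (g m^-2), from the sampled blade;
* `LA_tiller = DW * LMF_ab / (LMA * tiller count)` (m^2), using the
  species- and treatment-specific aboveground leaf mass fraction
  (perennial 0.66 ambient / 0.59 high CO2; annual 0.57 / 0.53);
* `A_plant = A_op * DW * LMF_ab / LMA` (umol s^-1 per plant), i.e. the
  leaf rate scaled by total plant leaf area. This assumes every leaf
  sees the average growth irradiance and performs at `A_op`; it is an
  acknowledged approximation of whole-plant carbon gain, not a canopy
  light-interception model;
* `WUE_op = A_op / E_op` (umol CO2 per mmol H2O). Water-use efficiency
  is defined from transpiration, not stomatal conductance, because the
  umol mmol^-1 unit convention only works out that way — this is why
  the generator emits transpiration.

The identities `A_plant = A_op * LA_tiller * tiller_count` and
`C:N = C_mass / N_mass` hold on every record to 1e-9 and are tested as
invariants.

## The synthetic-data generator

No per-plant raw data are distributed with the study this package
emulates, so the generator is a first-class module: it defines the
conditions under which every downstream stage is validated.

Design: 38 genotypes (11 cultivars, 16 semi-natural, 9 wild perennial
accessions, 1 annual, 1 hybrid), 2 CO2 treatments, 2 chambers nested in
each treatment, 5 plants per genotype and treatment split across the
chambers (~380 plants). Gas-exchange-derived traits (Vcmax, Jmax, Rd)
exist only on a 2-plants-per-cell subsample (~76 per arm), as in a
realistic A-Ci campaign.

Strictly positive traits are log-normal; each trait's log-variance is
split into a genotype share (default 0.85), a small chamber effect
(log-SD 0.005), and residual noise, with the arithmetic treatment means
and SDs taken from the emulated study's summary table. For respiration
in the light and LMA — whose CO2 responses were reported as not
statistically detectable — the generator's ground truth is a null
effect. Genotype intercepts are shared across treatments;
genotype-specific CO2-response multipliers (log-SD 0.15) act on tiller
count and on `A_op`. Tiller count and leaf area per tiller carry a
genotype-level log-correlation of -0.3, the familiar size-number
trade-off.

With the mechanistic link on (default), dry mass is not drawn but
computed: `DW = c * tillers * LA_tiller * LMA / LMF_ab * noise`, with
the constant `c` derived in closed form so the *population mean* of DW
equals the configured treatment mean (a mean of products is not the
product of means; without `c` the means would drift by ~6%). This makes
tiller count the dominant DW predictor and genotype DW means
rank-concordant between treatments — the structural claims the
statistical pipeline is meant to detect.

**Calibration and its limits.** The variance components were fixed once
against the study's printed anchors: genotype-mean DW rank concordance
~0.80, and DW ~ tiller-count marginal/conditional R2 of ~0.37/0.75
(ambient) and 0.42/0.65 (high CO2). Averaged over seeds the generator
yields rho ~ 0.78 and R2 ~ 0.38/0.70 and 0.45/0.74. One pair of printed
numbers cannot be satisfied jointly under a Gaussian random-effects
model: a -27%..+280% genotype response span implies enough response
variance to attenuate the observable 5-plant-mean concordance well
below 0.8. The calibration privileges the concordance and R2 anchors;
the simulated response span is typically ~ -10%..+140%. Passing tests
on these data therefore demonstrate correctness of the machinery under
a plausible, internally consistent emulation — not distributional
fidelity to the original raw data, which may be heavier-tailed.

## The inference chain

**Treatment comparisons** (`compare_treatments()`) fit
`trait ~ treatment + chamber + (1 | genotype)` by REML and report the
marginal treatment effect by its t-value with Satterthwaite degrees of
freedom. A fixed decision tree governs the model actually reported:
Shapiro-Wilk residual normality and Levene homoscedasticity both passing
at alpha = 0.05 keeps the mixed model; either failing triggers
Huber-weighted iterative reweighting of the mixed model (tuning constant
1.345), whose t is reported with the *regular* model's Satterthwaite df;
a genotype variance component below 1e-8 x residual variance drops to a
plain regression, with an HC3 heteroscedasticity-consistent covariance
when a studentized Breusch-Pagan test rejects. The path taken is part of
the result (`model_path`) so it can be audited and logged. The alpha of
the diagnostic triggers, the Huber constant, and the "~0" threshold are
arguments with the stated defaults.

Chambers are nested in treatments, so a flat 4-level chamber factor is
collinear with treatment; the identifiable fixed effect used here is the
chamber's position *within* its treatment (2 levels). The data keep the
4 nested labels (A1, A2, E1, E2).

**Trait relationships** (`fit_relationship()`) are mixed-model ANCOVAs
per treatment with marginal R2 = var(fixed) / (var(fixed) + var(random)
+ var(residual)) and conditional R2 adding the random component to the
numerator — the standard variance-components definition. With
`by_treatment = TRUE`, a full-data model adds the treatment x covariate
interaction and reports its p-value.

**Predictor attribution** (`neat_analysis()`) quantifies each trait's
unique contribution to predicting DW: after a VIF screen (cutoff 10;
the collinear sets are excluded with recorded reasons, and perfect
collinearity is an error naming the pair), all variables are
standardized and each predictor's increment
`delta R2 = R2(full) - R2(without it)` is computed. On orthogonal
designs this provably equals the squared simple correlation, which the
tests verify against an all-subsets oracle to 1e-10. Leaf area per
tiller must not be offered as a predictor of DW, since it is computed
from DW.

**Rank concordance, correlograms, germination.** Spearman statistics
use average ties throughout; the rank-regression R2 equals rho^2 by
construction, a coherence the tests assert. Correlograms are
complete-case only and star p at 0.05/0.01/0.001. Germination tables
get Fisher's exact test (2x2) with the chi-square statistic (no
continuity correction) alongside; Benjamini-Hochberg adjustment is
applied per contrast family, not globally.

## Clustering

Genotype x trait matrices of means (complete-case genotypes, z-scored
per trait with sample SD) are clustered with Ward's minimum-variance
criterion on Euclidean distances (`hclust` "ward.D2" — the
Lance-Williams update on squared distances; Ward dialects differ and
this one is pinned deliberately) and with k-means (25 seeded restarts).
Method and k are chosen by three internal validation metrics:
connectivity (neighbourhood size L = 10, the conventional default),
mean silhouette width, and the Dunn index (minimum between-cluster
distance over maximum within-cluster diameter); solutions are ranked by
silhouette with ties broken by lower connectivity. The clustering trait
set excludes subsample-only traits (Vcmax, Jmax, Rd) and the two
collinear ones (g_sop with WUE_op, N_mass with C:N); standardization
happens after complete-case subsetting. Two-cluster trait comparisons
follow the assumption-driven choice between Student's t, Welch's t, and
Mann-Whitney U via per-cluster Shapiro-Wilk and Levene tests.

## Problem sizes and numerical choices

The test-suite simulations use a 12-genotype, 3-plants-per-cell
configuration for repeated-fit studies (type-I calibration over 1000
null replicates), the full 38-genotype design for single study-scale
runs, and 250 genotypes x 20 plants where population means must be
resolved against configured targets; these sizes resolve the quantities
being checked while keeping the default test run fast. Other
numerical choices worth knowing: the A-Ci split search treats SSE ties
within 1e-12 as exact ties; Arrhenius round trips are exact to 1e-12
relative; the silhouette of a singleton cluster follows the `cluster`
package convention; k-means assignment noise is eliminated by seeding
each restart set.

## Known limitations

* The generator emulates summary-calibrated log-normal traits with a
  single shared genotype intercept per trait; real data will have
  trait-specific genotype correlation structure and possibly heavier
  tails.
* `A_plant` inherits the single-irradiance assumption; no within-canopy
  light gradient is modelled.
* Mesophyll conductance is not modelled (Ci-based, not Cc-based FvCB),
  TPU is excluded rather than fitted, and the leak correction is a
  linear placeholder for instrument-specific protocols.
* The robust mixed path is Huber IRLS on the residual scale; it covers
  the weighting contract of dedicated robust mixed-model estimators but
  not their full theory (e.g. no robustness weights on random effects).
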