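# ryeco2

Intraspecific CO2-response analysis for ryegrass (*Lolium*): FvCB A–Ci
curve fitting, whole-plant trait derivation, and a mixed-model trait
inference pipeline.

## The problem

Breeding strategies for a high-CO2 future need to know *which* traits
drive genotype-to-genotype differences in productivity. When dozens of
ryegrass genotypes are grown at ambient (~400 µmol mol⁻¹) and elevated
(~800 µmol mol⁻¹) CO2, aboveground dry mass (DW) can vary several-fold
among genotypes — and the question is whether that variation is carried
by leaf-level photosynthesis or by canopy construction: tillering and
leaf area. `ryeco2` implements the full computational chain needed to
answer this on per-plant trait tables and leaf gas-exchange curves, plus
a hierarchical synthetic-data generator so every stage is testable
without access to raw experimental data.

## What's inside

**Leaf biochemistry.** The Farquhar–von Caemmerer–Berry model of C3
photosynthesis: net assimilation is the minimum of a Rubisco-limited and
an RuBP-regeneration-limited rate,

    Ac = Vcmax (Ci − Γ*) / (Ci + Kc(1 + O/Ko)) − Rd
    Aj = Jmax (Ci − Γ*) / (4Ci + 8Γ*) − Rd

with Arrhenius temperature scaling of the kinetic constants and of the
fitted parameters. `fit_aci()` turns a measured A–Ci curve into
(Vcmax, Jmax, Rd) at leaf temperature and at 25 °C by exhaustive
transition-point search with *exact* per-split least squares (the model
is linear in the parameters once the phase split is fixed), after leak
correction and triose-phosphate-use point exclusion.

**Whole-plant traits.** LMA, C:N, WUE_op = A_op/E_op, leaf area per
tiller LA_tiller = DW·LMF_ab/(LMA·tillers), and whole-plant carbon gain
A_plant = A_op·DW·LMF_ab/LMA, with per-genotype percent responses to
elevated CO2.

**Inference.** Treatment comparisons through a documented
model-selection decision tree (mixed model → Huber-robust mixed →
plain/HC3 regression, with Satterthwaite df), mixed-model ANCOVA with
marginal/conditional R², genotype rank concordance between treatments,
Spearman correlograms, incremental-R² ("neat") predictor attribution
with VIF screening, status-group contrasts with Benjamini–Hochberg
adjustment, and germination contingency tests.

**Clustering.** Ward (ward.D2) hierarchical clustering and k-means of
standardized genotype × trait matrices, with method/k selection by
connectivity, silhouette width and Dunn index, and two-cluster
per-trait comparisons via the Student/Welch/Mann–Whitney decision rule.

**Synthetic data.** `generate_plants()` emulates the study design —
38 genotypes × 2 treatments × 2 chambers/treatment × 5 plants — with
genotype intercepts shared across treatments, genotype-specific CO2
response multipliers, and a mechanistic DW = tillers × LA_tiller × LMA /
LMF_ab link. See the methods vignette
(`vignettes/ryeco2-methods.Rmd`) for the model, calibration choices and
their limits.

## Worked example

```r
library(ryeco2)

# a study-scale synthetic dataset (380 plants, 38 genotypes)
plants <- generate_plants(generator_config(), seed = 42)

compare_treatments(plants, "dw")
#> dw: high CO2 - ambient = 9.09 (SE 0.71), t = 12.80, df = 340.0, p = 6.91e-31 [robust_mixed]

fit_relationship(plants, "dw", "tiller_count", by_treatment = TRUE)$fits[,
  c("treatment", "slope", "marginal_R2", "conditional_R2")]
#>   treatment slope marginal_R2 conditional_R2
#> 1 ambient   0.136       0.274          0.800
#> 2 high_CO2  0.201       0.453          0.754

gm <- genotype_mean_responses(plants, "dw")
rank_concordance(gm$mean_ambient, gm$mean_high)
#> rho = 0.79, rank R2 = 0.63 (38 genotypes)

# round-trip an A-Ci curve through the FvCB fitter
env <- predict_envelope(aci_grid(), fvcb_params(71.1, 134.3, 0.89),
                        kinetic_constants())
fit_aci(aci_curve(env$Ci, env$A))
#> A-Ci fit 'curve': Vcmax25 = 71.10, Jmax25 = 134.30, Rd25 = 0.890 | SSE = 2.3e-28 | converged
```

Reading: the simulated high-CO2 treatment raises DW by ~9 g per plant
(the robust mixed-model path was taken because the raw-scale residuals
of log-normal traits are right-skewed); tiller count explains ~27–45%
of DW variance through the fixed effect alone and ~75–80% once genotype
identity is added; genotype DW rankings are strongly concordant across
CO2 levels (rho ≈ 0.8); and a noiseless FvCB curve is inverted exactly.
`run_full_pipeline(config, seed, out_dir)` chains every stage and writes
Table-style CSV outputs, Newick dendrograms and a provenance log.

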