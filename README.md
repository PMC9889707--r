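# carstim

Stimulation-dose modelling for CAR-T cell manufacturing from cytometry
phenotypes.

## The problem

Autologous CAR-T products manufactured from different patients' T cells —
and from the same cells under different activation strengths — differ widely
in phenotype and killing capacity. During activation, the anti-CD3/anti-CD28
stimulation dose (tunable as mol% biotin on a lipid-coated scaffold, or as a
Dynabead bead:cell ratio, both measurable as pg of antibody per cell) skews
the product toward an activated/exhausted phenotype: PD-1⁺TIM-3⁺
co-expression, CD25/CD137 up-regulation, loss of CD45RA⁺ effector-like
cells, and a rising CD4:CD8 ratio. Patient-derived (ALL/CLL) T cells start
CD8-biased and effector-skewed and tolerate less stimulation than healthy
donor cells before their cytotoxic potential collapses.

`carstim` implements the computational side of this problem for analysts of
cell-manufacturing experiments:

1. **Gating and features.** Threshold gating of single-cell 12-marker
   intensity matrices into subpopulation-frequency feature tables
   (`apply_gating()`, `gate_features()`, `zscore_features()`).
2. **Cytotoxicity assay math.** Percent cytotoxicity from luminescence of
   luciferized target cells,
   `100 × (1 − (sample − max-lysis)/(target-only − max-lysis))`, and E:T
   dose-response curves (`percent_cytotoxicity()`, `build_curve()`).
3. **Single-cell cytotoxicity attribution.** Every CD8⁺ event inherits its
   product's observed % cytotoxicity (taken at the 1.25:1 E:T point);
   k-means clusterings are swept over k ∈ [2, 320]; for each k a random
   forest regresses cluster-mean cytotoxicity on cluster-mean marker
   expression and k is chosen by the highest *out-of-sample* explained
   variance; cluster cytotoxicities are z-scored and thresholded at ±1 SD
   into low / moderate / high cytotoxic phenotypes
   (`attribute_cytotoxicity()`).
4. **Product-phenotype classification.** Products are clustered into k = 5
   broad phenotypes; five classifiers (random forest, MLP, decision tree,
   naive Bayes, nearest neighbours) are grid-search-tuned and tenfold
   cross-validated to predict a product's cluster from the donor's blood
   phenotype plus stimulation dose; forest feature importances and a
   dose-only ablation quantify what drives the mapping
   (`cluster_products()`, `train_classifiers()`, `feature_importance()`,
   `dose_only_ablation()`, `status_classifier()`).
5. **Dose prediction.** A random-forest regression maps
   (blood phenotype, desired product phenotype) → required dose (pg/cell),
   validated donor-by-donor: leave one donor out, predict their dose series,
   score by R² between predicted and actual doses
   (`leave_one_donor_out()`, `predict_dose()`).
6. **Synthetic cohorts.** Because the underlying patient data are not
   public, a fully seeded generator (`generate_cohort()`) emulates the
   study design — 8 healthy + 8 patient donors, doses spanning
   0.02–0.3 mol% (56 healthy / 49 patient products) — with known ground
   truth for every subpopulation fraction, cytotoxic-class mixture and
   dose-response law, so every stage is testable end to end.

## Worked example

```r
library(carstim)

cfg    <- generation_config(n_healthy = 4, n_patient = 4,
                            n_events_per_sample = 2000, seed = 8)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic CAR-T cohort: 8 donors (4 healthy, 4 patient)
#>   healthy: 4 blood samples, 28 products
#>   patient: 4 blood samples, 25 products
#>   2000 events/sample, seed 8

## attribute product-level killing to single-cell phenotypes (patients)
cy  <- product_cytotox(cohort, et_ratio = 1.25)
pid <- cohort$metadata$sample_id[cohort$metadata$stage == "product" &
                                 cohort$metadata$status == "patient"]
attribute_cytotoxicity(cohort$samples[pid], cy[pid],
                       attribution_config(seed = 8))
#> Single-cell cytotoxicity attribution (CD8 compartment, 5000 events)
#>   selected k = 20 (explained variance 0.883)
#>   clusters: high = 3, low = 5, moderate = 12

## leave-one-donor-out dose prediction
ft <- cohort_features(cohort)
pf <- ft[ft$stage == "product" & ft$status == "patient" &
         ft$stim_type == "APC-ms", ]
bf <- ft[ft$stage == "blood" & ft$status == "patient", ]
frame <- dose_model_frame(zscore_features(bf), zscore_features(pf))
leave_one_donor_out(frame, seed = 8)
#> Leave-one-donor-out dose prediction (4 donors)
#>  donor_id n r_squared
#>       PT1 6     0.991
#>       PT2 6     0.985
#>       PT3 6     0.976
#>       PT4 6     0.983
#> Cross-donor mean R^2: 0.984 (98.4%)
```

The attribution output says that among 20 phenotype clusters of patient
CD8⁺ CAR-T events, 3 clusters sit ≥ 1 SD above the mean cluster-level
cytotoxicity ("high"), and the forest regression explains 88% of
cluster-level cytotoxicity variance out of sample. The dose-prediction
report lists, per held-out donor, the R² between predicted and actual
pg/cell doses over that donor's six dose levels; on synthetic cohorts the
planted phenotype→dose signal is strong, so R² is near 1.

A command-line wrapper over the same pipeline lives at
`inst/cli/carstim.R` (`simulate`/`gate`/`assay`/`attribute`/`classify`/
`predict` stages; `--seed`, `--out-dir`, `--stratum` flags).

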