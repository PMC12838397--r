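# pathqc

Predicting biospecimen quality from H&E histology images.

Biobanks grade stored tissue with two metrics: the **RNA Integrity Number**
(RIN, 1–10, measured by capillary electrophoresis — destructive and costly)
and the **autolysis score** (ordinal 0–3, assigned by expert pathologists —
slow and subjective). Both forms of degradation leave morphological traces
in routine H&E-stained slides. `pathqc` is for biobank informaticians and
computational pathology researchers who want to estimate both metrics
non-destructively from slide images, and to audit when those estimates can
be trusted.

## What it computes

For each slide *s*, background is removed by Sobel edge detection, stain
appearance is normalized by Macenko's method, and the slide is cut into
512×512 patches (patches over 50% background are dropped; slides with fewer
than 2 valid patches are excluded). A pluggable encoder maps each patch *p*
to a feature vector **z**_sp ∈ ℝ^d, and the slide embedding concatenates
four element-wise statistics over patches:

    x_s = [ mean_p(z_sp) | std_p(z_sp) | min_p(z_sp) | max_p(z_sp) ]  ∈ ℝ^{4d}

Per tissue, quality models are lasso regressions

    β* = argmin_β  1/(2N) ‖y − Xβ‖₂² + λ‖β‖₁

on z-scored embeddings screened to the top 5% of features by |Pearson r|
with the target; λ is chosen at minimum mean held-out MSE on a 100-value
log grid (λ_max down to λ_max·10⁻⁴) under 5-fold CV. A pan-tissue wrapper
first classifies tissue type (multinomial lasso on the top-500 ANOVA-F
features) and routes each slide to its tissue's models when the classifier's
confidence is ≥ 0.6. Diagnostics include covariate variance decomposition,
per-tissue Spearman coupling of RIN and autolysis, feature-sharing
heatmap inputs, fold-stability CV = σ/μ (stable < 0.2, unstable > 0.5), and
preservation-percentile robustness curves.

A deterministic image-statistics encoder and a synthetic-data generator
(stain-mixed tiles with ground-truth masks; embedding cohorts with planted
linear signal) make the entire pipeline runnable and testable offline.

## Worked example

```r
library(pathqc)

# a synthetic cohort: 3 tissues x 150 slides, 64-dim patch features
spec <- synthetic_spec(n_tissues = 3, slides_per_tissue = 150, d = 64, seed = 7)
ds <- generate_embedding_dataset(spec)

# tissue-specific RIN model, 5-fold cross-validation
liver <- ds$manifest[ds$manifest$tissue == "tissue_A", ]
cv <- cross_validate_tissue(liver, ds$X, "rin", n_folds = 5, seed = 7)
sprintf("pooled CV Pearson R = %.3f, RMSE = %.3f", cv$pooled_r, cv$pooled_rmse)
#> "pooled CV Pearson R = 0.746, RMSE = 0.990"

# is that performance stable across folds?
stability_cv(cv$fold_r)$label   # CV = 0.101
#> "stable"

# pan-tissue: classify tissue, then route to per-tissue quality models
split <- stratified_split(ds$manifest, test_fraction = 0.3, seed = 7)
pan <- fit_pan_tissue(ds$manifest[ds$manifest$slide_id %in% split$train, ],
                      ds$X, seed = 7)
routed <- route_and_predict(ds$X[split$test, ], pan)
report <- evaluate_pan(routed, ds$manifest[ds$manifest$slide_id %in% split$test, ])
sprintf("accuracy = %.3f, coverage = %.3f, RIN R = %.3f",
        report$accuracy, report$coverage, report$rin_r)
#> "accuracy = 1.000, coverage = 1.000, RIN R = 0.812"
```

The pooled CV R of 0.746 says held-out RIN predictions track the observed
scores closely on this synthetic tissue; the fold-stability label confirms
the five folds agree (CV of fold correlations ≈ 0.10). In the pan-tissue
run, the classifier routes every test slide to the right tissue at full
coverage, and routed RIN predictions reach R ≈ 0.81.

A command-line interface wraps the same functions:

```sh
pathqc simulate embeddings --out sim/ --seed 7
pathqc train --embeddings sim/embeddings.tsv --manifest sim/manifest.tsv \
             --target rin --tissue tissue_A --seed 7 --out model/
pathqc pan-train --embeddings sim/embeddings.tsv --manifest sim/manifest.tsv --out pan/
pathqc pan-predict --model pan/ --embeddings sim/embeddings.tsv --out routed.tsv
```

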