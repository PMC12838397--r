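---
title: "pathqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biobanks need to know whether a stored tissue specimen is still usable for
molecular work. The two standard quality metrics — the RNA Integrity Number
(RIN, a 1–10 capillary-electrophoresis score of RNA degradation) and the
histological autolysis score (ordinal 0 = none to 3 = severe) — are costly to
obtain: RIN consumes tissue in a destructive assay, and autolysis scoring
requires expert pathologist review. Both kinds of degradation, however, leave
morphological traces in routine H&E-stained slides. `pathqc` implements a
pipeline that predicts both metrics directly from slide images, plus the
diagnostic analyses needed to judge when such predictions can be trusted.

## The pipeline

**1. Preprocessing.** A slide raster is masked with Sobel edge detection on
the luminance channel: tissue is texture-rich, background is flat. The
gradient image is thresholded (Otsu's method by default, or an explicit
`gradient_threshold`), closed with a 3×3 box brush, hole-filled, and cleaned
of connected components under 64 px. Hole filling is not part of the minimal
"edge detection" recipe but is necessary for solid tissue regions: without
it, only boundary contours are masked and a filled region of area *A* would
be scored as a few percent tissue instead of ≈ *A*. Stain appearance is then
normalized by Macenko's method (below), and the slide is cut into
non-overlapping `patch_size` = 512 px tiles anchored at pixel (0,0); partial
edge tiles are dropped, patches with more than 50% background are excluded
(the boundary, exactly 50% tissue, is retained), and slides with fewer than
2 valid patches are excluded entirely.

**2. Macenko stain normalization.** Stain mixing is modelled in optical
density, OD = −log10((I+1)/256), where the Beer–Lambert law makes absorption
linear in stain concentration. Pixels with OD norm above `od_threshold` =
0.15 are projected onto the top-2 right-singular plane of their OD tuples;
the directions at the 1st and 99th percentile of the projection angle are the
two stain vectors. We identify hematoxylin as the vector with the larger
red-channel OD — hematoxylin transmits blue and absorbs red, so its red OD
exceeds eosin's; this matches the canonical Macenko implementations.
Concentrations are recovered with a clipped pseudo-inverse, rescaled so each
stain's 99th-percentile concentration matches the target profile, and
re-rendered through the target stain matrix. A reference profile
(H = (0.563, 0.720, 0.406), E = (0.216, 0.801, 0.558), maxima (1.97, 1.03))
ships as a constant so normalization needs no reference image.

Two numerical points. First, the high-OD filter uses the *Euclidean norm* of
the OD vector rather than a per-channel rule: per-channel filters retain
different pixel subsets under different stain bases, which breaks the
invariant that two images sharing a concentration field should normalize to
near-identical outputs. Second, a single-stain image leaves the OD cloud
effectively rank-1 and the stain plane undefined; we raise an error rather
than fabricate a second vector. The rank test uses a relative tolerance of
5×10⁻³ on the second singular value because 8-bit quantization alone keeps
it near 2.5×10⁻³ of the first even for a mathematically rank-1 image.

**3. Patch encoding and slide embedding.** Patches pass through a pluggable
encoder to d-dimensional feature vectors z. Production use would plug in a
pathology foundation model (d = 1024); the package ships a deterministic
image-statistics encoder (channel means, spreads, deciles, gradient energy,
expanded through a fixed seeded projection) so the full pipeline runs
reproducibly with no external weights. The P patch vectors of a slide are
aggregated element-wise into

x_s = [ mean_p(z_sp) | std_p(z_sp) | min_p(z_sp) | max_p(z_sp) ],

a 4d-length embedding (4096 for d = 1024) capturing central tendency and
within-slide heterogeneity. The standard deviation uses the sample
convention (divisor P−1); P ≥ 2 is guaranteed by the slide filter, so it is
always defined.

**4. Quality models.** Per tissue and per target, features are z-scored
(zero-variance columns dropped), screened to the top 5% by absolute Pearson
correlation with the target, and fit with the lasso

β\* = argmin_β 1/(2N) ‖y − Xβ‖₂² + λ‖β‖₁,

over a 100-value log-spaced grid from λ_max (where all coefficients vanish)
down to λ_max·10⁻⁴. λ_min minimizes mean held-out MSE in 5-fold CV. We pass
the grid to glmnet explicitly: glmnet's internal path stops early once the
deviance plateaus, and the truncated grid would otherwise change which λ is
selected on low-noise data. The headline metric is the Pearson R of
*pooled* cross-validated predictions (one held-out prediction per slide),
not the mean of per-fold Rs; per-fold Rs feed the stability analysis.
Autolysis is modelled by regression on its 0–3 scale and converted to
classes by rounding (ties to even, clipped to [0, 3]) for accuracy.

All fitting decisions — standardization, screening, λ — are refit inside
each outer fold on its training portion only. Whether the original
analysis refit the z-scoring per fold is ambiguous; refitting is the
leak-free choice and is what the tests enforce (perturbing held-out labels
must leave that fold's predictions bit-identical).

**5. Pan-tissue framework.** On slides with both labels present, a 70:30
train–test split stratified by tissue and RIN quartile (quartile breaks from
the full labeled cohort; strata under 2 members merged into the nearest
quartile of the same tissue) feeds a two-stage model: a multinomial lasso
tissue classifier on the top-500 ANOVA-F features (penalty by stratified
5-fold CV at minimum deviance), then routing to per-tissue RIN/autolysis
models trained on *all* 4d features with fold assignment stratified by RIN
quartiles and autolysis categories respectively. A slide is covered iff its
top-class probability is ≥ 0.6; the boundary is inclusive, which matters only
on measure-zero events. Non-covered slides get no quality prediction unless
`fallback = TRUE` routes them by argmax anyway (flagged). In ANOVA-F
selection, a feature with zero within-group variance but positive
between-group variance is perfectly separating and ranks first; a globally
constant feature has an undefined F and ranks last; remaining ties break by
lower index.

## Analyses

* **Variance decomposition** — for each covariate (tissue, Hardy scale, the
  other quality metric, age, sex) independently, the R² of a univariate
  linear model of the target on that covariate; categorical covariates enter
  as factors. Fractions from independent fits need not sum to 1. Whether
  the fractions should come from univariate or joint models is genuinely
  open; both are implemented (`method = "joint"` uses partial type-II sums
  of squares) with univariate the default.
* **RIN–autolysis coupling** — per-tissue Spearman ρ with average ranks for
  ties and asymptotic two-sided p-values; stars \*\*\* p < 0.001,
  \*\* p < 0.01, \* p < 0.05, ns otherwise. No multiple-testing correction
  is applied; p-values are reported unadjusted.
* **Feature sharing** — a feature's frequency is the number of tissues whose
  model gives it a nonzero coefficient; the global top-20 per target and the
  overlap of the two top-20 sets quantify sharing. The tissue × feature
  matrix is clustered with complete linkage on Euclidean distances, rows and
  columns independently.
* **Fold stability** — CV = σ/μ of per-fold correlations (sample SD). CV
  < 0.2 is stable, > 0.5 unstable, else intermediate; a non-positive mean
  leaves CV undefined and flags the model unstable with a warning.
* **Preservation percentiles** — slides are sorted by observed quality and
  the best-preserved progressively removed: at percentile q, slides at or
  below the q-th percentile of the observed metric are retained and R
  recomputed. q = 100 reproduces the full-sample R exactly; subsets under 5
  slides, or with constant observed values, report NA. Default cutoffs
  100, 90, …, 30.

## The synthetic-data generator

Two generators make every stage testable without downloads.

*Tiles*: white background plus elliptical blobs rendered through the exact
two-stain Beer–Lambert model with known stain vectors and concentration
fields (smooth radial profiles with multiplicative noise). Blob axes are
kept under 1/8 of the tile side so coverage can stop within 0.05 of the
requested tissue fraction. Ground-truth masks and concentration fields are
returned, so masking and stain estimation can be scored against the
construction itself.

*Embeddings*: patch vectors are Gaussian around a tissue signature (per-
coordinate SD = `tissue_signature_separation`, default 3), with each slide's
own latent offset u on the first `n_signal_features` coordinates. RIN is an
affine map of the weighted latent w·u plus a Hardy-scale proxy effect and
Gaussian noise (default SD 0.5× the signal SD), clipped to [1, 10] and
centred so most slides land between 5 and 8. Autolysis discretizes a
negatively coupled latent (−w·u plus noise) at its 50/80/95th percentiles,
placing most mass at scores 0–1 and making Spearman(RIN, autolysis) negative
by construction. Defaults: 5 tissues × 100 slides, d = 64, 8–16 patches per
slide, patch SD 1.

What this emulates: the statistical shape the pipeline assumes — tissue-
specific feature signatures, a sparse linear morphology–quality link, a
pre-analytical confounder, anti-correlated quality metrics, label
missingness. What it does not: real histological texture, encoder geometry,
donor structure (each synthetic slide is its own donor), heteroscedastic or
tissue-dependent noise, and any nonlinearity in the morphology–quality
relationship. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted signal, not performance on real
cohorts.

## Problem sizes

The test suite and the acceptance script run the quality models at n = 500
slides, d = 64 (256 embedding features), 5 planted signal features and noise
0.5× signal SD, where pooled CV R ≥ 0.8 is comfortably reproducible across
seeds; and the pan-tissue framework at 5 tissues × 200 slides, where tissue
signatures separated at 3 SD make classification essentially perfect,
coverage ≈ 1 at threshold 0.6, and routed predictions match oracle (true-
tissue) routing. These sizes were chosen as the smallest at which the
planted-signal recovery bounds are stable, and they keep the whole suite
under a minute.

## Known limitations

* The Sobel mask scores the visibly stained core of a region; faintly
  stained rims that fade into background may fall below the Otsu threshold,
  so edge-based tissue fractions are conservative relative to ground truth.
* Macenko estimation needs both stains present (≥ 100 high-OD pixels and a
  rank-2 OD cloud); monochrome or nearly unstained inputs error and the
  caller must fall back to the shipped reference profile.
* Stain normalization is per-slide by default (one source profile per
  slide); per-patch profiles are possible via the API but not the default,
  as patch-level estimation is noisier.
* The quality models are linear in the embedding; they inherit the lasso's
  behavior under correlated features (one of a correlated group is
  selected).
* Routing errors cannot be diagnosed when the tissue classifier is
  confidently wrong; coverage only gates on confidence, not correctness.
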