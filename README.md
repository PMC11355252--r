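# octmh

Morphometry-based prognosis of postoperative visual acuity in macular hole
surgery, from colour-annotated OCT layer masks and preoperative clinical
records.

## The problem

After vitrectomy for an idiopathic macular hole, anatomic closure is the
rule but the visual outcome is not: some eyes recover driving-level acuity,
others do not, and patients want to know before consenting. `octmh`
implements an interpretable machine-learning pipeline for that question. An
eye is labelled **Group A** (good prognosis) if its 6-month decimal
best-corrected visual acuity (BCVA) is ≥ 0.7 — equivalently ≤ 0.15 logMAR,
since logMAR = −log₁₀(decimal) — and **Group B** (poor prognosis) otherwise.
The classifier is an L2-penalised logistic regression

  P(poor) = logistic(β₀ + Σⱼ βⱼ zⱼ),  zⱼ = (xⱼ − x̄ⱼ)/sⱼ,

fit on z-scored explanatory variables (so the βⱼ are standard regression
coefficients, directly comparable as contribution measures), with:

- **features**: 41 per patient — 11 background variables plus handcrafted
  OCT morphometry from a 256×256 annotated mask (boundary defect lengths
  OPL-DL / ELM-DL / EZ-DL, per-band shortest defect lengths, minimum linear
  diameter `Hole-min`, base diameter `BDM`, band areas, and 16
  difference/ratio combinations such as `(OPL-DL) − (ONL-DL)` that quantify
  hole stenosis);
- **selection**: Kolmogorov–Smirnov / Fisher's exact screening at α = 0.05,
  then iterative elimination of any candidate whose auxiliary-regression
  R² > 0.9 (VIF > 10);
- **tuning**: the penalty constant c ∈ {0.001, …, 100} fixed at its modal
  value over 100 cross-validated pre-tests;
- **alignment**: the decision threshold chosen so precision ≥ recall (a
  deliberately high-precision, lower-recall operating point: a poor-prognosis
  call should rarely be wrong);
- **evaluation**: 100 repeats of stratified 5-fold cross-validation, each
  repeat pooling its test folds into one ROC/confusion matrix; metrics
  reported as mean ± SD with 95% t-intervals.

Because the original patient data are private, the package includes a
first-class synthetic-data module: a cohort sampler calibrated to the
published per-group means/SDs (with within-group correlations recovered from
the printed difference-feature SDs via Var(X−Y) = Var(X)+Var(Y)−2ρσₓσᵧ) and
a parametric macular-hole mask renderer with known ground-truth morphometry.
See the methods vignette (`vignettes/methods.Rmd`) for the model,
assumptions and numerical choices.

## Worked example

```r
library(octmh)

# a 43-patient synthetic cohort (32 good / 11 poor) at the study calibration
tab <- sample_feature_table(generator_config(seed = 1))

# selection -> hyperparameter fixing -> repeated stratified CV
res <- run_analysis(tab, pipeline_config(seed = 1))
res$selection
#> mh_selection: 16 candidate(s) -> 11 explanatory variable(s)
#>   iteration 1: max R^2 1.000, dropped BDM - (Hole-min)
#>   ...
#>   iteration 5: max R^2 0.981, dropped ELM-DL
#>   iteration 6: max R^2 0.865 (stop)
#>   final: Preoperative BCVA, Stage, BDM, Hole-min, ONL-DL, Sky blue-sDL, ...
res$tuning$c_star
#> [1] 0.1
res$report
#> mh_cv_report: 100 repeats of stratified 5-fold CV, c = 0.1
#>   accuracy  0.947 +/- 0.023  (95% CI 0.942~0.952)
#>   precision 0.938 +/- 0.071  (95% CI 0.924~0.952)
#>   recall    0.855 +/- 0.052  (95% CI 0.844~0.865)
#>   f_measure 0.892 +/- 0.045  (95% CI 0.883~0.901)
#>   auc       0.985 +/- 0.006  (95% CI 0.984~0.987)
```

Reading the output: on this particular cohort the screen found 16
significant candidates; the collinearity loop first removed the exactly
redundant difference features (R² = 1), then the ELM defect length; the
pre-tests fixed a strong penalty (c = 0.1); and the cross-validated report
shows the precision-favouring alignment at work (mean precision 0.938 above
mean recall 0.855). Single cohorts vary — the headline reconstruction below
averages over 20 of them. Mask morphometry works the same way on rendered or
real annotation masks:

```r
out <- render_synthetic_mask(random_mask_geometry(seed = 2))
f <- extract_mask_features(out$mask)
#> OPL-DL 628.1 um (truth 628.1), Hole-min 252.8 um (truth 252.8)
rec <- compose_features(f, clinical_record)   # -> the 41-feature row
```

End-to-end runs with file artifacts (selection, model bundle, CV report,
manifest, all JSON) go through `run_pipeline()`, driven by an R list or a
YAML configuration.

## Scope

The package starts from the annotation mask: it does not segment raw OCT
B-scans, and hole-height indices (MHI/THI) are out of scope. The renderer
emulates annotation geometry, not OCT speckle. See the methods vignette for
known limitations of the Gaussian cohort emulation.
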