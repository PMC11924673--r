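# myotexture

Radiomic texture analysis of cardiac MRI **native T1 maps** for
contrast-free assessment of **late gadolinium enhancement (LGE)** status,
aimed at Duchenne muscular dystrophy (DMD) cardiomyopathy screening. LGE
imaging requires a gadolinium-based contrast agent; repeated yearly
injections in children motivate predicting LGE status from the native
(pre-contrast) T1 map alone. This package implements the full analysis as
a tested, reusable R pipeline, driven by a synthetic T1-map generator so
every stage runs and is verifiable without patient data.

## What the pipeline does

1. **Image preparation** — rasterizes endo/epicardial contours into an
   annular myocardial mask (even-odd rule at pixel centres), resamples
   image and mask to 1.17 × 1.17 mm, clips in-mask intensities to
   µ ± 3σ, and discretizes to Ng = 32 gray levels.
2. **Filter bank** — gradient magnitude, square, LBP(8,1), LBP(8,2)
   (rotation-invariant uniform coding), and the four single-level
   stationary Coiflet-1 wavelet sub-bands (LL, LH, HL, HH); with the
   original image, nine shape-preserving variants.
3. **Texture features** — per variant: 9 shape-2D, 18 first-order,
   24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM = 102 features, hence
   **918 features per case**. Headline features have explicit formulas,
   e.g. IDMN = Σᵢⱼ p(i,j) / (1 + (i−j)²/Ng²) and
   zone% = N_zones / N_pixels.
4. **Reproducibility gate** — two readers × repeated contouring; per
   feature the consistency ICC (two-way model,
   ICC(C,1) = (MSR − MSE)/(MSR + (k−1)MSE)) and the coefficient of
   variation (sd/|mean|); features pass with intra- and inter-observer
   ICC ≥ 0.75 and CV ≤ 10%.
5. **Feature selection** — stratified 67/33 split with class balancing,
   then Boruta (shadow-feature random-forest search) and LASSO logistic
   regression (5-fold CV, λ_min) independently; hierarchical clustering
   on 1 − |Spearman ρ| decorrelates the union; VIF < 5 is verified.
6. **Classification** — per-feature univariate logistic models (z-scored
   on training data only), 10-fold cross-validation, AIC ranking, and a
   held-out metric panel: accuracy with exact Clopper–Pearson 95% CI,
   balanced accuracy, Cohen's κ, F1, and AUC with DeLong CI; plus a
   Gini-optimal decision-stump threshold on the best feature.
7. **Longitudinal model** — a random-intercept logistic mixed model,
   logit P(LGE) = β₀ + β₁·feature + u_patient, u ~ N(0, σ²), fitted by
   maximum likelihood with the Laplace approximation (implemented
   in-package; cross-checked against adaptive Gauss–Hermite quadrature
   and lme4 in the tests).

The synthetic generator produces annular T1 maps whose myocardium is a
class-mean T1 field (≈1032 ms LGE− / 1044 ms LGE+) plus a stationary
Gaussian random field with class-specific correlation length, focal
high-T1 lesion patches in LGE+ cases, reader-perturbed contours for the
ICC study, and longitudinal cohorts with monotone LGE progression.

## Worked example

```r
library(myotexture)

cfg <- pipeline_config(seed = 1L)          # 23 LGE+ / 19 LGE- cohort
res <- run_pipeline(cfg, outdir = "run1")
```

The run log prints each stage (numbers from this configuration):

```
simulate     15 gate + 42 cohort + 45 longitudinal cases (3.1 s)
extract      918 features x 42 cases (32.6 s)
gate         239 of 918 features reproducible (0.6 s)
select       boruta 113, lasso 9, union 113, independent 3 (4.8 s)
model        best by AIC: lbp_8_1__glcm__id (accuracy 0.929) (0.4 s)
longitudinal lbp_8_1__glcm__id: estimate 30.00 (26.3), p = 0.255 (11.9 s)
```

Reading the output: 918 features were extracted per case; 239 survived
the ICC/CV gate; the split left 24 balanced training and 14 balanced
testing cases; three decorrelated features remained, and the best model
by AIC (a GLCM homogeneity feature on the LBP(8,1) variant) classified
the held-out cases with accuracy 0.929. The longitudinal slope sits at
the optimizer's box bound with a large SE — the generated feature
separates the pooled outcomes completely, so the slope is unbounded and
the fit is flagged (`separated = TRUE` in `longitudinal_fit.json`);
class-conditional texture contrasts of this synthetic scale (Cohen's
d ≈ 2) make that expected. `run1/` contains every artifact: config echo,
manifests, `features.csv`, `gate_report.csv`, `selection.json`,
`model_metrics.json`, `longitudinal_fit.json`, and timings.

Lower-level entry points are exported too: `extract_features()`,
`icc_consistency()`, `boruta_select()`, `lasso_select()`,
`fit_glmm_logistic()`, `compare_groups()`, `required_sample_size()`, …
— see the help pages and the methods vignette
(`vignettes/methods.Rmd`).

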