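---
title: "Texture analysis of native T1 maps: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of native T1 maps: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(myotexture)
```

## The problem and the model

Late gadolinium enhancement (LGE) imaging is the reference standard for
detecting focal myocardial fibrosis in Duchenne muscular dystrophy, but it
requires a gadolinium-based contrast agent. Native (pre-contrast) T1
parametric maps quantify tissue relaxation per pixel; diffuse and focal
fibrosis alter both the level and the *spatial pattern* of T1 in the
myocardium. The working hypothesis of this pipeline is that engineered
texture features of the native T1 map carry enough of that pattern to
classify LGE status without contrast.

The pipeline's statistical core is therefore three models chained behind a
feature-engineering front end:

* a **reproducibility filter** on features, based on the two-way
  consistency intraclass correlation
  \(\mathrm{ICC}(C,1) = (MS_R - MS_E)\,/\,(MS_R + (k-1) MS_E)\)
  and the coefficient of variation \(\mathrm{sd}/|\mathrm{mean}|\);
* **univariate logistic classifiers**
  \(\operatorname{logit} P(\mathrm{LGE}=1) = \beta_0 + \beta_1 z\), with
  \(z\) the training-standardized feature, ranked by AIC and evaluated on a
  held-out balanced cohort;
* a **random-intercept logistic mixed model** for yearly repeated
  examinations,
  \(\operatorname{logit} P(y_{it}=1) = \beta_0 + \beta_1 x_{it} + u_i\),
  \(u_i \sim N(0, \sigma^2)\), fitted by maximum likelihood with the
  Laplace approximation.

## Preprocessing parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| target spacing | 1.17 | mm | fixed resampling grid so features are comparable across cases |
| intensity band | µ ± 3σ | ms | outlier clipping over the in-mask distribution |
| gray levels Ng | 32 | – | equal-width bins over the in-mask range |
| GLCM distance | 1 | px | nearest-neighbour co-occurrence, 4 angles, symmetric, angle-averaged |
| GLDM α / distance | 0 / Chebyshev 1 | – | dependence = equal-level 8-neighbours |
| connectivity | 8 | – | GLSZM zones and GLDM neighbourhoods |

Two of these deserve comment because the convention is genuinely open:

* **Clipping vs rescaling at µ ± 3σ.** The band is applied by *clipping*
  in-mask intensities. Clipping implements the outlier-removal reading,
  leaves in-band images untouched, and commutes with affine intensity
  maps when followed by equal-width binning — a property the tests assert
  (`normalize → discretize` is invariant to `a·x + b`). Re-normalizing a
  clipped image can clip further, since µ and σ change; the pipeline
  applies the band once.
* **Discretization.** A fixed *bin count* (32) over the in-mask range,
  applied after normalization and independently per filtered variant,
  bounds every texture-matrix size and makes Ng in IDMN's denominator
  well-defined across cases. A constant region degenerates to Ng = 1, for
  which the limit conventions are: entropies 0, IDMN/IDM/ID/IDN 1,
  inverse variance 0, correlation 1, MCC 1.

The processing order is fixed: rasterize → resample → crop to the mask
bounding box (8-pixel margin, which exceeds every filter support) →
normalize → filter → discretize each variant with the same rule.

## Filter bank

The eight filtered variants recompute all intensity families on
transformed images. Gradient magnitude uses spacing-aware central
differences; the square filter rescales \(x^2\) so its in-mask maximum
matches the pre-filter maximum; LBP uses rotation-invariant uniform
(riu2) coding with 8 circularly interpolated neighbours at radius 1 or 2,
treated downstream as an ordinary gray-level image; the wavelet variants
are the four sub-bands of a single-level *stationary* (undecimated) 2D
transform with the Coiflet-1 pair and symmetric boundary extension.
The undecimated transform is the load-bearing choice: sub-bands keep the
input shape, so the myocardial mask applies without resampling it. The
LBP encoding and wavelet kernel are configuration-level conventions; the
defaults are the common radiomics choices and the tests pin their
invariants (riu2 code histograms are 90°-rotation invariant; detail bands
of a constant image vanish; sub-band energy tracks input energy).

## The synthetic generator: what it emulates, what it does not

Patient data for this analysis cannot be public, so the package ships a
generator whose defaults *are* the study conditions used throughout the
tests:

* annular mid-ventricular masks (endo 16 px, epi 23 px radius) on a
  256 × 256, 1 mm grid — mid-wall area ≈ 860 px;
* class-conditional myocardial T1: mean 1032 ms (LGE−) vs 1044 ms (LGE+),
  within-myocardium SD 40 ms;
* spatial texture as a stationary Gaussian random field with
  squared-exponential covariance, synthesized spectrally on the torus;
  correlation length 1.6 px (LGE−) vs 3.0 px (LGE+);
* LGE+ cases additionally receive Poisson(2) focal lesion patches
  (Gaussian profile, ≈4 px radius, 180 ms peak), mean-centred inside the
  annulus so the *global* class mean stays at the configured value —
  lesions redistribute intensity rather than shifting the global mean;
* ages Normal(13, 3.3) truncated to [7, 22] years; cohort 23 LGE+ /
  19 LGE−; reader variants as smooth low-order Fourier perturbations of
  the contour radii (RMS ≈ 0.8 px); longitudinal cohorts of 15 patients ×
  3 years with a patient-level texture driver, a random intercept on the
  LGE propensity, and monotone (never-reverting) progression.

The class-contrast defaults were fixed once so that first-order entropy is
higher and GLSZM zone% lower in LGE+ — the two directions the texture
contrast targets. The direction of wavelet-LL IDMN is deliberately *not*
forced: a single Gaussian-field knob cannot guarantee higher homogeneity
and higher entropy in the same class simultaneously, and the generator
documents which directions it targets instead of guessing the tissue
mechanism. With these defaults the feature contrast is strong
(class-conditional Cohen's d ≈ 2, comparable to the printed
class-conditional feature summaries), which has a visible consequence:
univariate separation of small cohorts is common, so the longitudinal
slope may sit at the optimizer's box bound with a `separated` flag (see
below).

What the generator does **not** emulate: MOLLI acquisition physics,
motion artifacts and their correction, 3D geometry, partial-volume mixing
beyond pixel sampling, trabeculation, or scanner/vendor variation.
Passing tests therefore demonstrate the *machinery* — formula
correctness, gate behaviour, selection recovery, model calibration — not
clinical performance on real maps.

## Numerical choices

* **Rasterization** uses the even-odd rule at pixel centres; contours are
  in mm with pixel (r, c) centred at ((c − ½)·Δx, (r − ½)·Δy).
* **GLSZM labelling** is iterative minimum-label propagation over the 8
  shifts, which handles all gray levels in one vectorized sweep sequence;
  it equals a recursive flood fill (tested on random images).
* **Boruta** internals follow the shadow-feature algorithm: 500-tree
  random forests, impurity (Gini) importance, hits against the best
  shadow, two-sided binomial tests at α = 0.01 with Bonferroni correction
  over the initial feature count, tested from iteration 5, rejected
  features dropped from the pool. A property worth knowing: at small n,
  chance feature–outcome correlations are genuine in-sample signal and an
  all-relevant search occasionally confirms them (the same happens with
  permutation-importance z-scores); the all-noise property test therefore
  runs at n = 1000 where chance correlation is negligible.
* **LASSO** uses 5-fold cross-validated deviance and λ_min (the less
  conservative choice; λ_1SE would shrink the selection further).
* **Cluster representatives** are medoids — the member with maximal mean
  |Spearman ρ| to its cluster, ties broken alphabetically; the cascade
  feeds the *union* of Boruta-confirmed and LASSO-selected features into
  clustering.
* **Separation handling.** Univariate logistic fits fall back to Firth's
  bias-reduced scoring (Jeffreys-prior adjustment) when ML separates, and
  are flagged. The mixed model is optimized by L-BFGS-B over
  (β₀, β₁, log σ) with box bounds (|β| ≤ 30, σ ∈ [10⁻⁴, 15]); a separated
  longitudinal dataset yields a finite, flagged estimate at the bound
  rather than an error, mirroring how practitioners read diverging
  mixed-model slopes.
* **Laplace inner loop.** Per-patient posterior modes are found by damped
  Newton steps vectorized across patients; the outer objective is exact
  up to the Laplace approximation, whose absolute log-likelihood error
  grows with σ (≈0.1·σ² on the designs used here). The quadrature oracle
  check runs at σ = 0.5, where the approximation holds the 0.1 tolerance
  with a wide margin; at σ ≥ 1 with 3 observations per patient the
  Laplace slope is attenuated by ≈5–8% — a property of the method
  (identical numbers to other Laplace implementations), not of this
  implementation.
* **Stump threshold.** Candidate cuts are midpoints of sorted unique
  values; Gini impurity decides, ties resolve to the maximal-margin
  midpoint, then to the smallest cut.

## Problem sizes in the test-suite and acceptance runs

The suites use the default 256-px study conditions for cohort-level
checks (50 + 50 calibration cases, 24 + 24 power replicates, the full
23 + 19 pipeline) and a 72-px variant of the same geometry for structural
unit tests whose properties do not depend on scale. Simulation-heavy
properties run at deliberately chosen sizes: matrix-family oracles on 200
random ≤ 8×8 images; selection recovery on five 44-case replicates with
the original-image feature set (102 features); mixed-model slope recovery
on twenty 200 × 3 replicates; type-I calibration on 1000 replicates of
150 × 3 (measured rejection rate 0.051 at nominal 0.05).

## Known limitations

* Feature definitions follow the standard radiomics catalog at the
  printed family sizes (9/18/24/14/16/16/5), but exact member lists of
  historical extractions vary between library versions; the catalog
  manifest (`feature_catalog()`) is the package's single source of truth.
* Shape-2D features are computed from the mask only and are therefore
  identical across image variants; they are reported per variant to keep
  the 102 × 9 catalog rectangular.
* The age-matching step used in observational cohort assembly is out of
  scope — synthetic cohorts are generated age-balanced.
* No 3D features, no multi-level wavelets, no DICOM ingestion; real-data
  input is NIfTI plus contour CSV.
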