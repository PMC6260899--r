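---
title: "Methods: multi-exponential and tensor modelling of renal DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-exponential and tensor modelling of renal DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renaldwi)
```

## The models and their assumptions

The diffusion-weighted signal of renal tissue is modelled at four levels of
complexity. The mono-exponential model `S(b) = S0 exp(-b D_mono)` captures a
single apparent diffusivity. The bi-exponential (IVIM) model adds a
pseudo-diffusion compartment for capillary blood: a fraction `f_star`
decaying at `D_star`, with the remainder decaying at the tissue diffusivity
`D_bi`. The kidney additionally contains water moving at an intermediate
rate — on the order of free water, attributed to tubular flow and the
collecting system — which motivates the tri-exponential model with fractions
`f_fast` (perfusion), `f_interm` (free-water-scale) and the derived
`f_slow = 1 - f_fast - f_interm` at the slow tissue diffusivity `D_tri`.
The diffusion tensor model captures anisotropy, summarized by the rotational
invariants MD (trace/3) and FA.

All models share three assumptions worth stating: (i) compartments are in
slow exchange over the diffusion time, so signals add; (ii) scalar decay
models apply to the direction-averaged signal, which is exact for isotropic
compartments and an approximation otherwise; (iii) input volumes are already
motion-corrected and registered — no resampling or reorientation policy is
defined here, and the NIfTI affine is carried through untouched.

## Parameters, units, defaults

Diffusivities are stored and reported in 1e-3 mm^2/s and b-values in s/mm^2;
the model code multiplies by 1e-3 so `b * D` is dimensionless. Fractions are
proportions internally and percent in tables, matching the reporting
convention of the clinical literature.

The fast and intermediate pseudo-diffusion coefficients of the
tri-exponential model are not identifiable from the 10-b-value protocol with
realistic noise, and published parameter tables for this analysis do not
report them numerically. The package therefore fixes, by default,

* `D_fast = D_star = 50` (perfusion regime),
* `D_interm = 6` (order of magnitude of free water),

both configurable via `fit_config()` and `pseudo_diffusion_defaults()`. The
phantom generator and the fitters share these defaults, so recovery tests
are self-consistent: a green recovery test establishes that the estimator
inverts the forward model, not that 50 and 6 are biophysically exact.

Default fit bounds encode the compartment ordering: `D_mono`, `D_bi`,
`D_tri` in [0, 4]; `D_interm` in [3, 15]; `D_fast`, `D_star` in [15, 500]
(all 1e-3 mm^2/s); fractions in [0, 1]. The fraction-sum constraint
`f_fast + f_interm <= 1` is enforced by reparameterization: the optimizer
works on `u = f_interm / (1 - f_fast)` in [0, 1], so every iterate inside
the box is feasible. (Whether the original analysis constrained the sum
explicitly or via reparameterization is not documented; reparameterization
is this package's choice.)

## Estimators and numerical choices

**Mono-exponential.** Weighted linear least squares on the log signal with
weights `S^2`, the standard first-order correction for the noise distortion
of the log transform. Exact on noise-free data; `D` clipped into bounds.

**Tensor.** Iterative WLLS on the log signal. The first pass is unweighted:
starting from observed-signal weights would let a corrupted measurement with
a large signal dominate the fit through its squared weight and mask itself.
Subsequent passes use weights equal to the squared predicted signal.
Outlier rejection recomputes, each iteration, robust z-scores (median/MAD
scale) of the predicted-signal-weighted log residuals over *all* usable
measurements and keeps those with |z| <= 3; rebuilding the keep set from
scratch lets measurements wrongly rejected under an early, still-biased
estimate re-enter. When the residual scale is numerically zero (perfect
fit), membership is judged by absolute residual instead. The loop stops when
the keep set is stable and the coefficient change is below tolerance, or
after 10 iterations; fewer than 7 usable measurements is a flagged failure,
never silent. Negative eigenvalues of the fitted tensor are clipped to zero
before it is returned, guaranteeing FA in [0, 1]. This rejection rule is a
simple, testable surrogate for the robust estimation used by DTI processing
suites, not a re-implementation of any of them.

**Bi-/tri-exponential.** Bound-constrained nonlinear least squares
(`optim` L-BFGS-B, tight `factr`/`pgtol`), with one restart from the
solution, which costs little and tightens noise-free recovery. A restart
that cannot improve the objective at machine precision counts as converged
(L-BFGS-B reports an abnormal line search in that state). Initialization is
cascaded: a mono fit on the high-b tail (b >= 200) seeds the tissue
diffusivity and tissue-only intercept; the gap between the measured b = 0
signal and that intercept seeds the pseudo-diffusion fraction; the
tri-exponential fit additionally seeds from the bi-exponential solution. A
flat (midpoint-of-bounds) initializer is exposed for robustness testing.
In fixed mode the slow coefficient is additionally capped just below
`D_interm` so the compartment ordering can never invert.

**Direction handling.** Scalar decay fits consume the geometric mean of the
signal across directions per b-value (`exp(mean(log S))`), which for a
tensor compartment equals the decay of the mean diffusivity; arithmetic
averaging is available, and non-positive signals trigger a per-voxel
fallback to arithmetic averaging with a counted warning.

**Degenerate inputs.** Voxels with non-finite measurements are skipped and
flagged; all-equal b-values are a rank-deficiency error; decay fits require
b = 0 and a shell at >= 500 s/mm^2 so the tissue compartment is actually
constrained.

## The synthetic phantom: what it does and does not emulate

The phantom states the world the analysis assumes. Geometry is nested
boxes/ellipsoids on a 32 x 32 x 8 grid at 3 mm isotropic voxels (the
acquisition's voxel size; the grid size is a desk-scale choice). Each label
carries a published tissue preset: the seven parameters (MD, FA, f_star,
D_bi, f_fast, f_interm, D_tri) for healthy cortex, healthy medulla, cysts,
grouped and individual RCC subtypes, haemangioma and oncocytoma. Two 4D
datasets are emitted per phantom, mirroring the two acquisitions: the
10-b-value, 6-direction protocol generated from the tri-exponential presets,
and the b = 0/100/300, 15-direction protocol generated from axially
symmetric tensors constructed to match the preset MD and FA exactly (the
tensor eigensystem is otherwise unreported, so the principal direction is a
configurable choice, x by default). Gradient directions are spread
deterministically by electrostatic repulsion with antipodal symmetry.

Noise is Rician: `sqrt((S + n1)^2 + n2^2)` with i.i.d. Gaussian `n1`, `n2`
of standard deviation `sigma = S0 / SNR`. The default SNR of 50 is a
stand-in — the source protocol reports no SNR — chosen as a realistic value
for 3 T abdominal DWI at 3 mm voxels. Cohort sampling draws lesion-level
parameter sets from Gaussians at the published means and SDs, truncated to
the fit bounds so every synthetic lesion is physically valid, with matched
healthy cortex/medulla draws per synthetic patient.

Not emulated: anatomically realistic kidney geometry, breathing motion and
registration error, partial-volume mixing at tissue boundaries, multi-average
b = 0 acquisition (a single averaged b = 0 volume is generated), spatially
varying coil sensitivity. A green recovery test therefore establishes
correctness of the estimators under the stated noise model — it does not
establish that the pipeline is robust to motion or segmentation error, which
are out of scope (label maps are consumed as given).

## ROI analysis

Summaries are computed per voxel, then averaged within each label
(per-voxel-then-average; whether the original ROI means were computed this
way or from a whole-ROI fit is not documented — this is the package's
choice, and the phantom's constant-per-label design makes the two coincide
there). The SD is the sample (n - 1) SD. No ROI erosion is applied by
default: lesion labels are assumed drawn inside the lesion. The merged
fraction map encodes (red, green, blue) = (f_fast, f_slow, f_interm);
channels are clipped to [0, 1] with a counted warning and renormalized where
clipping pushed the sum past 1, so valid voxels always sum to 1.

## Group statistics

The Wilcoxon signed-rank test drops zero differences (Wilcoxon's original
convention) and reports the min-rank-sum statistic. For n <= 12 the
two-sided p-value is exact by full enumeration of all 2^n sign assignments
of the observed mid-ranks (valid under ties); above that, a normal
approximation with continuity correction and tie-corrected variance. The
threshold 12 keeps enumeration (4096 assignments) instantaneous while
covering the cohort sizes this analysis meets.

MANOVA uses Wilks' lambda; in the univariate case the closed-form ANOVA
equivalence `F = (1 - L)/L * (n - k)/(k - 1)` is used directly (and serves
as a cross-check of the multivariate path in the tests). Pairwise group
contrasts per parameter use the pooled within-group error of the one-way
fit, in the style of SPSS post-hoc comparisons. The Bonferroni family is
the 10 group contrasts (a–j) per parameter, mirroring the per-parameter
letter annotation of the published table; the original family definition is
not stated, so this is recorded as an assumption. All tests consume
lesion-level observations (one value per lesion), never voxel-level ones,
and the 5-cyst/13-solid cohort is treated as independent lesions (the
original patient nesting is not recoverable from the publication).

## Known limitations

* The tri-exponential model in free mode is weakly identified on 10
  b-values; fixed mode is the default and the validated configuration.
* The NIfTI-1 reader/writer is minimal (little-endian, no extensions,
  datatypes uint8/int16/int32/float32/float64) — sufficient for the
  pipeline's own files and typical scanner exports, not a general library.
* Rician noise biases magnitude signals upward at low SNR; the estimators
  do not include a noise-floor term, so very high-b, low-signal shells will
  bias diffusivities downward at SNRs well below the default.
* Statistical power claims are validated against the synthetic cohort's
  stated effect sizes only; no claim is made about new clinical data.
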