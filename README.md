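# renaldwi

Quantitative modelling of renal diffusion-weighted MRI (DWI), aimed at the
characterization of kidney lesions (renal cell carcinoma subtypes, cysts,
benign solid lesions) against healthy cortex and medulla.

Diffusion MRI probes water displacement: the signal at diffusion weighting
*b* (s/mm²) decays with the tissue's diffusivity. In renal tissue a single
apparent diffusion coefficient conflates true tissue diffusion with
capillary perfusion and fast tubular flow, so this package implements the
family of models used to separate them, together with the estimators,
phantom simulation and group statistics needed to run and validate the full
analysis:

- **mono-exponential**: S(b) = S₀ e^(−b·D_mono)
- **bi-exponential (IVIM)**: S(b) = S₀ [f\* e^(−b·D\*) + (1 − f\*) e^(−b·D_bi)]
- **tri-exponential**: S(b) = S₀ [f_fast e^(−b·D_fast) + f_interm e^(−b·D_interm) + f_slow e^(−b·D_tri)], with f_slow = 1 − f_fast − f_interm
- **diffusion tensor (DTI)**: S(b, g) = S₀ e^(−b·gᵀDg), with MD = tr(D)/3
  and FA = √(3/2)·√(Σᵢ(λᵢ−MD)² / Σᵢλᵢ²)

Diffusivities are in 10⁻³ mm²/s throughout; signal fractions are stored as
proportions and reported in percent.

Estimators: weighted log-linear least squares for the mono model; iterative
weighted linear least squares with robust outlier rejection for the tensor;
bound-constrained nonlinear least squares with cascaded initialization for
the bi- and tri-exponential models (fixed pseudo-diffusion coefficients by
default: D\* = D_fast = 50, D_interm = 6 ×10⁻³ mm²/s).

A synthetic phantom module generates multi-b-value renal DWI (b = 0, 10, 25,
40, 75, 100, 200, 300, 500, 700 s/mm², six directions) and DTI acquisitions
(b = 0, 100, 300 s/mm², 15 directions) from published per-tissue parameter
presets, corrupted by Rician magnitude noise, so every estimator can be
validated by parameter recovery. Group statistics cover paired Wilcoxon
signed-rank tests (exact by enumeration for small n) and MANOVA (Wilks'
lambda) with Bonferroni-corrected pairwise contrasts.

## Worked example

Generate a noise-free healthy-cortex decay on the 10-b-value protocol and
refit it:

```r
library(renaldwi)
scheme <- paper_scheme("ivim")
b <- sort(unique(scheme$bvalues))
truth <- preset_triexp("healthy_cortex", S0 = 100)
fit <- fit_triexp(predict_triexp(truth, b), b, fit_config("triexp"))
print(fit)
#> Voxel fit (triexp_params), rss = 1.326e-10
#>           S0       f_fast       D_fast     f_interm     D_interm        D_tri
#> 100.00000468   0.04140015  50.00000000   0.28799938   6.00000000   1.41000145
#>       f_slow
#>   0.67060046
```

The fit returns the generating preset: a 4.14% fast (perfusion) fraction, a
28.8% intermediate (free-water-scale) fraction and a slow tissue diffusivity
of 1.41 ×10⁻³ mm²/s, recovered to well under 1%.

Simulate a cohort shaped like the clinical study (13 solid lesions, 5 cysts,
with matched healthy-tissue draws per patient) and run the full contrast
grid (letters a–j: pairwise MANOVA contrasts; x, y, z: paired Wilcoxon):

```r
co <- sample_cohort(n_solid = 13, n_cyst = 5, seed = 42)
res <- run_paper_contrasts(co$lesions, co$healthy)
data.frame(parameter = names(res$significance),
           significance = unname(res$significance))
#>   parameter              significance
#> 1        MD       a, b, d, e, g, h, i
#> 2        FA                      x, y
#> 3    f_star                b, e, g, i
#> 4      D_bi       a, b, d, e, g, h, i
#> 5    f_fast          a, d, f, g, i, y
#> 6  f_interm a, b, c, d, e, f, i, x, y
#> 7     D_tri       b, d, e, g, h, i, z
```

Each letter marks a significant (Bonferroni-adjusted p < 0.05) group
contrast for that parameter, e.g. `b` = healthy cortex vs. cyst: the cyst
group separates on every diffusion coefficient, as expected from its much
higher slow diffusivity (2.74 vs 1.41 ×10⁻³ mm²/s).

## Command line

```sh
inst/cli/renaldwi simulate --out run1 --preset cyst --snr 50 --seed 1
inst/cli/renaldwi fit --dwi run1/ivim.nii --bval run1/ivim.bval \
    --bvec run1/ivim.bvec --labels run1/labels.nii --out run1/maps --model triexp
inst/cli/renaldwi compare --lesions lesions.tsv --healthy healthy.tsv --out stats
```

Exit codes: 0 success, 1 usage, 2 data/validation, 3 numerical failure.
Every run writes its resolved configuration next to its outputs.

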