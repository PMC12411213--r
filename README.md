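# nwuct — automated net water uptake from non-contrast head CT

`nwuct` computes **net water uptake (NWU)**, a quantitative ischemic-edema
biomarker, from non-contrast head CT in a fully automated way, and provides
the statistical machinery to benchmark it against competing markers such as
ASPECTS. It is aimed at stroke-imaging researchers who want a reproducible,
rater-independent alternative to visual early-infarct scoring, plus the
simulation tools to validate every stage without patient data.

## The biomarker

Ischemic edema lowers CT attenuation. NWU quantifies this per region as the
relative hypoattenuation of a stroke-side region against its mirror region
in the contralateral hemisphere:

```
NWU (%) = (1 − D_ipsilateral / D_contralateral) × 100
```

where `D` is the mean density (HU) over the region's voxels after excluding
voxels outside the closed 20–50 HU window (which automatically removes
encephalomalacia, calcification, and acute hemorrhage from the density
calculation). The pipeline:

1. load NIfTI or classic DICOM CT (HU-calibrated, reoriented to RAS),
2. field-of-view selection, Gaussian voxel smoothing, skull stripping,
3. affine registration to a brain atlas (masked mean-squared-error metric,
   3-level multi-resolution pyramid, rigid-first staging, deterministic
   centroid/principal-axes initialization),
4. segmentation into the 10 anterior-circulation ASPECTS regions (caudate,
   lentiform nucleus, internal capsule, insula, M1–M6) via paired left/right
   atlas masks,
5. per-region NWU, plus a conventional average over the 10 regions and a
   region-volume-weighted average.

Because no public atlas masks ship with the package, a **synthetic atlas**
(exactly mirror-symmetric schematic head) is built in code; a real atlas in
the same directory layout (`template.nii.gz`, `regions.nii.gz`,
`brain_mask.nii.gz`, `codes.json`) is a drop-in replacement.

For outcome evaluation the package implements, from first principles:
logistic regression by IRLS with Wald intervals, stratified 80:20
train/test splitting, AUROC as the Mann–Whitney statistic, the DeLong
paired AUROC comparison, Fisher's exact test, and the Wilcoxon rank-sum
test — the workflow used to compare an NWU-based against an ASPECTS-based
outcome model.

## Worked example

Simulate a stroke scan with known ground truth (20% water uptake in the left
insula, 10% in left M2, HU noise, a tilted scanner pose), then run the full
pipeline:

```r
library(nwuct)

atlas <- build_synthetic_atlas()
spec <- phantom_spec(
  lesions = list(list(region = "insula", w = 0.20),
                 list(region = "M2",     w = 0.10)),
  side = "left", noise_sd = 2,
  pose = make_transform(rotation_deg = c(0, 0, 5), translation = c(4, -2, 3)),
  seed = 7)
ph  <- generate_phantom(spec, atlas)
out <- nwu_pipeline(ph$volume, atlas)
out$result
#> <nwu_result> ipsilateral side: left
#>   average NWU 2.96%, volume-weighted 1.60%
#>    region                nwu weight_mm3
#>  1 caudate            0.393        2112
#>  2 lentiform_nucleus  0.296        3248
#>  3 internal_capsule  -0.932        2024
#>  4 insula            20.1          2304
#>  5 M1                -0.0701      35624
#>  6 M2                 9.82        32008
#>  ...
```

The lesioned regions are recovered at their constructed values (insula 20.1%
vs true 20%, M2 9.8% vs true 10%); unlesioned regions sit near zero, and the
stroke side was detected automatically. The average (2.96%) reflects both
lesion extent and severity; the volume-weighted average down-weights the
small insula.

Outcome-model comparison on a simulated 402-subject cohort (covariates:
age, NIHSS, tPA, EVT):

```r
cohort <- generate_cohort(402, seed = 7)
cmd_evaluate(cohort, "eval_out", seed = 7)
#> <model_comparison> AUROC 0.833 (A: avg_nwu+age+nihss+tpa+evt)
#>                       vs 0.845 (B: aspects+age+nihss+tpa+evt)
#>   DeLong z = -1.164, two-sided p = 0.245 (n_test = 80, seed 7)
```

Here ASPECTS is generated as a noisy transform of the same latent severity,
so the two models carry similar signal and the DeLong test is
non-significant — the structural behaviour expected when two biomarkers are
equally informative.

A thin command-line wrapper with subcommands `compute`, `phantom`,
`cohort`, and `evaluate` lives at `inst/cli/nwuct.R`.

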