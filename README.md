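# PKSynth

Direct pharmacokinetic (PK) map synthesis from dynamic contrast-enhanced MRI
(DCE-MRI), with uncertainty maps — and the conventional tracer-kinetic
pathway it is benchmarked against.

## The problem

DCE-MRI quantifies blood-brain-barrier leakage in brain tumours by fitting
the extended Tofts model

> C_t(t) = v_p C_p(t) + K^trans ∫₀ᵗ C_p(τ) e^(−k_ep (t−τ)) dτ,  k_ep = K^trans / V_e

to each voxel's contrast-concentration curve, yielding maps of the transfer
constant K^trans (min⁻¹), the extravascular extracellular fraction V_e and
the plasma fraction V_p. The weak link is the arterial input function
C_p(t): it is selected semi-automatically from vessel voxels by a human
rater, and two raters produce measurably different maps. PKSynth implements
both routes around this problem:

* **conventional**: semi-automatic AIF extraction (with a seeded emulation
  of inter-rater variability) plus voxelwise bounded nonlinear least
  squares;
* **synthetic**: a two-stage spatiotemporal neural network — a per-voxel
  temporal convolutional network condenses the 60-frame signal series into
  three temporal feature maps, and a probabilistic U-Net with a Gaussian
  latent space turns them into PK maps — trained end to end, needing no AIF
  at inference, and yielding voxelwise uncertainty maps from repeated
  latent draws.

Everything is validated on digital reference objects: glioma-like phantoms
(enhancing rim, necrotic core, non-enhancing infiltration, vessel voxels)
with known ground truth, rendered to 4D SPGR signal with Rician noise, and
organised into labelled cohorts (WHO grade, IDH status) for the diagnostic
tasks. The evaluation battery covers SSIM, NRMSE, ICC(A,1) with F-based
CIs, Bland-Altman limits of agreement, and AUROC with DeLong confidence
intervals and paired tests. Audience: quantitative-imaging researchers who
want a fully reproducible, CPU-scale testbed for direct PK estimation and
its reliability statistics.

## Worked example

```r
library(PKSynth)

## one synthetic subject: ground-truth maps + rendered 4D series
ph  <- buildPhantom(phantomSpec(seed = 7))
aif <- populationAIF(timeGrid())
dce <- renderDCE(ph$gt, aif, noiseSd = 1, seed = 7)

## conventional pathway: extract the AIF from vessel voxels, fit the ROI
sel <- extractAIF(dce, ph$masks$vessel, perturbation = "none")
fit <- fitVolume(dce, sel$aif, ph$masks$enhancing_tumor)
subjectScore(fit$maps, ph$masks$enhancing_tumor)
#>     ktrans         ve         vp
#> 0.05117856 0.26315540 0.02637498
subjectScore(ph$gt, ph$masks$enhancing_tumor)   # ground truth
#>     ktrans         ve         vp
#> 0.05123767 0.25542022 0.02548212
```

The fitted enhancing-ROI means recover the phantom's ground truth to a few
percent at this noise level. The full study — cohort simulation, two AIF
raters, network training, sampling and the complete reliability report —
is one call:

```r
run <- runAll(runConfig(nSubjects = 50, seed = 2026))
run$report
```

On the shipped desk-scale conditions (50 subjects, 32x32 slices, 60
frames, ~7 minutes on one CPU core) the seed-2026 report prints, among
others:

| quantity | full model | temporal-only ablation | conventional |
|---|---|---|---|
| SSIM vs ground truth, K^trans (brain) | 0.913 | 0.899 | — |
| SSIM vs ground truth, V_e (brain) | 0.770 | 0.755 | — |
| SSIM vs ground truth, V_p (brain) | 0.971 | 0.970 | — |
| ICC of enhancing-ROI K^trans across repeats | 0.9998 | — | 0.872 |
| Bland-Altman LoA width, K^trans | 0.0082 | — | 0.256 |
| AUROC, IDH task, K^trans | 0.84 | — | 0.78 |

reproducing the qualitative findings the package is built to test: the
synthetic pathway matches the ground truth closely and beats the
temporal-only ablation on every parameter (most clearly for V_e, the
noisiest map); its repeat-measurement reliability across latent samples far
exceeds the conventional pathway's across AIF raters, with ~30x narrower
limits of agreement; and the two pathways are diagnostically comparable
(AUROC 0.57-0.98 across tasks and parameters at this small test-set size,
with no significant paired DeLong differences). The numbers above are what
the code printed for that exact call; other seeds vary within the
cohort-level spread.

A thin command-line front end is provided in `inst/cli/pksynth.R`
(`simulate`, `fit-tofts`, `run-all`).

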