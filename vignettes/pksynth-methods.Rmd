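---
title: "Direct PK map synthesis from DCE-MRI: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct PK map synthesis from DCE-MRI: models, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

PKSynth implements and validates two routes from a dynamic contrast-enhanced
MRI (DCE-MRI) signal series to pharmacokinetic (PK) parameter maps of the
extended Tofts model — the volume transfer constant $K^{trans}$ (min$^{-1}$),
the extravascular extracellular volume fraction $V_e$, and the plasma volume
fraction $V_p$:

* the **conventional pathway**: semi-automatic arterial input function (AIF)
  extraction from vessel voxels followed by voxelwise nonlinear least-squares
  fitting, and
* the **synthetic pathway**: a two-stage spatiotemporal neural model — a
  per-voxel temporal convolutional network (TCN) feeding a probabilistic
  U-Net — that maps the signal series directly to PK maps, bypassing AIF
  selection, and produces uncertainty maps by sampling its Gaussian latent
  space.

Because no public DCE-MRI glioma dataset accompanies this problem, the
package ships a digital-reference-object (DRO) generator that emulates
treatment-naive glioma DCE-MRI with known ground truth, and the entire
validation battery (SSIM, NRMSE, ICC, Bland-Altman, AUROC with DeLong
inference) runs against those phantoms.

## The physics core

The extended Tofts model gives the tissue contrast concentration

$$C_t(t) = v_p\,C_p(t) + K^{trans}\!\int_0^t C_p(\tau)\,
  e^{-k_{ep}(t-\tau)}\,d\tau, \qquad k_{ep} = K^{trans}/V_e ,$$

with $C_p(t)$ the plasma AIF. Units are minutes, min$^{-1}$ and mM
throughout; TR and $T_1$ are seconds inside the signal equations (the classic
seconds/minutes confusion is the most common DCE bug, so every function
documents its units). `toftsForward()` discretises the convolution with
piecewise-linear $C_p$ between frames and *exact* integration of the
exponential kernel over each interval. The scheme is exact for the
interpolated AIF (the property the quadrature oracle tests exploit) and
$O(\Delta t^2)$ against a continuous AIF; a series expansion guards the
$k_{ep}\Delta t \to 0$ limit against catastrophic cancellation.

Signal conversion uses the spoiled gradient-echo steady state
$S = S_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR\cdot R_1}$,
with $R_1(t) = 1/T_{10} + r_1 C_t(t)$. The inverse estimates the per-voxel
equilibrium signal from the pre-contrast baseline frames, so baseline
concentration is zero-mean by construction; noise that pushes the signal
below the invertibility floor is clamped to zero concentration and flagged
per voxel. Defaults (TR 2.8 ms, flip 10°, $r_1$ 3.3 s$^{-1}$mM$^{-1}$,
$T_{10}$ 1.5 s, 60 frames at 5 s, 5 baseline frames) describe a typical 3-T
3D SPGR glioma protocol; all are configuration, not constants.

Two population AIF forms are shipped (`inst/extdata/aif_models.yaml`): the
mixed gaussian-plus-sigmoid form with the Parker population coefficients
(whole-blood, converted to plasma with haematocrit 0.42), and a
Weinmann-type biexponential. The gaussian-sigmoid form is the default
because its sharp first pass stresses temporal sampling the way real bolus
curves do.

## Conventional pathway

`extractAIF()` emulates semi-automatic AIF selection: vessel-candidate
voxels are ranked by peak concentration (earlier arrival breaks ties), the
top five curves are averaged, and the whole-blood curve is scaled by
$1/(1-\mathrm{Hct})$. Rater variability — the paper's central nuisance — is
emulated by a seeded jitter: multiplicative noise on the ranking score
(re-ranking the candidates), a scale error within ±10%, and a bolus delay of
±1 frame. Two seeds stand in for two independent human raters; with no
perturbation two selections are identical, so all conventional-pathway
disagreement is AIF-driven by construction.

`fitVoxel()` minimises the residual sum of squares with bounded
Levenberg-Marquardt (minpack.lm), bounds $K^{trans} \in [0,5]$ min$^{-1}$,
$V_e \in [10^{-4}, 1]$, $V_p \in [0,1]$, a penalty keeping $V_e + V_p \le 1$,
and a three-start deterministic multistart against the shallow
$V_p/K^{trans}$ trade-off; the best RSS wins, ties resolved toward the
smaller $K^{trans}$. Flat-zero curves return the lower-bound convention
(unidentifiable, flagged); voxels with fewer than 75% valid frames are
skipped and zero-filled.

## The phantom generator

`buildPhantom()` lays out an elliptical brain, a three-layer ellipsoidal
tumour — necrotic core (near-zero $K^{trans}$, low $V_p$), enhancing rim
(high $K^{trans}$/$V_p$), non-enhancing infiltrative halo (intermediate,
sub-threshold) — and a small vessel patch whose voxels carry
$(0, 0, 1-\mathrm{Hct})$, i.e. the blood-scaled AIF. Per-voxel PK values are
log-normal draws per tissue class, truncated to the physical simplex. Class
centres (geometric means, $(K^{trans}, V_e, V_p)$): normal
(0.01, 0.05, 0.01); core (0.003, 0.45, 0.004); low-grade rim
(0.05, 0.25, 0.025); infiltration (0.02, 0.15, 0.015); voxel-level log-SD
0.2. These are synthetic calibration values chosen to give realistic
contrast between tissue classes, not measurements from any dataset.

`generateCohort()` makes the two diagnostic tasks: each subject draws two
independent binary labels, WHO grade (low/high) and IDH status
(mutant/wildtype). High grade multiplies the rim/infiltration centres by
(3.0, 1.4, 2.4) — equivalently, the low/high rim centres are
(0.05, 0.25, 0.025) vs (0.15, 0.35, 0.06) — and IDH-wildtype by
(2.5, 1.3, 2.2). Every subject also draws a log-normal subject-level
multiplier (log-SD 0.6, 0.3, 0.6), the between-subject spread that keeps the
tasks in a realistic AUROC band (~0.8–0.9) rather than saturating. Under a
pure log-mean shift $\delta$ with subject SD $\sigma$ the subject-mean score
is (a monotone transform of) a Gaussian two-sample problem, so the expected
AUROC is $\Phi(\delta/(\sigma\sqrt2))$ — the closed form the generator is
tested against. Rician noise is applied at signal scale
($\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$, the magnitude-image model, which is
approximately Gaussian above SNR 5); the default $\sigma = 1$ is about 5% of
the baseline tissue signal. Labels influence nothing but the PK
distributions, so permuting them within a cohort destroys all diagnostic
signal — a property the tests assert. All randomness fans out from a single
cohort seed through a documented derivation, so a cohort is one integer.

What the phantom deliberately does **not** model: anatomy beyond ellipsoids,
$B_1$/$T_1$-mapping error, partial-volume vessels beyond a scale factor, or
spatially correlated physiological noise. Passing tests therefore show the
algorithms are correct and well-behaved under controlled conditions, not
that the trained network transfers to clinical data.

## The two-stage network

Stage 1 is a per-voxel TCN: residual blocks of non-causal dilated 1-D
convolutions (kernel 3; dilations 1, 2, 4, 8, 16; 8 channels), giving a
receptive field of $(3-1)\sum d_i + 1 = 63 \ge 60$ frames. The block stack
is followed by four temporal poolings per channel — mean, max (peak height
and arrival, which a pure average washes out), and the means of the first
and last thirds of the series (the wash-in/wash-out contrast that
identifies $k_{ep}$) — and a small MLP head that emits three temporal
feature maps, one per PK parameter. The early/late-window means matter: a
mean+max-only pooling loses washout-rate information, which measurably
degrades $K^{trans}$ recovery in weakly enhancing tissue. The
operation is strictly voxel-local — spatial permutation equivariance is a
tested invariant. Eight channels (rather than a wider stack) keep a full
desk-scale training run on one CPU core in minutes while already giving the
receptive field the frame count requires; width is a config knob
(`modelConfig()`).

Stage 2 is a probabilistic U-Net over the three feature maps: a two-level
U-Net (8 base channels) plus two convolutional Gaussian encoders — a prior
conditioned on the features and a training-time posterior additionally
conditioned on the normalised ground-truth maps — over a 6-dimensional
diagonal-Gaussian latent. The latent sample is broadcast and concatenated
before the final 1×1 convolutions. The decoder output is a *residual
refinement*: it is added to the stage-1 regression head's logits before the
final softplus, so an untrained (zero-initialised) refinement reproduces the
stage-1 estimate exactly and joint training can only build on it. This
residual coupling is the package's design resolution of how to train the
serial two-stage combination stably at desk scale. Softplus keeps outputs
non-negative; outputs are de-normalised by per-parameter scales
(0.1, 0.3, 0.05) chosen so the three normalised maps have comparable
magnitude in the loss.

Training minimises `recon + beta * KL(posterior || prior)` (MSE on
normalised maps; beta = 1 after a linear warm-up over the first 20% of joint
epochs) with Adam and a step learning-rate decay (full rate for the first
60% of a phase, then 0.3×, then 0.1× — the per-voxel regression plateaus
noisily without it). The recipe is two-phase: stage-1 pretraining on
randomly subsampled voxel curves (256 per subject per step, learning rate
3×10$^{-3}$ — the per-voxel regression is a much easier optimisation), then
the second stage on full slices (10$^{-3}$). `train()` defaults to joint
end-to-end updates in that second phase; the standard desk-scale recipe
used by `runAll()` instead freezes stage 1, which lets the temporal
features be computed once per subject and cached, making second-stage
epochs roughly an order of magnitude cheaper — the refinement and the
latent encoders then train on a converged, fixed trunk. The `tcn_only`
mode trains stage 1 plus its 1×1 regression head alone; in `runAll()` the
ablation comparator is the full checkpoint's own stage-1 head, so the
full-vs-temporal-only comparison is paired on an identical trunk and
isolates exactly the spatial probabilistic stage. Inputs are normalised
per subject by the mean baseline signal (removing scanner scale,
preserving enhancement dynamics); determinism is guaranteed by deriving
every epoch/subject/latent seed from the training seed. Second-phase steps
apply a random dihedral symmetry (rotation/flip) to each slice: the spatial
stage sees only a few dozen training slices, and this augmentation is its
main overfitting control (disable with `augment = FALSE`).

Prediction draws `nSamples` (default 4) latent vectors from the prior,
decodes each, and reports the voxelwise mean maps plus voxelwise standard
deviation — in parameter units — as the uncertainty maps. With the latent
collapsed to the prior mean the model is a deterministic U-Net pass and the
uncertainty is exactly zero.

## Validation battery

* **SSIM**: standard Gaussian-window form (11×11, $\sigma$ 1.5,
  $C_1 = (0.01R)^2$, $C_2 = (0.03R)^2$), computed on the window-valid
  interior and averaged over a mask; $R$ is the robust (99.5th-percentile)
  ground-truth maximum per parameter over the evaluated subjects. Verified
  against a reference implementation on a frozen fixture.
* **NRMSE**: RMSE over the mask divided by the ground-truth range in that
  mask, ×100 — so tumour values sit far above whole-brain values, matching
  how the two scales behave under range normalisation.
* **ICC**: two-way random effects, absolute agreement, single measurement —
  ICC(A,1) — from the ANOVA mean squares with the F-based 95% CI. This is
  the natural form when "raters" are interchangeable measurements: two AIF
  selections (conventional) or the prediction samples (synthetic). Computed
  on subject-level enhancing-ROI means. Degenerate zero-variance input is
  flagged rather than returning a number.
* **Bland-Altman**: mean difference and limits of agreement
  $\bar d \pm 1.96\,\mathrm{SD}(d)$ between two repeated measurements of
  each pathway.
* **AUROC**: Mann-Whitney with half-weight ties, DeLong variance/CI, and the
  paired DeLong z-test between pathways on the same subjects (pROC under the
  hood; identical score vectors return difference 0, p = 1 by convention).
  No multiplicity correction is applied; p-values are reported raw.

`evaluateCohort()` assembles all of this into a `ReliabilityReport`;
`runAll()` chains simulate → conventional fits (two perturbed-AIF raters) →
train (full + ablation) → predict → evaluate. In the standard desk-scale
recipe the conventional maps are fitted over the enhancing-tumour ROI — the
only region the reliability and diagnostic summaries consume — which keeps
the nonlinear fitting budget proportionate.

## Problem sizes and numerical choices

The shipped study conditions are 50 subjects of 32×32×1 voxels × 60 frames
(2D slice mode), split 50/19/31% into train/valid/test as a deterministic
function of the cohort seed; stage-1 pretraining 45 epochs, 40
frozen-trunk refinement epochs, 4 prediction samples. These sizes make the full pipeline — cohort,
two rater fits, two model trainings, prediction and the complete report —
run end to end on a single CPU core in minutes, which the package treats as
a feature of the experimental design: every result in the README and the
acceptance outputs is recomputed from scratch at these sizes. The training
target in this recipe is the simulator ground truth (the generator's maps);
training toward conventional-fit maps — mirroring a setting where the
"ground truth" itself comes from commercial-software fits — is available via
the `targets` argument of `train()`.

Numerical conventions worth knowing: $k_{ep}$ is reported as 0 where
$K^{trans} = 0$ (non-enhancing tissue); network $V_e$ output is floored at
10$^{-6}$ so $k_{ep}$ stays defined; $V_e + V_p$ is projected back onto the
simplex when a network output or truncated draw would exceed 1; fitted ties
in the multistart resolve toward smaller $K^{trans}$; and ReLU subgradients
at exactly 0 are taken as 0 (relevant only to the gradient-check tests,
which perturb weights to break structural ties).

## Known limitations

* The synthetic cohort cannot validate clinical transfer; it validates
  correctness, reliability mechanics and the direction of the ablation and
  reliability comparisons.
* Only the extended Tofts model is implemented; Patlak, two-compartment
  exchange and tissue-homogeneity models are out of scope.
* 2D slice processing; no 3D spatial context.
* The desk-scale network (8/8 channels, latent 6) is intentionally small;
  its absolute SSIM/NRMSE numbers are specific to these conditions.
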