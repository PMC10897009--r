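---
title: "Quantification methods and the digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods and the digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strokemri` quantifies longitudinal multiparametric MRI of experimental focal
cerebral ischemia in the rat: diffusion (ADC), T2 and serial R1 relaxometry,
dynamic susceptibility contrast (DSC) perfusion, blood–brain-barrier (BBB)
permeability by a reference-region Patlak analysis, cerebrovascular
reactivity (CVR) from a hypercapnic BOLD challenge, and lesion-core
region-of-interest (ROI) analytics. A digital two-hemisphere rat-brain
phantom generates every input modality from known ground truth, so each
stage of the pipeline is verifiable end to end without animal data.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology left
genuine freedom.

## The longitudinal design being emulated

Each synthetic subject is imaged at three sessions: during middle cerebral
artery occlusion, 0.5 h after recanalization, and at day 4. Every session
carries diffusion-weighted imaging (b = 0 plus three cardinal gradient
directions), a multi-echo T2 series and a DSC bolus passage. At day 4 the
subject additionally receives serial post-contrast T1 mapping (the input of
the permeability analysis, acquired after the DSC gadolinium bolus) and a
hypercapnic BOLD challenge with a baseline period followed by a gas
stimulus. BBB permeability is assessed at day 4 only: once cavitation sets
in, the unidirectional-uptake assumption of the Patlak model stops holding
at later stages, and the emulated design mirrors that restriction.

## Relaxometry

Signal models are mono-exponential throughout:

* ADC: `S(b) = S0 exp(-b * ADC)`, fitted voxelwise as the least-squares
  slope of `-ln(S/S0)` against b. With two b-values this is the closed form
  `(ln S0 - ln S_b)/b`; with three or more it is the ordinary least-squares
  slope on log-signal, which is exact on noise-free decays. The mean ADC map
  is the arithmetic average of the three directional maps.
* T2: `S(TE) = S0 exp(-TE/T2)`, log-linear initialization refined by
  Gauss–Newton nonlinear least squares on the signal scale (the maximum
  likelihood estimate under additive Gaussian noise). Non-decaying voxels
  are clamped to a physical cap (default 2000 ms) and flagged.
* R1: saturation recovery `S(t) = S0 (1 - exp(-t R1))` or inversion-recovery
  magnitude `|S0 (1 - 2 exp(-t R1))|` with polarity restoration around the
  null point. Initialization is a separable grid search over R1 (S0 solved
  in closed form per candidate), refined by Gauss–Newton.

All fits run vectorized across voxels (the Gauss–Newton normal equations are
2×2 per voxel), so a whole 64×64×32 brain fits in well under a minute of
one CPU. Fitting uses magnitude signals; the original acquisition community
also fits complex-valued data, which differs only in the low-SNR regime.
Voxels with non-positive signal inside the mask are flagged invalid rather
than raised as errors.

The phantom's acquisition protocol emulates standard preclinical practice:
two-point DWI (b = 0, 1000 s/mm²) with 4 signal averages, a 12-echo CPMG
train (TE 10–120 ms) with 2 averages, and 8-point saturation-recovery T1
mapping (50–6000 ms, single average, as serial post-contrast maps cannot be
averaged across dynamics). Echo trains are kept within ~2.5·T2 of brain so
the high-SNR Gaussian assumption stays valid. Under this protocol the ADC
and T2 estimators reach a median voxel error under 2% at a baseline SNR of
40; R1 from single-average saturation recovery is intrinsically less precise
(~3–5% per map), which the Patlak stage absorbs by regressing over eight
time points and reporting ROI statistics.

## DSC perfusion

Tissue passage of the bolus follows indicator-dilution theory:
`C(t) = CBF * (C_a ⊛ R)(t)` with exponential residue `R(t) = exp(-t/MTT)`.
Signal conversion uses the standard delta-R2* transform
`C(t) = -ln(S(t)/S0)/TE` with S0 the pre-bolus baseline mean.

* The arterial reference curve is extracted from the contralateral
  hemisphere: voxels whose peak concentration strictly exceeds the mask's
  90th-percentile peak (the bolus carriers) are averaged frame-wise and
  baseline-zeroed. If the percentile filter selects nothing, the whole-mask
  mean is used with a warning.
* CBF is obtained by block-circulant SVD deconvolution: the AIF matrix is
  zero-padded to twice the series length (preventing temporal wrap-around,
  which is the point of the circulant embedding), singular values below a
  configurable fraction of the largest (default 0.15) are truncated, and the
  scaled residue `k(t) = CBF·R(t)` is solved per voxel; CBF is `max k(t)`.
* CBV is the trapezoidal integral of the tissue curve truncated at the 400th
  frame to suppress recirculation; MTT = CBV/CBF voxelwise, with zero-flow
  voxels flagged invalid rather than infinite.

The truncation fraction is a regularization parameter and should match the
noise level: 0.15 is a sensible default for noisy in-vivo data, while
noise-free round-trip verification uses a near-zero threshold (1e-6),
because truncated SVD visibly biases noise-free CBF downward (about -34% at
MTT = 4 s, dt = 0.5 s with the 0.15 default). The package's tests therefore
treat the threshold as part of the noise model, not a fixed constant.

Absolute perfusion units are deliberately not claimed: CBV integrates the
tissue curve only, and the AIF is a measured reference whose scale depends
on the vasculature sampled, so CBF/CBV/MTT are relative quantities. Scaling
all tissue curves by c scales CBF and CBV by c and leaves MTT unchanged;
scaling the AIF by c divides CBF by c and multiplies MTT by c (both
properties are tested). Consequently only relative regional indices —
ipsilesional mean as a percentage of the mirrored contralateral homologue
(rrCBF, rrCBV, rrMTT) — are interpretable across subjects, which is exactly
how the pipeline reports perfusion.

## BBB permeability (reference-region Patlak)

Concentration is operationalized as delta-R1 (post- minus pre-contrast R1),
proportional to gadolinium concentration with a proportionality constant
that cancels from the analysis. The reference tissue is a muscle ROI
adjacent to the skull, assumed to exchange reversibly with plasma. The
generalized Patlak linearization plots

* `X(t) = ∫₀ᵗ C_RT dτ / C_RT(t)` (minutes) against
* `Y(t) = C(t) / C_RT(t)` (unitless),

and under unidirectional tissue uptake the points fall on the line
`Y = Ki·X + V0`, fitted voxelwise by ordinary least squares. The slope is
the blood-to-brain transfer constant Ki (1/min), the intercept the apparent
distribution volume V0.

Design choices: the fit window defaults to every frame after the first
post-injection map (the quasi-steady reference-exchange regime; the early
bolus frame is excluded), frames with non-positive reference concentration
are dropped, at least three frames are required, and negative fitted slopes
are retained in maps (clipping would bias group contrasts) while ROI
summaries use medians.

## Cerebrovascular reactivity

The BOLD series is normalized voxelwise to its own pre-stimulus baseline
mean, making the estimator invariant to global signal scaling. The
contralateral-hemisphere mean time course defines the reference response;
the frame of maximum absolute deviation from baseline (ties resolved to the
earliest frame) anchors a fixed 100-frame window, split 50 before / 50
after the peak. CVR is the voxelwise mean percent signal change over that
window. A window that would extend past the series end or before stimulus
onset is shifted inside the response epoch — not truncated — to preserve the
fixed-length average; the shift emits a warning. Reading "maximum change"
as maximum absolute deviation makes the rule robust to inverted responses
while behaving identically for the positive hypercapnic response.

The phantom's challenge layout is 90 baseline frames and 130 stimulus frames
(2 s frame interval, i.e. 3 min baseline and about 4.3 min of stimulation)
with a 10-frame onset ramp, keeping at least 100 frames of stimulated
plateau so the window rule is always satisfiable; configurations violating
that are rejected at construction.

## ROI analytics

Lesion segmentation is threshold-based against contralateral statistics:
threshold = contralateral mean ∓ `k_sd` standard deviations (hypointense for
cytotoxic edema on ADC during occlusion, hyperintense for vasogenic edema on
day-4 T2), restricted to the ipsilateral hemisphere, cleaned by a 1-voxel
6-connected morphological closing, and reduced to the largest connected
component. `k_sd = 2` is the default; the underlying semi-automatic
protocols in the experimental literature do not publish a universal
constant, so this is a documented interpretation, configurable per run.

The lesion core is the voxelwise intersection of the acute (occlusion ADC)
and final (day-4 T2) lesions — acute injury that proceeded to infarction.
Contralateral homologues are pure grid reflections about the central
sagittal plane; phantom grids have even x-extent, making the reflection an
exact volume-preserving involution. For real data a registration step would
be needed before mirroring and is out of scope here. Subjects enter cohort
summaries only if the acute ischemic volume is strictly larger than 30 µL.

## The digital phantom

Geometry: an ellipsoidal brain centered on the grid, split into hemispheres
at the central sagittal plane; a muscle slab adjacent to the posterior
skull, outside the brain, as the Patlak reference; a mirror-symmetric pair
of intracerebral vessel cylinders acting as arterial input carriers
(simulated as very-high-CBF, short-MTT tissue so the same convolution
forward model covers them); and an ellipsoidal right-hemisphere lesion whose
acute extent (occlusion) and final extent (day 4) differ by a per-preset
scale factor. Lesions may be cropped by the brain surface, as cortical
infarcts are, but must stay strictly inside the right hemisphere.

Ground-truth values are organized as anesthesia-group presets that encode
only the *direction* of the group effects: the isoflurane-like preset grows
its lesion (final > acute), shows day-4 hyperperfusion (rrCBF > 100%),
shortened rrMTT, higher lesion-core Ki and depressed lesion-core CVR; the
propofol-like preset the converse (final ⊂ acute, rrCBF ≤ 100%, longer
rrMTT, lower Ki, better-preserved CVR). Magnitudes are editable defaults
chosen to be physiologically plausible for rat brain at high field (e.g.
normal ADC 0.75×10⁻³ mm²/s with a 40% acute drop, T2 45 ms with day-4
vasogenic elevation, MTT 4 s, Ki of order 0.01 min⁻¹ in leaky infarct
versus 0.001 min⁻¹ with intact BBB, CVR 5% in healthy tissue); they are not
claims about any real cohort. Synthetic sensorimotor deficit scores are
Poisson draws (rates 6.0 and 3.8 per preset) clipped to the 0–22 scale of
the behavioral battery.

Noise is additive Gaussian on the magnitude signal — not Rician — with
per-modality defaults of 2.5% of baseline signal (SNR 40) for DWI, T2, T1
and DSC and 0.5% for BOLD. The Gaussian choice keeps closed-form recovery
tests exact and is indistinguishable from Rician in the high-SNR regime the
protocol maintains; it under-represents the Rician floor of genuinely
low-SNR magnitude data (e.g. heavily diffusion-weighted lesions at low S0).
Identical configuration and seed give bit-identical subjects; cohort
simulation adds per-subject lognormal jitter (5% SD, truncated at 2 SD) to
lesion radii and day-4 effect values.

What the phantom does **not** emulate: realistic anatomy, partial-volume
effects, motion or susceptibility artifacts, midline shift (and hence any
registration step), bolus delay/dispersion heterogeneity between
hemispheres, contrast-agent recirculation, and Rician noise floors. Passing
recovery tests on this phantom therefore demonstrates correctness of the
estimators on their own forward models, not robustness to every artifact of
real acquisitions.

## Numerical choices and degenerate inputs

* Trapezoidal rule for all time integrals (CBV, Patlak abscissa) — exact
  for piecewise-linear curves.
* The DSC concentration transform zeroes frames at or above baseline and
  guards the log at 1e-12; series need at least 3 baseline frames.
* Gauss–Newton iterations stop when voxel updates fall below 1e-13
  relative; rates are clamped to broad physical bounds before flagging.
* Tie-breaks are deterministic everywhere (earliest frame for CVR peaks,
  first maximum in grid searches).
* Degenerate inputs return flagged voxels, not exceptions: zero baselines,
  zero-flow voxels (MTT undefined), non-positive signals, empty
  segmentation results. Structural errors (grid or space-tag mismatches,
  invalid b-values, too-short plateaus, corrupt sidecars) fail fast with
  named conditions.

## Problem sizes used in verification

The shipped verification suite runs relaxometry recovery on the full
64×64×32 grid; DSC oracle equivalence on an 8×8×1 toy (brute-force
pseudoinverse per voxel); Patlak accuracy on 200 seeded replicates of an
8×8×2 ROI at SNR 20; and five independently seeded end-to-end cohorts of
11 isoflurane-like plus 8 propofol-like subjects on a 32×32×12 grid with a
150-frame DSC series, each required to reproduce every configured effect
direction. These sizes are the package's own verification choices; all
scale up by configuration.

## Worked example

```{r example}
library(strokemri)

cfg <- phantom_config(grid_shape = c(32L, 32L, 12L), seed = 1)
subject <- generate_subject(cfg)
result <- run_subject(subject, subject_id = "demo01")
result$report

cohort <- simulate_cohort(n_iso = 11, n_prop = 8, seed = 1,
                          grid_shape = c(32L, 32L, 12L),
                          n_dsc_frames = 150L, dsc_dt = 1)
summary <- summarize_cohort(cohort)
group_contrasts(summary)
plot_cohort_summary(summary, "rrCBF")
```

## Known limitations

* Relative-only perfusion: no partial-volume-corrected AIF, no leakage
  correction, no delay-insensitive (oSVD) deconvolution variants.
* Pure linear Patlak: no efflux term, no extended Tofts modeling.
* Magnitude-only relaxometry; complex-valued fitting is not implemented and
  its low-SNR behavior is not reproduced.
* Mirroring assumes a symmetric grid; real data with midline shift needs
  registration first.
* Group statistics are descriptive (mean ± SD and direction checks);
  inferential mixed-model analysis is delegated to external statistics
  tooling on the exported long-format tables.
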