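---
title: "Methods: GP-predicted arterial input functions for 15O-water CBF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP-predicted arterial input functions for 15O-water CBF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

Quantitative cerebral blood flow (CBF) from dynamic ¹⁵O-water PET requires
the arterial input function (AIF). `mlifpet` predicts it non-invasively:
three carotid image-derived input functions (IDIFs) with graded
partial-volume dilution are extracted automatically from the dynamic image
and mapped to an arterial curve by Gaussian-process (GP) regression trained
on scans for which a blood-sampled AIF exists. This vignette documents the
model, its assumptions, the tunable parameters, the numerical choices, and
what the digital phantom does and does not establish.

## Pipeline and assumptions

1. **Framing.** The acquisition is a 10-min scan reconstructed into 26
   frames (1×10, 8×5, 4×10, 2×15, 3×20, 2×30, 6×60 s). Frame values are
   treated as samples at frame midpoints; linear interpolation yields the
   1-s working grid. Before the first midpoint the curve is extrapolated
   linearly from 0 at t = 0 — a bolus scan starts at injection, so assuming
   zero pre-injection activity fabricates nothing. After the last midpoint
   the value is held. Decay correction is assumed already applied.
2. **Analysis window.** Only 0–6 min are used, limiting late-scan noise.
   The window is the closed interval [0, 360] s — 361 samples at 1 s. The
   endpoint convention is a package decision (array shapes must be fixed);
   windowing is idempotent.
3. **Carotid segmentation.** The search volume trims `xy_trim` voxels per
   side in-plane and `z_trim` slices per axial end (symmetric, since edge
   artefacts occur at both ends). The thresholding frame is the first whose
   grey-matter summed intensity strictly exceeds 25% of the frame-wise
   maximum of that sum — an early-bolus frame where the carotids are bright.
   The 10, 100 and 1000 highest-intensity voxels of that single frame form
   three VOIs; per-frame medians give IDIF₁₀/₁₀₀/₁₀₀₀. Ties at a cutoff are
   broken by ascending linear voxel index, which makes the selection
   deterministic and keeps the VOIs nested even under ties. The even-count
   median is the mean of the two central values.
4. **Blood correction.** The wrist signal is modelled as the true AIF
   convolved with (1/τ)e^(−t/τ); the inversion C_A = g + τ·dg/dt uses
   central differences (one-sided at the ends, no pre-smoothing by default;
   a moving-average width is exposed for noisy detectors). τ = 15 s, fixed
   for all subjects. Calibration scales the whole curve so its mean over
   ±10 s around the single well-counter draw matches that sample — the
   window suppresses 1-Hz detector noise and the factor is invariant to
   detector gain. Delay alignment maximises the dot product with IDIF₁₀
   over integer shifts in ±30 s (arm-to-brain transit is physiologically
   well inside that), zero-padding outside the support and breaking ties
   toward the smallest |shift|. Order: dispersion-correct → calibrate →
   align (calibration is a pure scale, so its position relative to the
   dispersion step is immaterial; the order is fixed for reproducibility).
5. **GP model.** Each scan's three windowed IDIFs are normalised by
   per-channel cohort-maximum peaks (training inputs land in [0, 1]; test
   inputs may exceed 1, deliberately preserving domain shift) and
   concatenated into a 3×361-dimensional input. A zero-mean GP with a
   single isotropic Matérn ν = 5/2 kernel is shared across the 361 output
   time points — the matrix form of the predictive equations with Y an
   N×T matrix. An isotropic lengthscale is forced by sample size: N ≈ 20
   subjects cannot support per-dimension lengthscales over 1000+ inputs.
   The mean function is zero (nothing in the data motivates another
   choice); training outputs stay in kBq/mL so the predicted curve carries
   absolute calibration; the noise variance σ_ε² is optimised with the
   kernel parameters. In leave-one-out use, normalisation constants are
   refit on each training fold, so the held-out scan contributes neither
   its AIF nor its peaks — the test side needs no blood data at all.
6. **Kinetics.** One-tissue-compartment model; for ¹⁵O-water CBF = K₁.
   The fit is uniformly weighted nonlinear least squares
   (Levenberg–Marquardt, `minpack.lm`) with physiologic bounds
   K₁ ∈ [0, 5] mL·min⁻¹·g⁻¹, k₂ ∈ [0, 10] min⁻¹, V_A ∈ [0, 1], start
   (0.5, 1.0, 0.05), tolerances 1e−12. Uniform weighting is the minimal
   assumption; frame-duration weighting would privilege late frames that
   the 0–6 min window already de-emphasises. Tissue density is taken as
   1 g/mL so mL·min⁻¹·mL⁻¹ reads as mL·min⁻¹·g⁻¹. Non-convergence is
   reported through a flag, never silently.

## Numerical choices

- **Dispersion forward model.** Kernel weights are bin integrals of
  (1/τ)e^(−t/τ) (exact for piecewise-constant input), renormalised to unit
  sum so the discrete operator preserves curve area; what is genuinely lost
  is the mass the continuous operator pushes past the window end, bounded
  by τ times the tail value. τ = 0 degenerates to the identity.
- **Tissue convolution.** C_A ⊗ e^(−k₂t) is evaluated by the interval-wise
  trapezoidal recursion I_i = I_{i−1}·e^(−k₂Δt) + Δt/2·(C_{i−1}e^(−k₂Δt) +
  C_i), exact for piecewise-linear input. A left-rectangle rule at Δt = 1 s
  carries a bias of order half a sample on the bolus rise — roughly 10%
  where the curve climbs fastest — which the trapezoidal form removes; the
  k₂ = 0 limit then reproduces the cumulative trapezoidal integral to
  machine precision.
- **GP optimisation.** L-BFGS-B on log-parameters (positivity by
  construction), gradient tolerance 1e−6, 1000 iterations, bounds
  ℓ ∈ [1e−3, 1e3], σ_f² ∈ [1e−6, 1e4], σ_ε² ∈ [1e−8, 1e2], jitter
  1e−10·σ_f² on the diagonal. The marginal likelihood has a degenerate
  optimum in which the kernel collapses (ℓ → 0) and the data are explained
  as pure noise around the zero mean; a fixed unit-scale start can land
  there because outputs are in kBq/mL. Initialisation is therefore
  data-driven and deterministic — ℓ₀ at the median pairwise training
  distance, σ_f² at the mean output variance, σ_ε² at 1% of it — with a
  three-point multi-start over ℓ₀ × {0.3, 1, 3}, keeping the best final
  likelihood. Degenerate inputs (all-zero channels, non-positive
  normalisation constants, dimension mismatches) raise errors rather than
  propagate.
- **Statistics.** Orthogonal regression is total least squares with equal
  error variances (the closed-form slope; swapping the variables inverts
  it). The outlier rule flags slopes more than 3 × 1.4826 × MAD from the
  median; when MAD = 0 the limit of the rule flags any value different
  from the median. Curve-level scatter is compared after frame-averaging
  the 1-s curves back onto the original 26-frame schedule (frames fully
  inside the window; frame-average chosen over midpoint sampling because
  it is what the scanner itself reports per frame).

## The digital phantom

The phantom exists so that every stage has ground truth. Per subject-scan
it draws a gamma-variate bolus with an exponential recirculation tail
(amplitude 40–70 kBq/mL, shape 2.5–3.5, scale 5–8 s, tail fraction
0.08–0.15), true CBF from Normal(0.45, 0.05) at baseline or
Normal(0.60, 0.07) after acetazolamide (truncated above 0.2 mL·min⁻¹·g⁻¹),
k₂ = CBF/0.9 (partition coefficient 0.9 mL/g), V_A = 0, a brain arrival
delay of 6–10 s (3 s shorter under acetazolamide, emulating increased flow
velocity), and a wrist delay 8–14 s longer with τ = 15 s dispersion. The
acetazolamide effect on curve shape is encoded as +15% brain-local bolus
area with the wrist shape unchanged — the central asymmetry the method is
sensitive to: the wrist does not see the local cerebrovascular change, so
wrist-AIF-based CBF overstates the acetazolamide increase relative to the
local truth while MLIF-vs-AIF comparisons remain consistent.

The image is a 44×44×22 grid of 2-mm voxels: two carotid tubes (radius 2.2
voxels) carrying the local arterial curve and a disjoint grey-matter
ellipsoid shell carrying the one-tissue tissue curve, frame-averaged,
blurred with a 5-mm-FWHM Gaussian PSF (separable shift-and-add convolution)
and degraded with Gaussian noise of variance noise_scale·signal/frame
duration (default noise_scale 0.5) — short early frames are noisiest, as in
reconstructed PET. Because the grid is small, the carotid search uses
trims of 6 voxels in-plane and 2 slices axially (`phantom_config()`); the
clinical defaults remain 20 and 5. All randomness flows from one seed
through named substreams; ground truth lives in a separate `truth` element
(a separate `truth/` directory on disk) that no pipeline function reads.

What the phantom does **not** emulate: anatomy beyond tubes-and-shell,
inter-frame motion, scanner reconstruction (OSEM point-spread and noise
correlations), scatter/randoms, detector dead time, between-scanner
heterogeneity, or pathology-driven AIF shape changes. Passing tests on the
phantom therefore demonstrate internal consistency of the method under its
own generative assumptions — not clinical performance.

## Problem sizes and runtime choices

The test suite and the acceptance script use a 20-subject paired cohort
(40 scans) for the end-to-end evaluation, 100 draws for delay-recovery and
K₁-noise studies, and a 5-subject toy set for the GP linear-algebra oracle.
The 100-draw K₁ study applies the phantom's frame-noise model at region
scale (voxel variance divided by the grey-matter voxel count — the noise of
a mean TAC) rather than rendering 100 full images, which measures the same
quantity at a fraction of the cost. These sizes were chosen as the smallest
that exercise cohort-level behaviour; all are package decisions, not
protocol constants.

## Known limitations

- Within-condition CBF correlation between MLIF and AIF is limited by the
  ratio of between-subject CBF spread to per-subject prediction error;
  like the original evaluation protocol, model comparisons may exclude
  scans flagged by the scaled-MAD slope rule.
- GP peak underprediction (regression slopes below 1) is expected when few
  high-amplitude samples exist near the bolus peak; it biases CBF upward
  through the K₁–C_A inverse relationship.
- The GP input encoding treats whole curves as single vectors with one
  isotropic kernel; per-time-point input encodings are a plausible
  alternative that this package does not implement.
- The predictive variance is reported but not used as a quality gate; no
  reliable relationship between it and CBF error is assumed.
- Per-subject dispersion constants, detector dead time and
  tubing-geometry-specific kernels are out of scope (τ is fixed at 15 s).
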