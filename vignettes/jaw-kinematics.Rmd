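---
title: "Measuring proal jaw kinematics from marker trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring proal jaw kinematics from marker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chewkin)
library(dplyr)
```

## The measurement problem

Rodents such as the brown rat chew with a *proal* power stroke: during
tooth–tooth contact the lower molars slide along the uppers from posterior to
anterior, driven by anterior translation of the mandibular condyle in a
shallow, eminence-free temporomandibular joint (TMJ). Because the left and
right hemimandibles are joined by an unfused, ligamentous symphysis, each can
in principle move semi-independently. Quantifying this behavior requires
six-degree-of-freedom (6-DOF) kinematics of three rigid bodies — cranium,
left and right hemimandibles — reconstructed from radio-opaque markers
implanted in each bone and tracked in biplanar X-ray video (an XROMM-style
workflow). `chewkin` implements the downstream analysis: from reconstructed
3D marker coordinates to a per-individual amplitude table with between-cycle
and workflow confidence intervals.

The pipeline stages are:

1. **Filtering.** Marker coordinates are low-pass filtered per marker per
   axis *before* pose estimation (zero-phase Butterworth). Filtering raw
   coordinates rather than poses keeps every estimated rotation exactly
   orthonormal and avoids interpolating rotations.
2. **Pose estimation.** Each bone's pose per frame is the least-squares rigid
   transform (orthogonal Procrustes with reflections excluded) mapping its
   reference marker constellation onto the observed markers. Missing markers
   are excluded, never imputed; frames with fewer than three usable markers
   yield missing poses that propagate as missing through every downstream
   trace.
3. **Coordinate systems.** A cranial anatomical coordinate system (ACS) is
   built by fitting a total-least-squares plane to the upper tooth-row cusp
   landmarks; X is the in-plane projection of the cranial long axis
   (anterior positive), Z is in-plane orthogonal to X (right positive), and
   Y = Z × X (superior positive). Mandibular ACSs are clones of the cranial
   ACS orientation at the zero posture, with origins at the condyle and
   symphysis centroids.
4. **Joint coordinate systems.** TMJ (cranium fixed, hemimandible mobile) and
   symphysis (left fixed, right mobile) use the Grood–Suntay axis hierarchy:
   pitch about the fixed body's Z, roll about the mobile body's X, yaw about
   the floating mutual perpendicular — an intrinsic Z–Y′–X″ factorization of
   the zero-referenced relative rotation. Translations are reported as the
   mobile ACS origin's displacement from its zero position, expressed in the
   fixed body's ACS axes (see *Design choices*).
5. **Cycle statistics.** Chew cycles are segmented at gape maxima,
   spline-interpolated to 100 samples, and summarized as per-variable
   absolute amplitudes (max − min) with between-cycle 95% CIs; the occlusal
   phase is the middle 40% of the normalized cycle (samples 31–70).
6. **Workflow precision.** Zero-motion (frozen cadaver) trials quantify the
   apparent joint motion produced by the measurement chain alone.

## The zero pose

All six DOFs of each joint are defined to be zero at *centric occlusion* of a
representative chew. The pipeline selects the representative cycle as the
kept cycle whose pitch amplitude is closest to the median across cycles
(deterministic; configurable via `zero_frame`), and takes the frame of peak
closure within it, with ties broken by the earliest frame. The mandibular
ACSs are then cloned from the cranial ACS at that frame, which makes the
6-DOF decomposition exactly zero there by construction.

## Sign conventions

X anterior, Y superior, Z to the animal's right, right-handed. Positive
pitch (Rz) closes the jaw; positive Tx is anterior; positive yaw (Ry) turns
the mandible toward the animal's left; positive roll (Rx) brings the right
side superior. At the symphysis the left hemimandible is the fixed body, so
swapping fixed/mobile flips only polarities, not magnitudes. These
conventions are enforced by a mirror test: reflecting a scene through the
midsagittal plane swaps the two TMJ traces and flips the signs of Rx, Ry,
and Tz while preserving Rz, Tx, Ty.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `cutoff_hz` | 20 | Hz | zero-phase Butterworth; `NULL` disables. Recordings at 250 frames/s; chew rate ≈ 5 Hz, so 20 Hz keeps ~4 harmonics. |
| `filter_order` | 2 | — | per pass; two passes double the attenuation in dB |
| `min_amplitude_deg` | 5 | deg | pitch gate: below this a "cycle" is not a chew |
| `max_amplitude_deg` | 25 | deg | food-gathering cycles pitch more than chews and are excluded |
| `min_prominence_deg` | 3 | deg | gape-peak prominence for cycle boundaries |
| `occlusal_start/end` | 31/70 | samples | middle 40% of the 100-sample cycle |
| `ci_mode` | pointwise | — | time-averaged pointwise CI band; `"amplitude"` uses the per-cycle amplitude distribution |
| `max_gap_frac` | 0.1 | — | longest interior missing run a cycle may carry |

## The synthetic generator

No public recordings accompany this kind of study, so the package ships a
first-class generator (`simulate_chew_trial()`) whose defaults emulate the
published in vivo conditions: three bodies with 4/4/4 markers (a 3-marker
right hemimandible for individual "B"), 250 frames/s, ≈5 Hz gape cycles with
an occlusal plateau occupying the middle 40% of the cycle, anterior (proal)
condylar translation concentrating 55% of its excursion inside occlusion,
low-amplitude sinusoids on the remaining DOFs, near-zero symphyseal motion,
slow whole-head motion, additive isotropic marker noise (default
σ = 0.05 mm), optional missingness, and zero-motion cadaver trials. The 15
per-individual amplitudes and the 13/7/18 cycle counts come from the bundled
reference table (`reference_amplitudes()`).

Choices the data did not dictate, made once:

- **Waveforms.** Chewing frequency and within-cycle waveform shapes are not
  reported for this system; we use raised-cosine open/close profiles because
  they are C¹-smooth, periodic, and give exact analytic control of the
  amplitude (max − min equals the injected value). The pitch profile carries
  a shallow closure bump (2% of pitch amplitude) inside the occlusal plateau
  so that peak closure — the zero posture — is unique at mid-cycle. All
  injected waveforms vanish at mid-occlusion, so the zero pose the pipeline
  finds coincides with the generator's all-zero posture.
- **Degrees of freedom.** Three bodies leave only 12 relative DOFs, so the
  condylar (working-side, right TMJ) and symphyseal waveforms are injected
  exactly and the left hemimandible follows from both (right pose composed
  with the inverse symphyseal motion). Molar-locator translations are
  emergent from geometry; their ground truth is computed analytically from
  the generated poses rather than injected, and their magnitudes therefore
  reflect the synthetic skull geometry, not the reference table.
- **Marker noise.** σ = 0.05 mm is of the order of marker-based
  videoradiography reconstruction error. The workflow CIs it produces with
  the default 3.5 mm constellation spread are larger than the published
  workflow row, which is expected: precision scales with the constellation
  lever arm, and σ is a free parameter (studies report CIs, not σ).
- **Cycle counts and padding.** A trial spans `n_cycles + 1` gape periods
  starting at mid-occlusion so that exactly `n_cycles` complete cycles lie
  between interior gape maxima.

### What the generator does *not* emulate

Real cycle-to-cycle variability (every synthetic cycle has identical
underlying kinematics, so between-cycle CIs reflect only marker noise),
correlated or non-Gaussian tracking error, marker occlusion structure
(missingness is i.i.d.), bone deformation, and food-bolus mechanics. Passing
the recovery tests therefore demonstrates that the *measurement chain* is
unbiased and precise under the stated noise model — not that it would
reproduce in vivo between-cycle variability.

## Numerical choices

- **Pose estimation** uses the SVD solution with the determinant correction
  (smallest-singular-value axis flipped when the optimal orthogonal matrix
  is a reflection); constellations whose second singular value falls below
  0.1 mm are rejected as collinear.
- **Filtering** runs the Butterworth difference equation with steady-state
  initial conditions and odd-reflection end padding, so constants pass
  through exactly and endpoint transients are suppressed; contiguous valid
  segments are filtered independently and segments shorter than the padding
  are passed through unfiltered and flagged.
- **Decomposition** flags (rather than fails on) yaw within 0.5° of gimbal
  lock; rat jaw yaw stays below ~3°, so the flag should never fire on
  plausible data.
- **Spline normalization** uses cubic interpolation through the valid
  samples; endpoints are preserved exactly. Amplitudes measured after
  normalization agree with the dense original to spline tolerance (~1e-3 of
  amplitude for a one-period sinusoid at 50+ samples), which is why
  end-to-end zero-noise recovery is specified at 1e-3 relative rather than
  machine precision.
- **Between-cycle CI** (default) is the average over the 100 normalized time
  points of the pointwise across-cycle t-based 95% CI half-width of the mean
  trace — the time-averaged width of the CI band around a mean cycle plot.
  With the t factor the CI shrinks slightly faster than 1/√n at small n.
- **Workflow CI** is the half-width of the t-based 95% interval for
  individual frame values pooled across zero-motion trials (t·s, not
  t·s/√n): it quantifies the scale of apparent motion, which is the quantity
  comparable to between-cycle variability and the natural tolerance for
  amplitude-recovery checks.
- **Report rounding** is half-up at two decimals (one for the symphyseal
  translation grand mean), matching the usual presentation; unrounded values
  are always carried in the machine-readable report.

## Worked example

```{r example}
params <- chew_model_params("A", n_cycles = 5, seed = 42)
sim <- simulate_chew_trial(params)
fit <- analyze_chew_trial(sim)
glance(fit)
tidy(fit) |> filter(startsWith(variable, "condyle"))
```

Recovered condylar amplitudes sit within noise tolerance of the injected
values (pitch 18.10°, anterior translation 2.13 mm), and the occlusal
displacement of `condyle_tx` is ≈ 0.55 × 2.13 ≈ 1.2 mm — anterior condylar
translation concentrated in the power stroke, the signature of proal
chewing.

```{r precision}
cad <- simulate_cadaver_trial(chew_model_params("A", head_motion_mm = 10,
                                                head_motion_deg = 10,
                                                cadaver_seconds = 2))
precision_analysis(cad)$precision
```

## Known limitations

- Between-cycle CIs from synthetic data understate in vivo values because
  the generator repeats one cycle shape.
- Molar-locator amplitudes depend on the synthetic skull geometry (condyle
  to molar lever arm) and are not calibrated to the reference table.
- The left (balancing-side) TMJ trace is derived from the working side and
  the symphysis, not independently injected.
- The pipeline assumes one marker-defined rigid body per bone; it does not
  model bone deformation or tooth wear, and starts from reconstructed 3D
  coordinates (camera calibration and 2D tracking are upstream tools'
  responsibility).
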