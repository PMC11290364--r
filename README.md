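# chewkin

Six-degree-of-freedom jaw kinematics from 3D marker trajectories, for
marker-based biplanar videoradiography (XROMM-style) studies of chewing —
in particular *proal* chewing, where the lower tooth row slides
posterior-to-anterior along the uppers during the power stroke, as in rats.

Given per-frame 3D marker coordinates for a cranium and two hemimandibles,
per-bone reference marker constellations, and anatomical landmarks, the
package reconstructs:

- **bone poses** per frame by least-squares rigid registration (orthogonal
  Procrustes / Kabsch, reflections excluded, missing markers dropped);
- **anatomical coordinate systems** from an occlusal-plane fit to the upper
  tooth-row cusps (X anterior, Y superior, Z right);
- **joint coordinate systems** at the temporomandibular joint and the
  mandibular symphysis with the Grood–Suntay axis hierarchy — pitch about
  the fixed body's Z axis, roll about the mobile body's X axis, yaw about
  the floating axis: an intrinsic Z–Y′–X″ factorization
  `R = Rz(pitch) · Ry(yaw) · Rx(roll)` of the zero-referenced relative
  rotation, with translations of the mobile origin expressed in the fixed
  body's axes;
- **chew-cycle statistics**: segmentation at gape maxima, 100-sample spline
  normalization, per-cycle absolute amplitudes (max − min), between-cycle
  95% CIs, and occlusal-phase (middle 40%) displacements;
- **workflow precision** from zero-motion (frozen cadaver) trials, as the
  t-based 95% interval half-width of the pooled apparent motion.

A first-class synthetic generator (`simulate_chew_trial()`,
`simulate_cadaver_trial()`) produces noisy marker trajectories with exact
analytic ground truth, so the whole pipeline is testable without any
recorded data.

## Worked example

```r
library(chewkin)
library(dplyr)

params <- chew_model_params("A", n_cycles = 5, seed = 42)  # reference-derived defaults
sim    <- simulate_chew_trial(params)                      # noisy markers + ground truth
fit    <- analyze_chew_trial(sim)                          # full pipeline
tidy(fit) |> filter(startsWith(variable, "condyle"))
#> # A tibble: 6 × 5
#>   variable   n_cycles mean_amplitude     ci occlusal_displacement
#>   <chr>         <int>          <dbl>  <dbl>                 <dbl>
#> 1 condyle_rx        5          1.18  0.260                 0.416
#> 2 condyle_ry        5          2.92  0.265                 2.63
#> 3 condyle_rz        5         18.1   0.275                 0.237
#> 4 condyle_tx        5          2.15  0.0471                1.19
#> 5 condyle_ty        5          1.40  0.0395                1.33
#> 6 condyle_tz        5          0.264 0.0494                0.0738
```

The injected condylar pitch (18.10°) and anterior translation (2.13 mm) are
recovered within noise tolerance; small-amplitude DOFs (roll 0.80°) are
inflated by marker noise by less than twice the workflow CI. The occlusal
displacement of `condyle_tx` — 1.19 mm, i.e. ≈55% of the full anterior
excursion inside the middle 40% of the cycle — is the proal signature:
anterior condylar translation concentrated in the power stroke.

Precision from a zero-motion trial:

```r
cad <- simulate_cadaver_trial(chew_model_params("A", head_motion_mm = 10,
                                                head_motion_deg = 10))
precision_analysis(cad)$precision
#> # A tibble: 6 × 3
#>   variable     ci n_frames
#>   <chr>     <dbl>    <int>
#> 1 rx       0.523      1000
#> 2 ry       0.528      1000
#> 3 rz       0.462      1000
#> 4 tx       0.0701     1000
#> 5 ty       0.0829     1000
#> 6 tz       0.0913     1000
```

Multi-individual reports (`chew_report()`) assemble the standard summary
table — individuals × 15 variables (6 condylar, 3 molar, 6 symphyseal) with
a workflow-CI row — and `write_report()` emits CSV plus a machine-readable
JSON with unrounded values and the configuration echo. `autoplot()` methods
draw per-joint traces and mean-cycle bands. A thin command-line wrapper
(`inst/cli/chew-pipeline.R`) exposes `simulate`, `analyze`, `precision` and
`report` verbs.

The methods vignette (`vignettes/jaw-kinematics.Rmd`) documents the model,
conventions, tunables, and the synthetic generator's assumptions.

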