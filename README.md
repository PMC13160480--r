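# uprom

Markerless upper-limb range of motion (ROM) from 2D pose landmarks, with
the agreement and reliability statistics used to validate such tools
against digital goniometry.

## The problem

Physiotherapists monitor arm recovery after stroke by measuring the
functional active ROM of the shoulder and elbow. Goniometers and
questionnaire scales need a trained assessor; video-based markerless
tools do not, which makes them attractive for clinics and for
telemonitoring of home exercises. A markerless pipeline turns each video
frame into named 2D pose landmarks (hip, shoulder, elbow, wrist, each
with a confidence score), computes joint angles from them, and reads a
per-repetition ROM off the angle trace. Before such a tool is used
clinically it must be validated: agreement with an accepted instrument
(Bland-Altman limits of agreement, ICC) and test-retest reliability
(ICC, SEM, MDC).

`uprom` implements that whole chain for R:

* **pose data** — a validated container for per-frame landmark
  coordinates and visibility (33-point whole-body topology names), CSV
  I/O, normalized-to-pixel conversion, and an adapter contract for any
  pose-estimation backend;
* **kinematics** — the interior joint angle at vertex B between rays to
  A and C,

  `theta = arccos( ((A-B).(C-B)) / (|A-B| |C-B|) )`,

  applied per frame (shoulder: hip-shoulder-elbow; elbow:
  shoulder-elbow-wrist), with visibility gating, gap interpolation and
  moving-average smoothing;
* **rom** — prominence-based repetition segmentation and per-repetition
  functional ROM (peak angle, or excursion from the resting baseline);
* **agreement** — `bland_altman()` (bias, SD of differences,
  `LoA = bias +/- 1.96 SD`, t-based bias CI, proportional-bias slope
  test), `icc21()` (two-way random effects, absolute agreement, single
  measure, with McGraw-Wong CI and the `F = MSR/MSE` test on
  `(n-1, (n-1)(k-1))` df), `SEM = SD sqrt(1-ICC)`,
  `MDC = SEM sqrt(2) x 1.96`, interpretation bands, and grouped report
  tables;
* **synthetic** — forward-kinematic simulators of task recordings with
  exact angle ground truth, and paired-rater / two-way ANOVA generators
  with known bias, LoA and population ICC;
* **cli** — `run_angles()`, `run_rom()`, `run_agree()`,
  `run_simulate()` plus a thin shell wrapper in `inst/cli/uprom`.

## Worked example

Simulate a lab recording of task 1 (arm abduction, three repetitions
with prescribed peaks 100, 105, 98 degrees, 2 px landmark jitter), then
recover the per-repetition ROM:

```r
library(uprom)

spec <- trajectory_spec(task_id = 1, peak_angles_deg = c(100, 105, 98),
                        noise_px = 2, seed = 42)
sim  <- simulate_task_trajectory(spec)
out  <- summarize_recording(sim$sequence, default_task_registry()[["1"]],
                            side = "right")
out$shoulder
#> <rom_summary> task 1 (arm abduction), right shoulder, lab
#>   repetitions: 3 of 3
#>   rom (deg): 99.59, 105.49, 98.67  mean: 101.25
```

The recovered peaks sit within a fraction of a degree of the prescribed
100/105/98: the angle computation inverts the simulator's forward
kinematics exactly, and the residual error is the landmark jitter that
survives the 5-frame smoothing window.

Agreement between two tools rating the same observations:

```r
p  <- simulate_rater_pairs(81, bias_deg = 0.76, diff_sd_deg = 1.25, seed = 1)
ba <- bland_altman(p$tool1, p$tool2)
ba
#> Bland-Altman agreement (n = 81)
#>   bias: 0.87 (SD 1.15; 95% CI 0.61 to 1.12)
#>   95% limits of agreement: -1.38 to 3.12
#>   proportional bias: slope -0.002 (p = 0.777)
icc21(cbind(p$tool1, p$tool2))
#> ICC(2,1), two-way random effects, absolute agreement, single measure
#>   ICC = 0.997 (95% CI 0.987 to 0.999) [excellent]
#>   F(80, 80) = 980.014, p = 1.11e-97
#>   subjects: 81  raters: 2
```

The bias and limits of agreement recover the generator's population
values (0.76 and 0.76 +/- 1.96 x 1.25 = -1.69 to 3.21) within sampling
error, and the ICC lands in the excellent band, as expected for two
tools whose disagreement SD is small against the between-subject
spread.

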