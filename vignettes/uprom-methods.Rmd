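---
title: "Models and methods behind uprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uprom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uprom)
```

`uprom` measures shoulder and elbow functional range of motion (ROM) from
2D pose-landmark time series and provides the statistics used to validate
such a tool against an accepted instrument. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
what the synthetic generators do and do not emulate, and the known
limitations.

## The joint-angle model

Every angle in the package is the *interior angle* at a vertex landmark B
between the rays to two adjacent landmarks A and C:

$$\theta = \arccos\!\left(\frac{(A-B)\cdot(C-B)}{\lVert A-B\rVert\,\lVert C-B\rVert}\right),$$

in degrees in $[0, 180]$. For the shoulder the vertex is the ipsilateral
shoulder with rays to the ipsilateral hip (trunk segment) and the elbow
(upper arm); for the elbow the vertex is the elbow with rays to the
shoulder and the wrist (forearm). The ipsilateral hip is used because the
trunk vector should belong to the measured side. Two consequences of this
choice matter in practice:

* **No anatomical re-zeroing.** The arm hanging parallel to the trunk
  reads roughly 0° at the shoulder; a fully extended elbow reads 180°.
  Both a markerless pipeline and a digital goniometer applied to the same
  frames measure this same geometric angle, so comparisons between tools
  are unaffected by the convention.
* **Pixel space is mandatory.** The formula is invariant to translation,
  rotation and *uniform* scaling — but pose backends emit coordinates
  normalized independently by image width and height, and that non-uniform
  scaling changes angles (only collinear triples are unaffected, since the
  map is linear). `normalize_to_pixels()` must therefore run before any
  kinematics, and the readers enforce it. Coordinates keep the image
  convention (origin top-left, y downward); the interior angle is
  indifferent to the y flip, so no axis correction is applied.

Numerically, the cosine is clamped to $[-1, 1]$ so that near-collinear
triples never produce a domain error; an overshoot beyond $10^{-9}$
indicates corrupted input and raises instead of being silently absorbed.
A zero-length ray (two coincident landmarks) is a degenerate-geometry
error at the single-triple level and an invalid (flagged) sample at the
series level.

## From landmarks to a usable angle trace

Frames are never dropped. Three stages, in order:

1. **Visibility gating** (`gate_by_visibility`): a sample is valid only
   if all three contributing landmarks reach the visibility threshold.
   Default 0.5 — the conventional midpoint of a pose backend's confidence
   scale.
2. **Gap bridging**: interior runs of at most `max_gap_frames` invalid
   samples between two valid neighbours are linearly interpolated and
   flagged `interpolated`. Default 5 frames (about 0.17 s at 30 fps):
   long enough to bridge single-frame detection flickers, short enough
   never to invent movement. Longer gaps stay invalid.
3. **Smoothing** (`smooth_series`): a centered moving average over valid
   samples only. Default window 5 frames; at 30 fps this suppresses
   landmark jitter while attenuating a 4-second movement bump by well
   under 0.2°. Window 1 disables smoothing; even windows are rejected.

## Repetition segmentation and the ROM readout

The assumed protocol is a small number of repetitions (default 3) of one
task per recording, separated by rest periods of the order of 10 s.
Segmentation (`segment_repetitions`) finds local extrema by *topographic
prominence* — height above the higher of the two key saddles toward
higher ground — which is robust to baseline drift and to jitter in a way
plain height thresholds are not. Defaults: prominence at least 10°,
separation at least 5 s (half the nominal rest, permissive toward rushed
home recordings). Joints whose functional extremum is a minimum (elbow
flexion: a deeper flexion is a smaller interior angle) are handled by
negating the trace. Segment boundaries fall at the lowest point between
adjacent kept peaks.

When fewer qualifying peaks exist than expected, the result carries a
mismatch flag rather than raising: imperfect home recordings are a normal
operating condition, and the tool must degrade gracefully.

The per-repetition readout (`peak_rom`) defaults to `mode = "peak"`, the
extremal angle reached in the segment — the clinically conventional
"maximal functional angle" — with `mode = "excursion"`
(|extremum − baseline|, baseline being the median of the rest portion of
the segment) available where a change-from-rest measure is wanted. The
task registry maps task ids to measured joints (task 1: shoulder only;
tasks 2–4: shoulder and elbow) and per-joint extremum directions; it is
an ordinary configurable list, since task numbering conventions vary
between protocols.

## Agreement and reliability statistics

For paired measurements of the same observations by two tools:

* **Bland-Altman** (`bland_altman`): bias = mean difference, SD of
  differences with the $n-1$ denominator, and
  $\mathrm{LoA} = \text{bias} \pm 1.96\,\mathrm{SD}$. The multiplier is
  the Normal $z$ = 1.96, matching the convention of the validation
  literature this package serves, not a $t$ quantile. The bias CI *does*
  use the $t$ quantile on $n-1$ df (the more conservative choice; at
  $n \approx 80$ the two differ only in the third decimal). Proportional
  bias is operationalized as the least-squares slope of differences on
  pair means with a two-sided t-test, flagged at $p < 0.05$.
* **ICC(2,1)** (`icc21`): two-way random-effects ANOVA, absolute
  agreement, single measurement:
  $$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},$$
  with the McGraw–Wong confidence interval and $F = MS_R/MS_E$ on
  $(n-1,\,(n-1)(k-1))$ df — for $k = 2$ tools that is $(n-1, n-1)$.
  No multiple-testing correction is applied; p-values are reported raw.
* **SEM and MDC**: $\mathrm{SEM} = \mathrm{SD}\sqrt{1-\mathrm{ICC}}$ and
  $\mathrm{MDC} = \mathrm{SEM}\cdot\sqrt{2}\cdot 1.96$. The "SD" entering
  the SEM is not uniquely defined in the reporting tradition; the default
  is the pooled SD of all measurements in the group (across repetitions
  and tools), with per-tool SDs available via `sd_method`, and every
  report echoes the SD it used (`sd_used`).
* **Interpretation bands**: excellent $[0.81, 1.0]$, good
  $[0.61, 0.80]$, moderate $[0.41, 0.60]$, fair $[0.21, 0.40]$, poor
  below 0.20. The printed edges leave tiny gaps (e.g. 0.805); gaps are
  assigned to the lower band, so the rule is simply `icc >= 0.81` is
  excellent, `icc >= 0.61` good, and so on.

Test-retest reliability (`reliability_report`) treats the $k$ repetitions
of each subject as the "raters" of the two-way design, following the
three-independent-measures protocol.

Grouped reports keep full precision internally and in their CSV/JSON
output; rounding to 2 decimals happens only in the print methods. Groups
with fewer than 3 complete pairs are reported as skipped with a reason,
never silently dropped.

## The synthetic generators

`simulate_task_trajectory` builds a planar kinematic chain — hip fixed,
shoulder `trunk_px` above it, elbow placed at the prescribed shoulder
angle from the trunk vector, wrist at the prescribed elbow angle from the
upper-arm vector — and animates it with raised-cosine bumps, chosen
because they are smooth, compactly supported and have an analytically
known peak. Gaussian pixel noise and visibility dropout are applied
*after* exact placement, modelling landmark jitter rather than kinematic
noise, so the returned ground-truth series are exact and the
forward-placement-then-angle-computation round trip is an exact inverse
(the central oracle pairing the kinematics and synthetic modules). For
tasks that do not measure the elbow, the elbow is held at 175° so
single-joint tasks stay clean.

Defaults describe a plausible consumer recording — 30 fps, 1920×1080,
subject at arm's length from a phone camera: trunk 250 px, upper arm
180 px, forearm 160 px, 3 repetitions, 10 s rest, 4 s bumps. The source
protocol did not fix frame rate or resolution, so these are configuration
values, not assumptions about any particular study. Chains that would
leave the frame are rescaled with a warning.

What the generator does *not* emulate: out-of-plane (3D) motion and
perspective, compensatory trunk rotation, autocorrelated or
heteroscedastic landmark noise, occlusion that correlates across
landmarks, and soft-tissue artefact. Passing round-trip tests therefore
demonstrates the correctness of the geometry, gating, segmentation and
statistics — not robustness to the ways real video deviates from a
planar chain.

`simulate_rater_pairs` and `simulate_two_way` generate paired-tool and
two-way ANOVA data with known population bias, LoA and
$\mathrm{ICC} = \sigma_s^2/(\sigma_s^2+\sigma_r^2+\sigma_e^2)$. All
generators are deterministic under a fixed seed and record it.

## Numerical and statistical caveats found during development

* **Finite-$k$ ICC behaviour.** With only $k = 2$ raters the two rater
  effects are a single draw per panel: the ICC(2,1) estimate of one
  panel scatters around the population ratio with SD ≈ 0.05 even at
  $n = 5000$, and at low population ICC a small positive Jensen-type
  bias (≈ +0.03 at ICC 0.5) remains that does not vanish with $n$. In
  the high-reliability regime this package targets (ICC ≥ 0.8) the bias
  is below 0.01. Estimator-recovery checks therefore average over
  replicate panels; a single panel cannot be held to a ±0.02 bound.
* **Peak-frame identifiability under jitter.** A raised-cosine top is
  locally flat: with 2 px landmark jitter the residual angle noise after
  smoothing (≈ 0.5°) exceeds the per-frame curvature drop near the peak,
  so the peak *frame* wanders by several frames even though the peak
  *value* is recovered to well under a degree on average (measured mean
  worst-repetition error 0.63° per recording; about 9% of recordings
  exceed 1°). Tests assert exact frame recovery only in the noise-free
  case and value recovery on averages over recordings.
* **Smoothing at series edges** uses the available part of the window
  (shrinking average), which slightly underweights smoothing in the
  first and last two frames; repetitions never start at the very edge
  under the supported protocols.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make Monte-Carlo noise
small against the asserted tolerances: Bland-Altman recovery and LoA
coverage at $n = 10^5$ pairs; ICC recovery on 100 panels of
$5000 \times 2$; CI coverage on 2000 replicates at $n = 30$; kinematics
round trips on 52-second recordings at 30 fps (1560 frames). The full
suite completes in well under a minute on one core.

## Known limitations

The pipeline is strictly 2D: no depth, no out-of-plane correction, so
movements with substantial rotation out of the camera plane will read
differently than a 3D system would. Trunk-compensation quantification,
movement-smoothness metrics and automatic task recognition are out of
scope. The pose-estimation backend itself is outside the package: it is
reached only through the adapter contract of `from_pose_backend()`, and
frames the backend fails on are carried as all-invisible rather than
dropped.
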