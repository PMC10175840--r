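---
title: "Methods: CO2-evoked calcium and locomotion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CO2-evoked calcium and locomotion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemoresponse)
```

`nemoresponse` quantifies how *C. elegans* responds to an acute CO2 pulse
at two levels: neural activity, measured by ratiometric (FRET) calcium
imaging of identified neurons, and motor output, measured from centroid
trajectories of freely moving animals. This vignette documents the models,
the defaults and why they were chosen, the numerical conventions, and what
the synthetic-data generators do and do not emulate.

## Stimulus protocols

Every recording is described by a `stimulus_protocol`: contiguous,
half-open gas segments (air / pulse / air) on a fixed frame grid. The
standard behavioral protocol is a 20 s air pre-pulse, a 60 s CO2 pulse
(2.5% CO2, 21% O2, balance N2), and a 40 s post period at 5 frames/s; the
imaging protocol uses a 30 s baseline, a 60 s pulse of 15% CO2, and a 60 s
post period at 2 frames/s. An air control replaces the pulse with air of
equal duration while retaining the pulse clock times, so every analysis
window can be matched between conditions.

Acquisition rates and the imaging pulse duration are exposed in the run
config rather than hard-coded: the defaults above (2 fps imaging, 5 fps
behavior, 60 s pulses) are documented package choices at the time scale
typical for this kind of recording, not measured properties of any
particular rig.

All windows in the package are half-open, `[start_s, end_s)`, evaluated
against frame timestamps. This makes windows tile without double-counting
and makes every boundary decision reproducible.

## Calcium model and %dR/R0

A FRET indicator reports calcium as the acceptor/donor emission ratio
`R = acceptor / donor`. The package computes, per animal,

```
dR/R0 (%) = 100 * (R(t) - R0) / R0
```

with `R0` the mean ratio over a pre-pulse baseline window (default: the
pre-pulse segment minus its first 2 s, which discards settling). Because
both channels share gain, focus drift, and bleaching, the ratio cancels
them; this invariance is asserted exactly in the tests.

The simulator generates the ratio as `r0 * (1 + s * A/100 * k(t))`, where
`s` is +1 (excitatory), -1 (inhibitory) or 0 (silent), `A` the amplitude
in percent, and `k(t)` a unit bump with a linear rise (default 3 s) and
exponential decay (default tau = 10 s) starting at pulse onset plus a
latency (default drawn uniformly from 1-3 s). The kernel shape is a
package choice: the analysis only requires a smooth rise-and-decay
transient, and the analytic peak of the kernel provides an exact oracle
for the peak-extraction code. Responses that begin after pulse offset
(as for the post-pulse inhibition seen in dauer RIG) are generated with
`post_offset = TRUE`, and the default response window runs from pulse
onset to 30 s past offset to capture them.

Channel noise is multiplicative Gaussian per channel (default SD 1% of
signal), independent between donor and acceptor; bleaching is a shared
exponential (default off). The ratio cancels the shared part; the
residual two-channel noise, about sqrt(2) x 1% per frame on dR/R0, is
what the downstream classification must tolerate.

## Response classification against an air-control null

A response is called excitatory or inhibitory when its magnitude exceeds
`k` standard deviations (default `k = 3`) of the response measured in air
controls. "The response" needs an operational definition; the package
uses the per-animal *signed extremum* of dR/R0 over the response window
(the value of largest magnitude). The null SD is the sample SD (n-1) of
that same statistic across air-control animals. A stimulus animal is then

* excitatory if `max > k * sd` and `max >= |min|`,
* inhibitory if `|min| > k * sd` and `|min| > max`,
* silent otherwise.

Magnitude ties above threshold classify excitatory; the tie has
probability zero under continuous noise and the rule makes the
classifier a deterministic function of its inputs. A null fitted from
identical controls (`sd = 0`) is flagged with a degenerate-null warning,
since any nonzero response then classifies as non-silent.

Because the extremum of ~100+ noise frames concentrates well above the
per-frame noise SD, a 3-SD-of-extremum threshold is a conservative test:
its false-positive rate on null traces is near zero. The calibration test
verifies this against an independent 1e5-draw Monte-Carlo oracle of the
extremum distribution and checks that the non-silent rate is monotone
non-increasing in `k` over 1..5. Whether per-frame or per-animal
statistics were used in the original assays is not stated at this level
of detail anywhere accessible; the extremum convention is therefore a
documented package default, switchable via `statistic` in
`fit_air_null()`.

## Heatmap ordering

Per-animal dR/R0 vectors are ordered by agglomerative hierarchical
clustering (Euclidean distance, average linkage by default, via
`stats::hclust`). Dendrogram leaf order is not unique, so the package
canonicalizes it: at every merge, the subtree containing the
alphabetically smallest animal id leads. This makes the ordering
deterministic and invariant to the order traces are supplied in. An
optimal-leaf-ordering refinement was considered and not adopted: no
installed implementation exists here, and the canonical order already
satisfies the properties the figures need (distinct responders segregate
to an end; reproducible output).

## Locomotion model

The generator runs a continuous-time Markov jump process over
forward / reverse / pause with piecewise-constant rates: `baseline`
outside the stimulus epoch and `stimulus` inside it. The epoch is the
pulse segment, optionally truncated `adapt_s` seconds after onset
(rates revert to baseline while gas is still flowing — behavioral
adaptation) and optionally extended `carry_over_s` past offset. Position
integrates per-state speed (Gaussian, truncated at zero) along a heading
that diffuses (default 0.1 rad^2/s); reversal flips the effective heading
by pi. Trajectories carry `n_frames + 1` position fenceposts so the
`n_frames` displacement steps tile `[0, duration)` exactly.

Two presets express the life-stage contrast observed in CO2-evoked motor
output:

* `dauer_like`: pause-entry rates strongly elevated for the whole pulse
  (forward-to-pause 0.6/s vs 0.02/s at baseline), producing prolonged
  near-arrest;
* `adult_like`: moderately elevated reversal and pause rates with
  `adapt_s = 20`, producing a transient slowdown confined to the first
  20 s of the pulse.

Baseline rates (forward-dominant, mean forward sojourn of about 14 s) and
speeds (forward 0.15 mm/s, reverse 0.12 mm/s, pause ~0) are package
choices at the scale typical of crawling worms on agar; they are
documented defaults, not inferences about any particular tracker's
output.

## Trajectory analysis

*Instantaneous speed* is framewise displacement over the frame interval,
with the sample assigned to the later frame and an optional centered
moving average (default 1 s; edges use truncated windows, so constant
speed is a fixed point). *Mean speeds* are reported for the first 20 s of
the pulse and for the 20 s window starting 30 s after onset — the two
windows in which the life-stage difference manifests: transient slowing
recovers before the late window, sustained slowing does not.

*State segmentation* works from centroid data only. Frames slower than
`pause_speed_mm_s` (default 0.02 mm/s) are pauses. Moving frames start
forward and toggle forward/reverse when the heading deviates more than
`reversal_angle_deg` (default 120 degrees) from a smoothed reference
heading of the current bout (exponential moving average, weight 0.25),
which then resets. Bouts shorter than `min_bout_s` (default 0.6 s) are
merged into their longer neighbor, shortest first, earlier bout on ties.
A body-orientation tracker could label reversals directly; from centroids
the sustained-heading-flip heuristic is the standard substitute, and all
thresholds are exposed. The defaults were fixed once against the
generator's geometry (a true reversal flips heading by ~180 degrees;
120 degrees leaves margin for curvature) and validated by the
ground-truth recovery test (>= 99% framewise agreement with jitter
disabled) — the segmentation is not tuned per dataset.

*Time ratios* over a window partition it among the three states. The
pause ratio is computed as the complement of a Fast2Sum-compensated
forward + reverse, so the three ratios sum to exactly 1 in floating
point, including under long-double accumulation. *Straight-line
distance* is the net displacement between the first and last positions
in the window; *reverse distance* sums displacement magnitudes over
steps labeled reverse. All metrics are invariant to rigid rotation and
translation of the coordinate frame.

## Chemotaxis and the statistics harness

The chemotaxis index is `(n_test - n_control) / (n_test + n_control)`,
the standard two-region assay index, bounded in [-1, 1] and antisymmetric
under swapping counts. Worms scored at the origin, if recorded, are
excluded by the caller before constructing counts.

Group comparisons delegate to the standard implementations: Welch's t
(`t.test`), Mann-Whitney (`wilcox.test`, exact when sample sizes permit
and there are no ties), Kruskal-Wallis (`kruskal.test`), one- and two-way
ANOVA (`aov`), Fisher's exact test (`fisher.test`), and Dunnett's
posttest (`multcomp::glht`). Two procedures are implemented in the
package because no installed implementation exists: Dunn's posttest
(pairwise rank-sum z with tie correction, Bonferroni-style adjustment
over the tested pairs) and the Sidak posttest after two-way ANOVA
(cell-mean contrasts on the pooled residual mean square,
`p_adj = 1 - (1 - p)^m`). All p-values are two-sided; adjusted p-values
never fall below raw ones. Test selection is explicit in the run config —
there is no automatic parametric/nonparametric switching.

Calibration: each test path is run under its null 1e4 times and its
rejection rate at alpha = 0.05 checked against nominal within 3 binomial
SEs. The designs were chosen by exact or asymptotic size computation so
that discreteness does not dominate: Welch 10+10, exact Mann-Whitney 8+8
(exact size 0.0499), Kruskal-Wallis 3x15, one-way F 3x10, two-way
interaction F at 6/cell, and Fisher on 1000-worm margins. Fisher's exact
test is intrinsically conservative; 1000-per-group margins give its size
closest to nominal (0.0466 by exact computation). With small tables its
true size is far below 0.05 — a property of the test, not a defect of the
harness.

## Randomness and reproducibility

Every simulator takes a seed; cohorts derive one child seed per animal
from `(root seed, animal index)` with a fixed affine map modulo 2^31 - 1,
so a cohort is reproducible as a whole and each animal individually, and
growing a cohort leaves earlier animals unchanged. The pipeline derives
per-stream seeds from the root seed the same way. Re-running a config
with the same seed reproduces bit-identical CSV outputs (checksummed in
the run manifest); figures are identical up to PNG metadata.

## Problem sizes used in verification

The shipped verification suite uses: 200 randomized cases per brute-force
oracle; 200 air controls, 2000 test traces, and a 1e5-draw oracle for
null calibration; 200 animals for class recovery (amplitudes 25-40%,
at least 5 null SDs); 30 animals for state-label agreement and
5 x 50 animals for the pause-rate sweep; 1e4 replicates per test-size
check; and 100 replicates of 4 x 20 animals for the life-stage speed
contrast. These sizes give the binomial error bands quoted in the tests
while keeping a full run in the minutes range on one core.

## What the generators do and do not emulate

The generators reproduce the statistical structure the analysis consumes:
stimulus-locked transients of either sign with variable amplitude and
latency (including post-offset responses), state-switching locomotion
whose rates change at pulse onset, and binomial assay counts. They do not
emulate body posture (no skeletons or eigenworms), gas diffusion or
receptor kinetics, slow behavioral drift, tracking artifacts (collisions,
lost frames), or non-Gaussian imaging noise. Passing the recovery tests
therefore demonstrates that the analysis chain is correct and calibrated
under its stated assumptions — not that those assumptions hold for any
particular real recording.

## Known limitations

* Reversal detection from centroids cannot distinguish a true reversal
  from a fast in-place omega turn; posture-level taxonomy is out of
  scope.
* The empirical-null classification is conservative by construction
  (extremum statistic); small sustained responses below ~3 null SDs are
  called silent.
* The two-way ANOVA Sidak posttest assumes homoscedastic cells (pooled
  MSE), matching standard practice but not robust to strong variance
  heterogeneity.
* Air-control matching assumes identical protocol timing between
  stimulus and control recordings; the pipeline validates this and
  refuses mixed timings.
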