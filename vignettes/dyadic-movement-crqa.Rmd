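---
title: "Quantifying dyadic movement coordination with categorical cross-recurrence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic movement coordination with categorical cross-recurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two people working on a joint task at a table continuously adjust their body
position relative to each other. Three aspects of that non-verbal dynamic
carry information about their attitude toward one another:

* **spatial distance** — how close they keep (approach vs avoidance);
* **leading** — whose movements tend to come first, and by how much;
* **coordination and coupling** — how tightly one person's movements are
  echoed by the other.

`dyadcrqa` implements a complete pipeline for measuring all three from
markerless pose-estimation output (DeepLabCut-style coordinate exports) for
a dyad filmed from the side: a *participant* and an *assistant* seated on
opposite sides of a table, recorded at 30 fps in a 1280 x 720 px frame.

# From coordinates to primitives

```{r, eval = FALSE}
library(dyadcrqa)
p <- read_pose_table("dyad01_participant.csv", person_id = "participant")
a <- read_pose_table("dyad01_assistant.csv", person_id = "assistant")
dyad <- dyad_track(p, a, dyad_id = "dyad01", group = "high")
```

**Median filtering.** Pose estimators occasionally misplace a landmark for a
single frame. Each coordinate channel is passed through a centred running
median of window 7 frames (`median_filter_track()`), which deletes
one-frame outliers while leaving genuine movement intact. At the series
edges the window shrinks symmetrically to the available neighbourhood; this
choice avoids padding artefacts and leaves the first and last frames
untouched. Filtering is applied per channel (x and y independently), and
before any derived quantity, so the distance series inherits it.

**Spatial distance.** `nose_distance()` is the per-frame Euclidean distance
in pixels between the two nose landmarks — the head is the least occluded,
most reliably tracked part, and head position captures the leaning
forward/backward that matters for approach and avoidance.

**Movement categorisation.** `categorize_movement()` reduces each head
trajectory to one symbol per frame transition: `NONE` when the 2-D
Euclidean displacement is below a radius (default 0.1 px), otherwise `LEFT`
or `RIGHT` by the sign of the horizontal displacement. Direction is defined
horizontally because, in the side-camera geometry, approaching the table is
a horizontal movement. A supra-threshold displacement with exactly zero
horizontal component is assigned `NONE`; exact ties have measure zero on
real coordinates and arise only in constructed data. The radius is the most
sensitive tunable of the whole pipeline (small radii let camera noise
register as movement; large radii erase subtle movements), so it is
exposed everywhere; a radius sweep is a one-liner:

```{r, eval = FALSE}
sapply(c(0.05, 0.1, 0.5, 1), function(r) {
  s <- categorize_movement(p, cfg = motion_config(radius = r))
  mean(s$symbols == "NONE")
})
```

**Mirroring.** Because the two people face each other, approaching the
table moves the participant rightward in the image but the assistant
leftward. `mirror_series()` swaps `LEFT`/`RIGHT` in the assistant's series
so that complementary approach (or lean-back) movements count as matches.

# Categorical cross-recurrence

With two aligned symbol series, the cross-recurrence plot marks cell
`(i, j)` when the participant's symbol at transition `i` equals the
assistant's at `j`. All quantities are computed without materialising the
matrix (run-length and per-diagonal identities), and the test suite checks
them for exact agreement against a brute-force full-matrix enumeration.

**Diagonal lag profile** (`lag_profile()`). The recurrence rate along the
diagonal at lag `k` frames is the fraction of frames where the
participant's symbol `k` frames *later* matches the assistant's current
symbol, normalised by the `n - |k|` comparisons actually available (so the
profile does not decay artificially toward the window edges). By this
construction a follower copying the participant `d` frames later produces a
peak at lag `-d`: negative lags mean the participant leads. The sign
convention is the most error-prone part of the method, so it is pinned by
simulator-based tests that plant a known lag and recover it end to end.
The default window is ±3 s (181 lags at 30 fps). Min–max normalisation
(`normalize_profile()`) is provided for display only; every statistic
operates on raw rates, because rescaling per dyad would distort
between-group rate comparisons.

**Surrogate baseline** (`shuffle_baseline()`). The profile is compared
against the same computation after randomly permuting the assistant's
symbols (default 100 permutations, seeded). Permutation preserves symbol
frequencies but destroys temporal structure, so it estimates the
chance-matching level inherent in the task and symbol distribution.

**CRQA measures** (`crqa_measures()`). Recurrence rate (RR), mean diagonal
line length (MeanLine), vertical and horizontal trapping times (TT_V,
TT_H), and the block-area categorical entropy (CatEnt): in a categorical
plot the recurrences form rectangles (runs of a shared symbol in each
series), and CatEnt is the Shannon entropy (natural log) of the
distribution of rectangle areas — low when coordination episodes have
stereotyped durations, high when their durations vary. Area-1 blocks are
included by default; a `min_area` parameter is exposed because reasonable
implementations differ on whether single-cell blocks constitute a
"pattern". The minimum line length is `lmin = 2` (the standard recurrence
default), and the main diagonal is included in MeanLine (for cross
recurrence between two distinct systems it is not a trivial self-match; a
toggle exists). Degenerate plots with no lines report 0 with an explicit
`lines_defined` flag rather than erroring, so batch runs survive degenerate
dyads.

# Profile statistics and group comparisons

**Density moments** (`profile_moments()`). Treating the profile as a
density over lags yields dispersion (weighted SD, in seconds), skewness,
and *non-excess* kurtosis (Gaussian = 3, continuous uniform = 1.8). Higher
kurtosis and lower dispersion mean recurrence concentrated in a narrow lag
band — punctual, effective coordination. The non-excess convention is used
because empirical profile kurtosis values for weakly peaked profiles sit
between the uniform (1.8) and Gaussian (3.0) values, where the "higher
kurtosis = sharper coordination" reading is coherent. Dispersion is
reported in seconds; when comparing against values computed elsewhere note
that lag-bin units differ by a factor of the frame rate.

**Blocks and tests.** Distance series are compared in 15-s blocks and lag
profiles in 0.5-s lag bands (`block_means()`); a trailing partial block is
kept only if at least half full — with the ±3-s grid of 181 lags this
yields 12 full 15-lag bands, the single leftover lag (+3 s) being dropped.
Between-group comparisons use the rank-sum test (`mann_whitney()`: midrank
ties, per-group U and mean ranks, exact p for small untied samples, else
tie-corrected normal approximation). Paired original-vs-surrogate
comparisons within a dyad use the signed-rank test
(`wilcoxon_signed_rank()`). Note that a signed-rank test is only defined
for paired data; between groups of unequal size the rank-sum test is the
applicable choice, and that is what `blockwise_group_test()` uses there.
No multiple-testing correction is applied across blocks by default,
matching common reporting practice for exploratory blockwise maps; a
Benjamini–Hochberg option is behind `p_adjust = "BH"`.

`run_study()` orchestrates everything per dyad and per group,
deterministically for a fixed configuration seed, and optionally writes
tidy CSV tables plus a run log echoing every parameter.

# The synthetic coupled-dyad generator

Real interaction videos cannot be redistributed, so validation rests on a
generator (`simulate_dyad_categorical()`, `simulate_dyad_coordinates()`,
`simulate_group_study()`) that emulates the statistical structure the
analysis assumes, with known ground truth:

* the participant (leader) emits `LEFT`/`RIGHT`/`NONE` symbols from a
  first-order persistence chain (default persistence 0.3, mild
  autocorrelation; stationary marginals equal `symbol_rates`);
* the assistant (follower) copies the leader's movement — sign-flipped, so
  the mirroring rule is exercised — `lead_lag` frames later with
  probability `fidelity`, and otherwise moves independently (keeping the
  chance-matching rate analytic at `sum(rates^2)`);
* at the coordinate level the leader's nose performs a mean-reverting
  (AR(1), reversion 0.005/frame) walk of ~1-px steps plus a slow sinusoidal
  lean-in excursion; all six body parts ride on the nose at fixed offsets;
  Gaussian jitter of sd `noise_sd` is added to every emitted coordinate.

Defaults encode the study conditions the pipeline targets: 16 high vs 12
low dyads, 9000 frames (5 min at 30 fps), 1280 x 720 px. Values the design
does not fix were chosen once on plausibility grounds: planted lead lags of
11 and 22 frames (≈ 370 and 730 ms, the order of observed leader lags in
dyadic tasks), nose separations of 150 and 220 px for two seated people in
a 1280-px frame, coupling fidelities 0.95 and 0.85, steps of 1 px/frame
(head movement between consecutive frames is typically below a pixel), and
measurement jitter of 0.5 px.

What the generator does **not** emulate: biomechanics (posture, limb
kinematics), tracking failures beyond Gaussian jitter, non-stationary
strategy changes over the task, and vertical movement structure. Passing
tests therefore demonstrate that the machinery recovers planted coupling
structure under realistic noise — not that any particular empirical
finding about human dyads is reproduced.

# Numerical choices and degenerate inputs

* Lag rates divide by `n - |k|` valid comparisons (edge-corrected).
* `peak_lag()` tie-breaks toward the smallest absolute lag, then the
  negative one; a flat profile reports 0 s.
* Zero-mass profiles and point-mass dispersion are errors / `NA` rather
  than silent zeros in `profile_moments()`.
* Exactly vertical supra-threshold displacements categorise as `NONE`.
* Surrogate and pipeline seeds derive deterministically from the
  configuration seed (per-dyad offsets), so identical configurations give
  byte-identical outputs.
* Empty recurrence plots report measures of 0 with `lines_defined` flags.

# Problem sizes used in the shipped tests

The validation suite runs the full study scale where it matters (lag
recovery and planted-effect propagation use 9000-frame dyads, 16 vs 12
dyads for the group study) and reduced scales where only calibration is at
stake (null false-positive calibration uses 1000 simulated studies of
1800-frame dyads; surrogate validation uses 3000-frame dyads with 20
permutations). These sizes are the package's own validation design and are
stated here so they can be scaled up when exploring.

# Known limitations

* The 0.1-px radius sits below typical pose-estimation error; the
  categorisation is deliberately faithful to that convention but users
  should sweep the radius before interpreting differences.
* Leading is summarised from the lag profile; it localises the typical
  leader lag but cannot count discrete leadership episodes.
* The blockwise maps are uncorrected for multiplicity by default.
* Dispersion/kurtosis/skewness of weakly peaked profiles are dominated by
  the chance plateau; differences between groups are meaningful only
  relative to a surrogate baseline, which is why the pipeline always
  carries one.
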