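# dyadcrqa

Categorical cross-recurrence analysis of dyadic movement dynamics.

## What it is for

When two people perform a joint task at a table, their body movements carry
non-verbal markers of their attitude toward each other: how close they keep
(**spatial distance**), whose movements come first (**leading**), and how
tightly one person's movements echo the other's (**coordination** and
**coupling**). `dyadcrqa` measures all of these from markerless
pose-estimation exports (DeepLabCut-style CSV tables: per-frame `x`, `y`,
`likelihood` for named body parts of each person), for researchers in
social/behavioral science analysing dyadic interactions recorded on video.

## The method

For each dyad, head (nose) trajectories are median-filtered (window 7) and
reduced to two primitives:

* the per-frame Euclidean **nose-to-nose distance** in pixels;
* a **categorical movement series** per person — one symbol per frame
  transition, `NONE` if the 2-D displacement is below a radius (default
  0.1 px), else `LEFT`/`RIGHT` by the sign of the horizontal displacement —
  with the assistant's series mirrored so complementary approach movements
  match.

Coupling is quantified by categorical cross-recurrence quantification
analysis (CRQA). With participant series *p* and mirrored assistant series
*a* of length *n*, a cell (i, j) of the cross-recurrence plot is recurrent
when `p[i] == a[j]`. The **diagonal lag profile** is

    RR(k) = #{ t : p[t + k] = a[t] } / (n − |k|),   k = −3 s … +3 s,

so a follower copying the leader *d* frames later peaks at lag −*d*:
negative lags = participant leading. Profiles are compared against shuffled
**surrogate baselines** (random permutations of the assistant's symbols),
summarised as density moments over lags (peak lag, dispersion, skewness,
non-excess kurtosis), and complemented by the plot-level measures RR,
MeanLine, TT_V, TT_H, and the block-area categorical entropy CatEnt.
Group comparisons use blockwise rank-sum tests (15-s distance blocks,
0.5-s lag bands) and paired original-vs-surrogate signed-rank tests.

A seeded simulator of coupled leader–follower dyads (known lead lag,
coupling fidelity, separation and noise) generates both symbol-level and
full coordinate-level data, and is what the validation suite uses in place
of the original (unavailable) videos.

## Worked example

```r
library(dyadcrqa)

study <- simulate_group_study(
  n_high = 4, n_low = 4,
  cfg_high = sim_config(n_frames = 3000, lead_lag = 11, fidelity = 0.95, separation = 150),
  cfg_low  = sim_config(n_frames = 3000, lead_lag = 22, fidelity = 0.85, separation = 220),
  seed = 7)
res <- run_study(study, run_config(n_shuffles = 20, seed = 7))
res
#> <dyad_study_result> 8 dyads (4 high / 4 low)
#>   distance high vs low: U = 0, p = 0.0286 (significant)
#>   high: peak lag -0.367 s, kurtosis 1.849, dispersion 1.717 s
#>   low: peak lag -0.733 s, kurtosis 1.833, dispersion 1.721 s

res$dyads[[1]]$profile
#> <lag_profile> lags -3..3 s (181 bins), max rr 0.6489 at -0.3666667 s

res$dyads[[1]]$measures
#> <crqa_measures> rr=0.3398 mean_line=2.919 tt_v=3.546 tt_h=3.504 cat_ent=2.417
```

Reading the output: the planted group difference in seating distance is
detected (U = 0 means complete separation of the 4-vs-4 group values;
exact p = 0.0286). Both groups are participant-led (negative peak lags),
and the "high" group's planted 11-frame lead lag is recovered at
−0.367 s against −0.733 s for the planted 22 frames of the "low" group.
The first dyad's lag profile peaks at rr = 0.65 — well above the ~0.34
chance-matching plateau — and its CRQA measures summarise the plot
structure (e.g. matched movement episodes last 2.9 frames on average).

To analyse real pose exports instead, pass `run_study()` a manifest
`data.frame` with columns `dyad_id`, `participant`, `assistant` (paths to
pose tables) and `group`.

## Layout

* `R/` — pose-table I/O and filtering, kinematics (distance,
  categorisation, mirroring), CRQA core (profiles, surrogates, measures),
  profile statistics and rank tests, the coupled-dyad simulator, and the
  `run_study()` orchestrator.
* `tests/testthat/` — unit and property tests, including exact agreement
  of every CRQA quantity with a brute-force full-matrix oracle, and
  end-to-end validation on seeded simulations.
* `vignettes/dyadic-movement-crqa.Rmd` — the methods vignette: model,
  conventions, tunables, simulator design, numerical choices, limitations.
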