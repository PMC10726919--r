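---
title: "Video actigraphy sleep scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video actigraphy sleep scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcam)
```

`sleepcam` scores mouse sleep from home-cage video. The chain is: frames
→ foreground-pixel motion trace → thresholded activity → immobility-rule
hypnogram → per-hour sleep times → Bland–Altman agreement against an
EEG/EMG reference. This vignette explains each model, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the method left room.

## The motion detector

The detector is a sample-based background subtractor. Pixel `x` keeps
`n_samples = 20` previously seen intensities; in a new frame it is
*background* when at least `min_matches = 2` stored samples lie within
`match_radius = 20` intensity units (inclusive) of its current value, and
*foreground* ("the mouse moved here") otherwise. Background pixels refresh
their model stochastically: with probability `1/subsample_factor`
(`subsample_factor = 16`) they overwrite one random own sample with the
current value, and with the same probability one random sample of a random
8-neighbour. The model is initialised by sampling, for every pixel, 20
values from its 8-neighbourhood in the first frame (clamped at borders),
and the first `burn_in_s = 2` seconds of frames update the model without
contributing counts. These are the canonical defaults of the algorithm
family; all are exposed in `vibe_params()`.

Two deliberate choices deserve notice:

* **Inclusive matching.** A sample at exactly `match_radius` from the pixel
  value counts as a match. The boundary must be defined somewhere for the
  classifier to be testable; inclusive matches err towards background.

* **Static-foreground absorption (`absorb_after`).** Under the purely
  conservative update, foreground pixels never touch the model, so an
  animal that stops moving would remain "foreground" indefinitely — its
  whole silhouette would be counted as motion for as long as it sleeps, and
  the ghost it leaves after walking away would erode only by neighbour
  diffusion, roughly one pixel layer per `5 * subsample_factor` frames. A
  sleep monitor cannot work that way: immobility is precisely the signal.
  `sleepcam` therefore absorbs any pixel that has been foreground for
  `absorb_after` consecutive frames (default `5 * subsample_factor = 80`
  frames, i.e. 16 s at 5 fps) by seeding `min_matches` of its model slots
  with the current value. This is the standard "static foreground counter"
  extension of the algorithm family. Setting `absorb_after = Inf` restores
  the pure conservative behaviour. The default is chosen well below the
  shortest immobility rule (35 s), so absorption can never erase genuine
  wake activity, and well above the frame-to-frame dwell of a walking
  mouse, so locomotion is never absorbed.

Absorption has a visible, well-understood signature: at each sleep onset
the settled silhouette is still counted as foreground for
`absorb_after / fps` seconds before the model accepts it. Sleep onsets are
therefore detected late and never early, so the video systematically
*under*-scores sleep a little — the conservative direction for a sleep
assay. Exact bin-level identity with the truth is consequently impossible
through rendered video for any causal detector of this type; agreement
converges to 100% only at the trace level (below).

Per-frame counts are aggregated into `bin_s = 1` second bins, by default
with the **maximum** (a single vigorous movement inside a second marks that
second active); `aggregate = "mean"` is available.

## Scoring: threshold and immobility rule

A bin is *active* iff its count strictly exceeds
`threshold_pct / 100 * reference_count`. The method's percentage grid never
defined what 100% means; `sleepcam` defines `reference_count` as the 99th
percentile of the trace's positive counts — a proxy for full-body motion —
so thresholds are scale-free across camera resolutions, and any other
value can be supplied. Strictness matters at 0%: breathing and ear
movements with nonzero counts must be classifiable as inactive by a
positive threshold, while a zero count is never active.

`calibrate_threshold()` scores sleep at every grid value (default 0–100%
in 5% steps) and maximises bin-level accuracy against a reference
hypnogram; ties go to the **lowest** threshold, favouring wake sensitivity
(sub-threshold breathing must not trigger arousal, but genuine movement
should).

`score_sleep()` labels every maximal run of inactive bins with duration
`>= immobility_min_s` as sleep *over its whole extent*, from run onset —
the whole-run convention of the immobility-rule lineage. Boundary choices:
a run of exactly the rule length qualifies (the "over 40 s" phrasing
conflicts with "set at 40 s"; inclusive is documented and tested), and runs
truncated by the recording edges qualify by their observed duration. The
rule must be an integer multiple of the bin width. Totals are provably
monotone: raising `immobility_min_s` can only remove sleep; raising the
threshold can only add it.

## Agreement

Manual EEG/EMG scoring arrives as Wake/NREM/REM labels in 10 s epochs;
total sleep is REM + NREM, so `collapse_reference()` maps both to sleep.
Comparison granularity is **per-hour totals** — each paired observation is
one subject-hour — because that is the granularity at which this class of
systems is validated. `paired_hourly()` accepts any whole number of hours
(a condensed two-hour recording pairs two observations; the standard study
is 24 x 1 h); anything else is an error, never silently padded.
`bland_altman()` uses the sample SD (n − 1) and the conventional 1.96
multiplier. Pooling across subjects is simple pooling; no random subject
effect is fitted, and the report says so.

The consistency coefficient has no uniquely determined published formula
(no ratio of printed group totals reproduces all published cells), so
`sleepcam` defaults to `100 * (1 - sum(|d_i|) / sum(reference_i))` over all
subject-hours, offers `"total-ratio"` and Lin's concordance (`"ccc"`) as
alternatives, and always reports which formula produced the number. The
default is 100 iff all pairs agree exactly, 0 for an all-zero video against
a sleeping reference, and is scale-invariant; it can go negative when the
video overshoots the reference by more than the reference total, which is
reported as-is rather than clamped.

`resample_epochs()` (needed to put 1 s video bins on the 10 s epoch grid)
takes the majority label per epoch; exact ties go to wake, conservative
against over-scoring sleep.

## The synthetic generator

`sim_spec()` → `simulate_hypnogram()` draws alternating sleep/wake bouts
from lognormal distributions with phase-specific medians under a 12/12
light/dark cycle (lights on 08:00). Rather than asking the user for wake
medians, the spec takes per-phase **sleep-fraction targets** (defaults:
light 0.65, dark 0.30 — a nocturnal pattern giving roughly half of the day
asleep, in the ballpark of healthy laboratory mice) and derives the wake
medians so the expected realised fraction matches the target. Defaults:
sleep-bout medians 300 s (light) / 150 s (dark), `sdlog` 0.5 (sleep) and
0.8 (wake), minimum sleep bout 60 s. Brief arousals (default 4/h of sleep,
2–20 s, always shorter than the 35 s rule) are carved out of sleep bouts
and logged. Pharmacological or stress interventions are emulated only as
multipliers on the bout medians. These distributions are test fixtures
with the right statistical structure, not biological claims.

`trace_noise_spec()` → `simulate_trace()` draws wake counts from a gamma
distribution above a hard floor (default floor 100 px, mean 500 px — a
locomoting mouse always displaces at least its limb area of pixels) and
sleep counts from breathing-band pulsation (2.5 Hz, peak 10 px) plus
Poisson micro-motion (mean 8 px). The defaults separate the regimes by
well over 5x, the well-posed case; shrinking the floor and means creates
overlap for stress-testing calibration.

`render_video()` rasterises the truth as an elliptical target (default
semi-axes 24 x 14 px in a 320 x 240 frame at 5 fps; the reference hardware
is 1920 x 1080) that random-walks during wake (reflecting at the walls, so
it never leaves the frame) and holds position during sleep with ±3% area
pulsation at 2.5 Hz plus occasional 1–2 px ear flickers. Gaussian pixel
noise (SD 2) is added per frame. Frames are materialised lazily in chunks
with per-frame noise seeds, so a full day never sits in memory and streams
are bit-identical regardless of chunk size. `lead_in_s` prepends two
seconds of held initial pose so detector burn-in consumes lead-in rather
than scored recording.

`degrade_reference()` emulates the human scorer: majority-resample the
truth to 10 s epochs, keep each sleep epoch with probability `sensitivity`
and each wake epoch with probability `specificity`, and label retained
sleep epochs REM with probability `rem_fraction` (default 0.12).

**What the generator does not emulate:** multiple animals, occlusions and
bedding disturbance, illumination drift, camera noise that is non-Gaussian
or spatially correlated, genuine NREM/REM microstructure, and sleep states
without immobility (cataplexy-like events) or immobility without sleep
(freezing). Tests passing on synthetic data therefore validate the
*algorithmic* chain — detection, thresholding, run-length scoring,
agreement statistics — not the biological claim that immobility equals
sleep in any particular preparation.

## Exactness, and the sizes the tests use

Two identity regimes are used in the test suite:

* **Trace level (exact).** With separated count distributions, no
  arousals, all sleep bouts ≥ 60 s and bout boundaries quantised to the
  10 s epoch grid (`quantize_s = 10`, so a perfect 10 s-epoch reference is
  lossless), calibration followed by scoring recovers the truth bin for
  bin, and agreement is exactly 100% with zero bias. The test suite
  asserts this on a full 24 h day.

* **Rendered video (stochastic).** The same pipeline through a rendered
  two-hour condensed day (1 h light / 1 h dark, 320 x 240, 5 fps) stays
  above 90% consistency against both a perfect and a 0.9/0.9-degraded
  reference; the shortfall from 100% is the documented absorption latency
  at sleep onsets.

Problem sizes were chosen to exercise the asymptotics while keeping the
suite quick: 1,000 random activity sequences of length 10,000 for the
scoring oracle; 200 simulated traces for monotonicity; 500 replicates of a
six-subject, 24 h Bland–Altman recovery plus a 10,000-pair coverage check;
100 overlapping-distribution traces for calibration recovery against a
0.1% brute-force grid; and the two identity regimes above.

## Known limitations

* Video can measure immobility, not sleep architecture: NREM/REM cannot be
  distinguished, nor sleep depth.
* Any causal background-model detector reports sleep onsets late by its
  absorption time; with the defaults this is 16 s per bout, visible as a
  small negative bias (video under reference).
* Interventions that suppress movement without producing sleep (or produce
  wake without movement) defeat the immobility rule itself; the generator
  can emulate the bout-statistics of such interventions but not rescue the
  inference.
* The consistency coefficient is formula-dependent; cross-study
  comparisons should quote the formula alongside the number.
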