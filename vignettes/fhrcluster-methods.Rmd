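---
title: "Clustering-based fetal QRS detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-based fetal QRS detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhrcluster)
```

This vignette documents the scientific model behind `fhrcluster`, the
parameters that matter, the choices made where the procedure admitted more
than one reading, and what the synthetic benchmark does and does not show.

## The problem

An abdominal ECG is a superposition of the maternal ECG (large, slow), the
fetal ECG (small, fast, narrow QRS), baseline wander and noise. Fetal beat
detection from a single channel must separate three populations of
transient events without knowing in advance how large fetal beats are
relative to maternal ones — the amplitude ratio varies with gestational
age, electrode placement and the relative orientation of the two hearts.
Fixed amplitude thresholds therefore generalise poorly. The approach here
treats detection as unsupervised classification: describe every candidate
deflection by scalar features and let a 3-cluster partition find the
maternal, fetal and noise groups for each processing window.

## Stage by stage

### Wavelet denoising

One decimated DWT decomposition/reconstruction handles baseline wander and
noise simultaneously. With `db6` and depth $L = 7$ at 1 ksps, the level-7
approximation spans roughly 0–3.9 Hz; replacing it with zeros removes DC
and wander (typically < 0.5 Hz). The three finest detail levels (62.5–500
Hz) are mostly noise at this sampling rate and are soft-thresholded with
the universal threshold $\sigma\sqrt{2\ln n}$, where
$\sigma = \mathrm{median}(|d_1|)/0.6745$ is estimated once from the
level-1 details and reused at levels 1–3 ("single rescaling"). Levels 4–7
(3.9–62.5 Hz), which carry both QRS complexes, pass unchanged — so the
operation cannot erase the fetal QRS, only shift its peak by a few samples
(the tests bound this at 5 samples).

Numerical choices:

* **Boundary handling** — symmetric (half-point) extension, the standard
  low-artifact choice for biosignals. The transform is expansive at the
  edges, so reconstruction is exact to machine precision for any length
  (no power-of-two requirement).
* **$n$ in the threshold** — the full signal length, not the per-level
  coefficient count, matching the `'sln'` convention of the MATLAB wavelet
  toolbox whose vocabulary (universal threshold, single rescaling, soft)
  the method's parameter set uses.
* **Short inputs** — a signal too short for $L = 7$ is processed at the
  largest feasible depth with a warning rather than rejected.

### Max-min points

An RS deflection appears as a local maximum followed by a local minimum.
The scan emits *every* such pair — no gating — because separating "other
waves" is the clustering stage's job. Plateaus (runs of equal samples, a
real occurrence in 16-bit quantised data) count once, at the run's first
sample; a maximum not followed by a minimum in the extremum sequence is
discarded since only the immediate max→min geometry is of interest.
Inverted complexes (S before R) are out of scope; negating the signal is
the user-level workaround.

### Feature selection

Per window the amplitude histogram over $[0, \mathrm{MA}]$ (MA = largest
amplitude in the window) is computed with 50 equal bins, normalised by the
point count, and smoothed. The first local minimum separates the dominant
near-zero noise mode from the beat modes. The decision table counts the
prominent local maxima beyond that minimum:

* two maxima separated by $\ge 0.35\,\mathrm{MA}$ → fetal and maternal
  amplitudes are distinct; classify on **amplitude**;
* two maxima closer than that, or a single maximum → fetal and maternal
  amplitudes overlap; classify on **amplitude × sample span**, which
  separates them because the fetal QRS is roughly half as wide;
* zero or more than two prominent maxima → fall back to amplitude.

Design choices (all config-exposed via `feature_config()`):

* **Smoother** — centred moving average, width 5 bins, window shrinking at
  the edges. At 50 bins this suppresses single-bin jitter without merging
  modes ~5 bins apart; it is the simplest filter with one parameter.
* **"Separated by 35% of MA"** — implemented as
  $d_{\max\text{-}\max} \ge 0.35\,\mathrm{MA}$ measured between bin
  centres, with the tie counting as the separated case. The alternative
  reading ("35% greater than MA") is geometrically impossible for two
  points inside $[0, \mathrm{MA}]$ whose distance is at most MA, so the
  fraction-of-MA reading is the only consistent one.
* **Prominence floor** — post-minimum maxima with smoothed height below
  0.5% of total mass are ignored; without this, near-empty bins between
  modes occasionally spawn spurious third maxima and flip the case.
* **Extremum convention** — strict neighbour comparison with the
  plateau-first-bin rule; boundary bins may qualify one-sidedly (the
  maternal mode often occupies the top bin).

### Clustering

The selected 1-D feature is partitioned into $k = 3$ clusters by
k-medoids with ++ seeding (first medoid uniform, subsequent medoids
sampled proportionally to squared distance from the nearest chosen one)
under squared-Euclidean dissimilarity, 20 restarts, best total cost wins.
In 1-D with squared-Euclidean cost the medoid update has a closed form —
the member value nearest the cluster mean — so the Voronoi-style
alternation is exact and fast; a PAM-style swap search adds nothing at
this scale, and the test suite verifies against exhaustive search over all
medoid triples that best-of-20 attains the global optimum essentially
always on small problems. One seeded generator drives all replicates, so
results are a pure function of the seed. Roles are assigned by median
ordering: smallest → noise, middle → fetal, largest → maternal; tied
medians are broken by medoid value with a warning.

### Refinement and RR correction

Refinement re-derives limits from the same smoothed histogram: the lower
amplitude bound is the bin centre of the first local minimum (the
noise/fetal boundary); the upper bound is the midpoint between the two
mode centres *when two well-separated modes are identifiable* (the
amplitude-scenario case), else MA — under the overlapping-amplitude
scenario the two histogram modes are not fetal-vs-maternal on the
amplitude axis, so a midpoint cut would bisect the merged beat mode.
A span limit (60 ms default) removes wide maternal-like deflections.

The correction stage encodes RR plausibility with explicit, tunable
defaults (the published description defers the exact thresholds to earlier
work, so these are this package's reconstruction, not authorial values):
a 100–220 bpm physiological band, short-RR gate at 0.5× and long-RR gate
at 1.5× the running median RR (centred window of 9 beats, shrunk at the
ends), smaller-amplitude victim selection for false positives, and a
±30 ms search for the largest unused max-min point at each expected beat
position inside a long gap. Every removal/insertion is recorded in an
audit trail. This stage is what recovers fetal beats that coincide with a
maternal QRS: the merged deflection is not in the fetal cluster, but the
resulting 2×RR gap triggers a search that usually lands on the maternal
peak — within the 50 ms tolerance of the true fetal beat.

### Windowing

Records are denoised whole (windowed wavelet transforms would add edge
artifacts at every seam; a per-window mode exists as a config flag), then
classified in 50,000-sample windows — classification quality is flat over
roughly 10,000–60,000 samples, and a trailing window shorter than 10,000
samples is merged into its predecessor. Feature selection runs per window,
so a record can switch scenario mid-way. Detections from adjacent windows
closer than the matching tolerance collapse to the larger-amplitude one,
and RR correction runs once on the full train.

## The synthetic generator

`generate_aecg()` emulates exactly what the detector consumes: two
independent jittered beat trains (maternal ~78 bpm, fetal ~140 bpm by
default) of biphasic templates (difference of two Gaussians — the max→min
RS geometry is all the pipeline reads, so richer P-QRS-T morphology would
add nothing testable), sinusoidal baseline wander, and white Gaussian
noise. Multiplicative RR jitter is clipped at ±3 s.d. to keep intervals
positive and bounded. Because the trains are independent, fetal beats
genuinely collide with maternal beats at rate crossings (~5–10% of beats),
which is the hard case in real abdominal data.

The two presets pin the study conditions: `scenario1` (fetal/maternal
amplitude ratio 0.3, widths 30/45 ms) and `scenario2` (ratio 0.9, widths
20/45 ms), both with noise at 5% of the fetal amplitude and 0.5 a.u.
wander at 0.25 Hz. Five-minute records at 1 ksps mirror the training
database's record length.

What passing the synthetic benchmark does **not** show: robustness to
electromyographic bursts, electrode motion artifacts, saturation,
uterine-contraction interference, or non-stationary fetal rates —
real-recording phenomena the generator deliberately omits. Published
per-recording results on the clinical databases span roughly 71–99%
sensitivity depending on artifact burden; the synthetic figures
characterise the algorithm under clean-to-moderate conditions, not
clinical performance.

## Evaluation conventions

Matching is one-to-one and greedy in reference order (nearest unused
detection within 50 ms). At fetal RR ≥ 270 ms and a 50 ms tolerance this
coincides with optimal assignment except in pathological fixtures. TD and
TP name the same quantity; TD is used throughout. Metrics are kept as raw
floats and displayed with half-up 2-decimal rounding, matching the
convention of published evaluation tables. Sample indices are 0-based
everywhere internally (plain-text annotation files are documented as
0-based); at a 50 ms tolerance the 0- vs 1-based distinction is
immaterial for matching, but one convention prevents off-by-one drift.

## Problem sizes

The test suite generates its fixtures at 30–120 s; the acceptance script
uses twenty 5-minute records per scenario (≈ 14,000 fetal beats pooled
per scenario) plus 100 exhaustive-search clustering comparisons. A full
acceptance run completes in well under a minute on one core.

## Known limitations

* Single channel by design; no multichannel fusion.
* No inverted-polarity handling; no maternal-beat subtraction.
* The FP/FN gate values are reconstructions, tunable via
  `correction_config()`, not published constants.
* WFDB support covers format-16 records and MIT annotation beat codes —
  enough for the abdominal fetal databases, not the full format zoo.
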