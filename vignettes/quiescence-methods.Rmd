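---
title: "Methods: state segmentation and screen statistics in quiescr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state segmentation and screen statistics in quiescr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Well-fed *C. elegans* adults enter a sleep-like state — satiety quiescence —
in which locomotion stops. In the assay this package models, a single worm is
filmed at 1 frame/s for 30 minutes, its centroid is extracted from each frame,
and the centroid displacement between frames is the sole behavioral readout.
The animal's session is partitioned into three locomotor states:

* **roaming (R)** — fast, relatively straight exploration;
* **dwelling (D)** — slow, local back-and-forth movement;
* **quiescence (Q)** — no movement beyond centroid noise.

Per animal, the scientific quantities are the percent time in each state and
the six state-to-state transition rates, which behave like first-order rate
constants: `rate[i→j] = (number of i→j switches) / (time spent in i)`. In an
RNAi screen, each treated group is compared to a concurrent control group
(same brood, empty-vector bacteria, same rig and day), and every metric is
reported as the ratio of the treated group mean to the concurrent control
group mean.

```{r, message = FALSE}
library(quiescr)
library(dplyr)
```

## The hidden Markov model

Raw speed traces do not cleanly threshold into three states: dwelling and
quiescence overlap near the centroid-noise floor, and single-frame spikes
would fragment bouts. The package therefore models the observed log speed
with a 3-hidden-state HMM:

* observations: `y_t = log(speed_t + ε)`, with a small floor `ε`
  (default 0.01 px/s) guarding `log(0)`;
* emissions: one Gaussian per state on the log-speed scale;
* dynamics: a per-frame 3×3 transition matrix `A`, initial distribution `π`.

Speed is the only feature. Roaming is also straighter than dwelling, but
speed alone already separates the states when the emission means are
distinct, and a single observed feature keeps the estimator exactly inverse
to the generator used for validation. States carry no labels during fitting;
after convergence they are sorted by emission mean, and the slowest state is
called Q, the middle D, the fastest R (`label_states()`). Exactly equal means
are rejected as unidentifiable.

Fitting is multi-sequence Baum–Welch (`fit_hmm()`), pooling expected counts
across animals and segments. The recursions are scaled per frame, so
likelihoods are exact in log space at any session length; the EM trace is
non-decreasing up to 1e-8 numerical slack, and the test suite asserts this on
every fit. Initialization is deterministic ("quantile"): pooled log speeds
are split at their 33rd/67th percentiles, per-tercile means/sds seed the
emissions, `A` starts at 0.95 self-transition, `π` uniform. No random
restarts are performed by default, so a fit is a pure function of the data.
Emission standard deviations are floored at 1e-3 to prevent variance
collapse onto single observations.

Decoding (`decode_states()`) is Viterbi in log space, with ties broken
toward the lowest state index (Q before D before R); forward–backward
posteriors accompany every frame. Sequences are decoded per contiguous
segment and no transition is ever counted across a tracking gap.

One protocol decision matters for screens: **a single model per experiment,
fitted on the concurrent control group only and then frozen to decode every
animal** of that experiment. Decoding treated animals with a model fitted on
their own (possibly perturbed) behavior would move the state boundaries with
the treatment; the shared frozen model guarantees that treated/control
differences reflect behavior, not segmentation. `run_pipeline()` implements
this per gene.

A known consequence of mixture flexibility: if the data genuinely contain
fewer than three speed modes (e.g. an animal that never roams), the three
Gaussians legitimately subdivide the existing cloud rather than starving the
spare states — a 3-component fit of a single Gaussian has higher likelihood
than the single component. Downstream group comparisons are protected by the
shared-model protocol, but per-animal fits on degenerate sessions should not
be over-interpreted; this is why per-animal fitting is not the default.

## From track to speeds

`compute_speeds()` converts centroid tracks to speed series: Euclidean
displacement between consecutive valid frames over elapsed time, each sample
assigned to the later frame of its pair. Dropouts of at most
`max_gap_frames` (default 5) are bridged by linear position interpolation —
the bridged speed equals the gap-average speed, so interpolation can never
manufacture a speed exceeding the pre/post displacement over the gap
duration. Longer dropouts split the series into independent segments rather
than fabricating stillness.

An optional centered moving average (`window_s`) is available but **off by
default**, and this default deserves its rationale. The obvious motivation
for smoothing — suppressing frame-to-frame centroid jitter so quiescence
reads as near-zero speed — is already handled by the model itself: the
quiescence emission component *is* the jitter-floor distribution, so raw
unsmoothed speeds are exactly what the HMM expects. Averaging, by contrast,
actively harms segmentation: a window of even three frames mixes quiescent
frames at bout boundaries upward, shrinks the within-state spread of
dwelling speeds far below its natural log-normal width, and leaves the rare
roaming mode (about 1% of frames under control dynamics) unable to hold an
emission component — on synthetic sessions, decoding accuracy falls from
essentially perfect to below 50%, with dwelling frames absorbed into a
spurious fast state. The window remains a knob for recordings whose centroid
noise genuinely rivals dwelling displacements, with the caveat that
state-occupancy estimates should then be interpreted comparatively (the
shared-model protocol keeps treated/control contrasts valid even when
absolute occupancies are distorted).

Centroid extraction (`extract_centroid()`) binarizes each frame (Otsu by
default; a fixed threshold is available for noiseless synthetic frames),
labels connected components, keeps the largest one of at least `min_area`
pixels (default 5), and returns its intensity-weighted centroid. Coordinates
are x = column, y = row, 0-based, origin top-left, pixel centers at
integers. On noiseless rendered disks the centroid is exact at integer
centers and within 0.5 px at arbitrary subpixel positions.

## The synthetic-data generator

No raw recordings accompany the assay, so validation rests on a generator
whose ground truth is known exactly:

* **States** (`simulate_states()`): a discrete-time Markov chain with
  per-frame probabilities `p[i,j] = r[i,j] / frame_rate`, started from the
  chain's stationary distribution to avoid burn-in in 30-minute sessions.
  The linear rate-to-probability conversion (rather than a matrix
  exponential) is accurate to well below estimation error at 1 frame/s with
  rates of order 0.02/s and below, and it makes `transition_rates()` the
  exact maximum-likelihood inverse of the generator.
* **Default control rates**: dwelling and quiescence exchange at
  0.02/s each (the balanced switching seen in control animals); rates into
  roaming are tiny (D→R 0.001/s, Q→R 0.0002/s, the magnitudes reported for
  control worms); roaming exits at 0.05/s to D and 0.005/s to Q, keeping
  roaming rare (~1% occupancy) as observed. All overridable.
* **Speeds**: per-state log-normal, dwelling centered at 1 px/s and roaming
  at 8 px/s (sd 0.35 in log units). No numeric speed ranges are published
  for the assay, so these defaults are chosen for identifiability — clearly
  separated modes — not fidelity to a particular rig. Quiescence is "not
  moving" only up to centroid noise: its displacement is isotropic Gaussian
  jitter (sd `jitter_px = 0.05` px per axis), whose magnitude is
  Rayleigh-distributed; the quiescence emission defaults are the exact
  log-moments of that Rayleigh (`mean = log(jitter) + (log 2 − γ)/2`,
  `sd = π/√24 ≈ 0.64`), so the kinematic model and the emission table agree.
* **Tracks** (`simulate_track()`): roaming keeps a persistent heading with
  Gaussian angular diffusion (sd 0.2 rad/frame); dwelling reverses heading
  with probability 1/2 each frame; positions reflect at the arena boundary.
  Heading dynamics are cosmetic — the HMM sees speed only — but reflections
  do shorten displacements near walls, which is why distribution-level
  checks of the emission model use a large arena.
* **Frames** (`render_frames()`): a filled bright disk (radius 4 px by
  default) at the true centroid, optional additive Gaussian noise; written
  losslessly as 16-bit multi-page TIFF.
* **Screens** (`simulate_screen()`): per gene, an independent concurrent
  control group and a treated group whose rates are the control rates times
  the effect's multipliers. Group sizes default to 8 controls vs 16 treated,
  within the assay's typical ranges (6–9 controls, 14–24 treated). One
  master seed deterministically derives per-animal seeds.

What the generator does **not** emulate: worm posture and body shape,
multi-animal arenas, pharyngeal pumping, lighting drift, slow behavioral
non-stationarity within a session, and day-to-day baseline drift between
experiments (each synthetic control group is drawn from the same law, so
concurrent-control normalization is validated for its statistical behavior,
not for its ability to remove real batch effects). Passing tests therefore
demonstrate correctness of the estimators and the screen machinery under the
assay's idealized model, not robustness to every artifact of real video.

## Screen statistics

Per gene (`screen_report()`):

* **Normalization**: ratio of arithmetic group means, per metric. Ratios
  whose control mean is below a floor (0.5 percentage points for percent
  time; 1e-4/s for rates) are flagged `unstable` and reported `NA` —
  control roaming is near zero, and silently dividing by it would print
  meaningless hundred-fold "effects". Ratio-of-means is used rather than
  mean-of-ratios; the alternative is easy to compute from the per-animal
  summaries if wanted.
* **Testing**: pooled-variance two-sided Student's t on per-animal percent
  time, `df = n1 + n2 − 2`. Raw p-values are reported and compared against
  the Bonferroni per-comparison threshold `alpha / m`; p-values are not
  themselves adjusted. The family defaults to (number of genes) × 2 — one
  comparison each for dwelling and quiescence; roaming is excluded from the
  family because control roaming time is too small to test meaningfully.
  With 28 genes this gives m = 56 and a displayed threshold of 0.0009 at
  alpha = 0.05.
* **Classification**: two rules on normalized quiescence, exposed
  separately from significance rather than fused. `ratio_band` (default)
  calls reduced/enhanced outside 1 ± 0.20; `ratio_asym` uses cutoffs 0.6
  and 1.7. Ratio class and t-test significance answer different questions
  (effect size vs evidence), and combining them into a single hit flag is a
  choice the analyst should make explicitly; `significant_q` is provided
  alongside `classification`.

Degenerate cases are deterministic: zero pooled variance gives p = 1 for
equal means and p = 0 (flagged) otherwise; a missing normalized quiescence
classifies as `unresolved`; an empty group or an orphan treated group is an
error naming the offender.

## Numerical choices and problem sizes

Tolerances: forward/Viterbi agree with exhaustive path enumeration to 1e-9
on instances small enough to enumerate; EM monotonicity is asserted with
1e-8 slack; posterior rows sum to 1 within 1e-9; percent times sum to 100
within 1e-9, and `rate × occupancy` reproduces integer transition counts
exactly. CSV and JSON round trips are bit-for-bit: doubles are written at
full precision and read back with a correctly-rounded parser.

The validation suite runs at the assay's own scale where that matters:
30-minute 1 frame/s sessions, 20 animals for parameter recovery, 1e5-frame
sequences for rate and bout statistics, 200 replicate 28-gene null families
(8 controls vs 16 treated) for family-wise calibration, and 50 replicate
single-gene screens for knockdown detection. Rendering-based checks use
shorter sessions (200 frames) since centroid accuracy is a per-frame
property.

## Worked example

```{r, eval = FALSE}
cfg <- sim_config()                      # 1 frame/s x 1800 s, control rates
states <- simulate_states(cfg, seed = 1)
track <- simulate_track(states, cfg, seed = 2)
speeds <- compute_speeds(track)          # raw speeds, gap bridging
fit <- fit_hmm(speeds)                   # deterministic quantile init
decoded <- decode_states(fit, speeds)
behavior_summary(decoded, frame_rate_hz = 1)
```

For a whole mock screen, `simulate_screen()` plus `write_track_csv()` and a
manifest feed `run_pipeline()`, which fits on the concurrent controls per
gene, decodes everyone with the frozen model, and returns the screen table
(see the README for a complete run with output).

## Known limitations

* Speed-only emissions cannot separate fast-but-local from fast-and-straight
  movement; a path-straightness feature would be the natural extension.
* Transition rates assume the decoded chain is the true chain; decoding
  errors near state boundaries bias rates slightly upward for brief bouts,
  which matters at smoothing windows much larger than the default.
* Rate units are per second throughout; at 1 frame/s, per-frame and
  per-second rates coincide numerically, and the choice is recorded in all
  outputs rather than assumed.
* Bout-duration summaries exclude censored bouts by default; on short
  sessions with long quiescence bouts most bouts are censored and the
  uncensored mean under-represents the true duration.
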