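---
title: "Methods: from raw daily-diary streams to foraging models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw daily-diary streams to foraging models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesforage)
```

`sesforage` implements a complete analysis chain for high-resolution
bio-logging records from deep-diving marine predators such as southern
elephant seals: 1 Hz depth from a pressure sensor, 16 Hz tri-axial
acceleration and magnetometry from a back-mounted daily-diary tag, and
intermittent GPS fixes at surfacings. The chain runs from raw streams to
prey-encounter events, dive and phase segmentation, a per-dive covariate
table, and five regression models relating prey encounter rate, horizontal
transit speed, dive efficiency and transit duration to diving behaviour.
This vignette documents the models, the conventions and the numerical
choices, and what the bundled simulator does and does not emulate.

## Signal processing

All filters are order-3 digital Butterworth designs (bilinear transform,
via the `signal` package), specified by physical cutoffs at the 16 Hz
sampling rate:

* **static acceleration** — low-pass at 0.20 Hz, then each sample rescaled
  to exactly unit norm. This isolates the gravity direction in the body
  frame, from which posture follows by trigonometry alone.
* **dynamic acceleration** — high-pass at 2.64 Hz. Rapid head/body jerks
  associated with prey strikes live above this cutoff; stroking (below
  ~1 Hz) and posture changes do not.
* **swimming effort** — band-pass 0.44–1.02 Hz on the lateral axis (the
  stroking band), rectified and averaged over non-overlapping one-second
  blocks aligned to the record start. For a pure in-band sinusoid of
  amplitude $A$ the steady-state effort is $2A/\pi$, which the tests use as
  a calibration anchor.

Filtering is zero-phase by default (forward–backward pass): the
prey-encounter detector compares states across three axes and against the
depth channel, and any group delay would misalign them. A causal
forward-only mode is available. Edges are handled by odd-reflection padding
of three characteristic filter lengths ($3 f_s / f_c$), and the padded
edge region is flagged.

## Body posture

Body axes follow the logger: X forward, Y right, Z down, so a level,
stationary tag reads $(0, 0, +1)$ g. With the unit static vector
$\mathbf{s}$, in the North-East-Down frame:

$$\text{pitch} = -\arcsin(s_x), \qquad \text{roll} = \mathrm{atan2}(s_y, s_z)$$

with pitch positive nose-up and roll positive right-side-down. These sign
conventions are fixed here because the downstream covariates — pitch
steepness in transit, circular variances at the bottom — are invariant to
them. Heading comes from the magnetometer (low-passed with the same
0.20 Hz filter), de-rotated to the horizontal plane by roll then pitch;
$\text{heading} = \mathrm{atan2}(-m_{y,h}, m_{x,h})$, clockwise from
magnetic north. Heading is undefined (flagged) at pitch $\pm 90^\circ$ or
when the horizontal field component vanishes; declination correction is
out of scope since only heading *variability* enters the models. Angles
are averaged from 16 Hz to 1 Hz by circular block means so every stream
shares the depth timeline.

Circular summaries use the standard resultant-vector definitions:
$\bar\theta = \mathrm{atan2}(\overline{\sin\theta}, \overline{\cos\theta})$
and circular variance $1 - \bar R \in [0, 1]$.

## Prey-encounter events

Per axis: dynamic acceleration, per-second block SD (sample SD, $n-1$),
five-second centred moving SD, then an exact 1-D two-means clustering over
the whole deployment labels each second *high* or *low*. A prey-encounter
event (PEE) is a maximal run of seconds in which **all three axes** are
simultaneously high. Design choices:

* The two-means problem is solved exactly by scanning the sorted split
  (every 1-D two-means optimum is a sorted split), so there is no random
  initialization and detection is deterministic.
* Clustering is per-deployment, not per-dive, so states are comparable
  across dives; a config switch is not needed because the caller can
  always subset.
* **Bimodality guard**: on a record with no burst activity, a two-state
  clustering of unimodal noise would still split it and tri-axial
  coincidences would occur by chance. The clusterer therefore labels
  everything low (with a warning) unless the between-cluster mean gap
  exceeds 3 pooled within-cluster standard deviations. For an unorganised
  unimodal sample this separation ratio sits near 2.6 regardless of scale;
  genuinely bimodal state signals from burst records sit well above 4.
  The threshold is an argument (`min_separation`), and 0 disables the
  guard (the tests use that when checking exactness against the
  exhaustive-split oracle).
* Events live on the 1 Hz state timeline; sub-second timing is beyond the
  method's resolution.

## Dives, phases and bottom events

**Zero offset correction.** Pressure sensors drift slowly. Per 3 h rolling
window, the baseline is the 10th percentile of raw samples shallower than
10 m, anchored at the mean time of the samples that realize that low
quantile — not the window midpoint, which would lag a steady drift by
almost half a window — linearly interpolated between anchors and
extrapolated at the record edges. The corrected depth is clipped at
−0.5 m, the sensor resolution.

**Dives** are maximal runs of corrected depth > 15 m. Durations outside
500–1950 s are flagged (`too_short` / `too_long`) and excluded from
analysis but never silently dropped.

**Vertical speed** is the central difference of 3 s moving-average
smoothed depth, descending positive. The smoothing exists because 0.5 m
depth quantization otherwise injects 0.5 m/s spikes; 3 s is the smallest
window that suppresses a single quantization tick. A numerical deadband
(|v| < 1e-9 m/s treated as zero) keeps floating-point dust from creating
zero-amplitude events on flat bottoms.

**Wiggles** are down-then-up depth excursions: an ascending ($v<0$) run
preceded by descent and ending before the dive's final sample (an
ascending run that reaches the last sample is the terminal ascent, never a
wiggle). The event interval runs from the local depth maximum bounding the
ascent to the end of the ascending run, half-open. The minimum wiggle
amplitude defaults to 0 m (any sign change) and is a parameter.
**Steps** are maximal runs of at least 5 s with $v$ strictly inside
(0, 0.35) m/s — the slow-glide band whose ceiling is the published
king-penguin value, close to observed passive sink rates for elephant
seals. Samples already claimed by a wiggle are excluded first. The 5 s
minimum is again a quantization guard.

**Bottom delimitation** uses the ledge rule: events whose maximum depth
exceeds 75% of the dive's maximum depth qualify, and the bottom phase runs
from the start of the first to the end of the last qualifying event, which
guarantees phase limits can never bisect a wiggle or step. If no event
qualifies the bottom falls back to the first-to-last crossing of the 75%
isobath and the dive is flagged `fallback_delimitation`. Phases always
partition the dive exactly.

**Drift dives** (passive resting/digesting descents) are excluded from the
analysis table. The operational rule — reconstructed, since the behaviour
is only cited in the source literature — flags a dive containing a segment
of ≥ 200 s whose per-second swimming effort stays below the deployment's
10th percentile while |vertical speed| is a stable slow sink or rise
(mean in 0.05–0.6 m/s, SD < 0.1 m/s). Every threshold is an argument.

## The per-dive table

One row per analysable dive: bottom PEE count and rate (count divided by
bottom minutes), bottom median depth, bottom vertical extent (Q90 − Q10 of
bottom depth samples, linear-interpolation quantiles — stated explicitly
because the extent is sensitive to the quantile convention), percentage of
bottom time in wiggles and in steps, circular mean transit pitch, mean
transit effort, circular variances of pitch and heading at the bottom,
dive efficiency (bottom duration / dive duration, necessarily in (0,1)
when both transits are non-empty, flagged otherwise), surface horizontal
speed, and a day/night label.

Surface speed divides the haversine distance (sphere radius 6 371 008.8 m)
between the fixes bracketing the dive by the elapsed time between them,
fix-to-fix; it is missing when either adjacent surfacing yielded no fix.
Day/night uses solar altitude at the dive start from a compact
low-precision solar ephemeris (mean solar longitude/anomaly, equation of
time, hour angle — accurate to a small fraction of a degree), at the
position linearly interpolated between fixes; altitude ≥ 0° is day, and
the boundary convention and threshold are arguments.

## The five models

All models standardize covariates (zero mean, unit SD, scaling stored for
back-transformation) so slopes are comparable. Temporal autocorrelation is
addressed by thinning to one dive in ten on long records (the bundled
analysis uses `thin_k = 1` because its synthetic records are hours, not
months). Covariates are screened with VIF < 5 (warning only).

* **1a, 1b** — negative-binomial GLM (log link) of the bottom PEE count,
  with log bottom duration as an offset whose coefficient is fixed at one,
  so the modelled quantity is a rate; fitted separately on daytime and
  night-time dives; individuals as fixed intercepts.
* **2** — Gaussian LMM of surface horizontal speed, random intercept per
  individual, on the subset of dives with bracketing fixes.
* **3** — variable-dispersion beta regression of dive efficiency: logit
  mean link and log precision link, the precision submodel defaulting to
  the mean submodel's covariates (the heteroskedasticity is the point);
  fitted with `glmmTMB` and its dispersion formula.
* **4** — Gaussian LMM of transit-phase duration with phase type
  (descent/ascent) interacting with phase maximum depth and mean effort.

**Selection** is backward elimination by AIC from the full model (drop the
single term whose removal lowers AIC most; ties drop the later-listed
term, deterministically), followed by per-covariate polynomial degree
escalation (1 → 2 → 3…, orthogonal polynomials for numerical stability,
stopping at the first non-improvement, hard cap at degree 4). Mixed models
use ML during selection and are refitted with REML at the end.

A known property worth stating plainly: backward AIC retains a pure-noise
covariate with probability $P(\chi^2_1 > 2) \approx 0.157$, so with three
null candidates the *exact* true support is recovered in only ~60% of
replicates even when every real effect is retained 100% of the time. This
is inherent to AIC-based selection, not an implementation artefact, and
the selection simulation reports exactly that behaviour.

**Goodness of fit.** For the count models, deviance explained
$D^2 = 1 - D_{res}/D_{null}$ with the null = intercept + offset
(individual intercepts count as part of the model; a switch includes them
in the null instead, since either reading is defensible), plus
per-covariate NDE by single-term deletion (non-negative, need not sum to
$D^2$). For the LMMs, Nakagawa marginal/conditional $R^2$ computed from
the variance of the fixed-effect predictor and the fitted variance
components. For every family, a squared Pearson correlation between the
link-transformed response and the linear predictor; zero counts receive a
half-count continuity adjustment before the log (logged, configurable).

## The simulator and what passing tests mean

`simulate_deployment()` generates the study conditions: ~50 dives drawn
with duration mean 1103 s, SD 308 s (clamped to 600–1900 s), target depths
200–1300 m capped by what a 2 m/s swim speed can reach in the drawn
transit times, 2–3 min surfacings, bottom phases containing 1–4 wiggles
and 0–2 steps, ~0.8 prey bursts per bottom minute (≈ 200 per deployment)
plus a smaller transit fraction, three drift dives, 0.5 m depth
quantization, 0.5 m/h pressure drift, GPS fixes at 60% of surfacings and
accelerometer noise SD 0.05 g. Swim speed is a configurable constant with
no claim of realism (the original velocity sensors failed, so no empirical
value exists to emulate). Pitch is *derived* from the depth profile
(vertical speed = swim speed × sin |pitch|), so depth and orientation are
physically consistent by construction; bursts are amplitude-modulated
3–7.5 Hz noise on all three axes (two-axis negative controls available);
the magnetometer sees the local NED field rotated by the true orientation.

Not emulated: hydrodynamics and buoyancy, current advection of the track,
tag-attachment artefacts, magnetometer calibration error, prey-patch
structure in the covariates (the covariate simulator draws independent
normal covariates), or any dependence of surface speed on diving
behaviour. Consequently, green detection/segmentation/recovery tests show
the *algorithms* are correct under the stated signal model — they do not
certify performance on real tags, where burst SNR, drift shape and
magnetic disturbance are all less polite.

Problem sizes used by the bundled analysis and checks: deployments of
40–50 dives (~13–17 h of record), 200 replicates at n = 1000 for
parameter recovery, 100 replicates at n = 500 for selection. These sizes
give Monte-Carlo error comfortably below the tolerances being asserted.

## Degenerate inputs and edge behaviour

Constant axes, empty deployments, all-identical clustering inputs,
antipodal circular means (undefined, returned NA), beta responses at
exactly 0/1 (rejected, pointing at the efficiency flags), windows without
surface samples (baseline carried forward with a warning), dives whose
phases degenerate (dropped with a message, listed in an attribute) are all
handled explicitly and tested; nothing is silently discarded.
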