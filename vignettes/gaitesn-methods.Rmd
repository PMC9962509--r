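---
title: "Methods: reservoir-computing prediction of ground reaction force and gait events from one IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reservoir-computing prediction of ground reaction force and gait events from one IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitesn)
```

## Overview

`gaitesn` maps the tri-axial acceleration of a single lower-limb IMU to
two targets a force plate would deliver: the body-weight-normalized ground
reaction force vector (GRF; anterior–posterior, medio-lateral, vertical)
and binary indicators of five stance-phase events (heel strike HS, heel
push HP, foot flat FF, toe push TP, toe off TO). The mapping is a leaky
echo state network (ESN): a fixed random recurrent expansion of the input
history, read out by linear ridge regression. Everything downstream —
event peak detection, record-weighted error scoring in gait-cycle zones,
and the sensor-location × axis-combination sweep — quantifies how well
each sensor placement supports that mapping in able-bodied and medial
knee osteoarthritis (MKOA) gait.

## The reservoir model

For input $u(t) = [1, a_{\text{axes}}(t)]^\top$ (a constant bias plus the
selected acceleration axes, z-scored with training-split statistics):

$$\tilde x(t) = \tanh(W_{in} u(t) + W x(t-1)), \qquad
  x(t) = \alpha \tilde x(t) + (1-\alpha)\, x(t-1), \qquad
  y(t) = W_{out}\, x(t).$$

Defaults (see `esn_hyperparameters()`): $N = 100$ nodes, leak rate
$\alpha = 0.1053$, recurrent spectral radius $\rho = 0.7471$, recurrent
sparsity $0.21$, ridge parameter $\gamma = 10^{-6}$, input scaling 1.
These values are taken as given; no hyperparameter search is performed.
$W$ is sampled sparse with non-zero entries uniform on $[-1, 1]$ and then
rescaled by (target radius / realized radius), so the spectral radius is
met exactly; $W_{in}$ is dense uniform. Both are regenerated
bit-identically from the seed.

Two deliberate choices around the update equation:

* **Leak sign.** The state update is the convex combination
  $\alpha \tilde x + (1-\alpha) x$. An alternative form with
  $(\alpha - 1)$ on the retained state is available as
  `leak_variant = "printed"` for comparison; with $\alpha \approx 0.105$
  it flips the sign of the remembered state at every step and destroys
  the fading-memory interpretation, so it is not the default.
* **Washout.** The first 200 samples (1 s at 200 Hz) of every record are
  excluded from the training normal equations (`washout` argument,
  settable to 0). From a zero initial state, two trajectories on the same
  input agree to $<10^{-6}$ well before this horizon at the default
  operating point, so the washout removes the only transient that could
  bias the readout.

Inputs are standardized per channel (mean/SD over the pooled training
split) before entering the reservoir; this keeps the $\tanh$ units out of
saturation regardless of a location's raw acceleration scale.

## Readout training

Training streams per-record state/target blocks into normal equations

$$XX^\top = \sum_p X_p P_p X_p^\top,\qquad
  YX^\top = \sum_p Y_p P_p X_p^\top,\qquad
  W_{out} = (YX^\top)\,(XX^\top + \gamma I)^{-1},$$

solved by Cholesky back-substitution (never an explicit inverse). $P_p$
is the identity for **standard** training. For **kernel** training, all
samples of record $p$ share the weight
$\exp(-(v_p - c_k)^2 / 2w^2)$, where $v_p$ is the record's mean temporal
parameter on the training split — cycle duration (consecutive HS
intervals), stance duration (HS→TO), or stance proportion — and $c_k$ is
the bank centre. One readout is fitted per centre; centres default to 5
equally spaced points over the 5th–95th percentile range of the training
parameters and the Gaussian width to half the centre spacing, so the bank
covers the observed range without empty kernels. At prediction time the
readout with the centre nearest the record's parameter is selected (hard
selection; midpoint ties go to the lower centre). Soft blending would be
an alternative; hard nearest-centre is the documented choice because it
keeps each prediction attributable to one specialized readout.

The temporal parameter used for selection is measured from the GED task's
own predictions on the held-out segment (predicted HS/TO peaks), so
operation never touches force-plate data. One shared reservoir trajectory
feeds both tasks; GED and GRF simply have separate readouts.

Stance duration is defined HS→TO. An HS→FF variant exists
(`stance_rule = "hs_ff"` in `compute_temporal_parameters()`) because both
definitions circulate in the field's descriptions; it is exposed without
endorsement and nothing downstream defaults to it.

GED targets are kept as literal single-sample binary spikes. Least squares
on 1-of-T spikes is fragile in principle, so an optional triangular target
widening (`ged_pulse_halfwidth`) exists, but it is OFF by default: the
method is defined with strict binaries, and the default pipeline performs
well without widening.

## Event labelling and scoring

`detect_events_from_vgrf()` labels measured vertical GRF: stance bouts are
threshold crossings (default 20 N, ~3 % body weight for a 70 kg adult —
standard force-plate practice; the threshold is configurable), HS/TO are
the bout edges, HP/TP the first/last interior maxima, FF the global
interior minimum between them, or `round((HP+TP)/2)` when no interior
minimum exists — the flat-valley pattern of slow and MKOA walking. Ties on
flat-topped extrema resolve to the plateau centre; when one maximal
plateau spans the whole mid-stance (the flat-valley case), its first and
last samples serve as HP and TP, i.e. the ends of the rising and falling
edges. Bouts touching the record edges are dropped.

Predicted events are peaks in the readout output: local maxima above 30 %
of the row maximum (the output is near-binary, so the floor only
suppresses ripple), thinned to a minimum separation of 0.7 × the group's
mean training-set cycle duration — the same rule that yields ≈1.06 s for
healthy and ≈1.09 s windows for MKOA walkers at those groups' cadences.
Each labelled event is matched one-to-one to its nearest predicted peak
(greedy by increasing distance); unmatched events are counted and excluded
from the error. Errors are reported in ms as the mean over records of the
per-record mean — record-weighted, so a long record does not dominate.

One subtlety: inside pooled fits with strongly variable cadence, a single
0.7 × mean window under-resolves the fastest walkers (every other HS peak
is suppressed and their cycle duration doubles). Event *scoring* keeps the
group rule, but the internal temporal-parameter estimator that drives
kernel selection uses 0.7 × the 5th percentile of training cycle
durations, so it resolves the fastest cadences the kernel bank spans.

Force errors are record-weighted MAE in body-weight fractions, over three
gait-cycle zones: the whole cycle (0–100 %), weight acceptance (10–18 %)
and push-off (44–52 %). Zone phase is measured HS→next-HS on the
labelled (force-derived) events; the zone bounds follow the tabulated
(10, 18) convention rather than the alternative 0–18 description, and any
zone can be supplied explicitly (e.g. `list("(0,18)" = c(0, 18))`).
Within a zone, the per-record mean runs over the masked samples only.

## The synthetic gait generator

The study data behind this design are not deposited, so the package
generates its own (`generate_dataset()`), with the statistical structure
the analysis presumes:

* **Vertical GRF** per cycle is composed of strictly monotone half-cosine
  segments between knots at HP (25 % of stance), FF (50 %), TP (75 %):
  zero in swing, peaks of $(1 + 0.45 d)\,BW$ and a valley $d \cdot BW$
  below them ($d$ = `vgrf_valley_depth`; 0.35 for the healthy profile,
  0 for MKOA, which produces an exactly flat plateau and hence exercises
  the FF midpoint fallback). The contact convention jumps 0 → 20 N at HS
  and back after TO, so threshold-based edge detection recovers the
  construction-time HS/TO exactly and swing is exactly zero. Putting the
  knots at integer samples makes all five labelled events *exactly*
  recoverable — the cross-module oracle the event tests rely on.
* **AP force** is a braking then propulsion lobe with discretely cancelled
  impulses (steady-speed walking); **ML** is a small single bump.
* **Accelerations** at the five locations are deterministic functions of
  the cycle phase (three harmonics with location-specific amplitudes and
  phases) plus Gaussian impact transients locked to the true HS and TO
  times, mixed with a location-specific `coupling` fraction: the
  remainder is cycle-independent distractor oscillation (fixed 1.3 and
  2.9 Hz, random phase per record), and additive noise is scaled by
  `noise_sd` × channel scale / location SNR. Top of shoe is constructed
  as the most informative location (sharpest impacts, coupling 0.95, SNR
  3.0; the medial shank is the least informative at 0.60/0.8) — the
  planted ground truth the sweep is expected to recover. GRF channels are
  noise-free: force-plate noise is negligible at this scale, and the
  labelling oracle and swing-zero invariant require clean VGRF.
* **Participants.** Self-selected speed and body mass are drawn per
  participant from group distributions (healthy 1.28 ± 0.13 m/s,
  73.1 ± 16.5 kg; MKOA 0.75 ± 0.23 m/s, 80.5 ± 15.3 kg; truncated at
  0.25 m/s and 40 kg), constant across that participant's three speed
  conditions (self-selected, +20 %, −20 %). Cycle duration scales
  inversely with speed from group means of 1.514 s (healthy) and 1.557 s
  (MKOA) — the values at which the 0.7 × mean-cycle peak window
  reproduces the 1.06/1.09 s constants — with 2–3 % cycle-to-cycle
  variability. The default 27 + 18 participants × 3 speeds give the
  study-scale 135 records; record duration is a free knob (the original
  trials ran minutes; tests use 10–30 s).

What the generator does **not** emulate: sensor drift and bias,
gyroscope/magnetometer channels, belt dynamics, double-support force
sharing between feet, kinematic realism of the acceleration waveforms, or
hardware clock desynchronization (both clocks share $t = 0$ by
construction, so the cross-correlation alignment used with real hardware
is unnecessary). Consequently, passing tests show the *pipeline* is
correct and self-consistent — that the network can extract what the
signals contain, that labelling, training, selection and scoring do what
they claim — not that any particular accuracy would be achieved on real
walkers.

## Numerical choices

* **Resampling** (1000 → 200 Hz force targets): zero-phase windowed-sinc
  FIR (Blackman window, 151 taps, cutoff 90 % of target Nyquist) with
  reflection padding, then decimation. Passband deviation on a 2 Hz tone
  is <1e-3 away from the first/last half filter length; the edge
  transient is confined to those regions. Only integer decimation factors
  are supported.
* **Event indices across clocks** map by nearest sample; label cycles
  whose mapped indices fall outside the record are dropped.
* **Round-half-to-even:** the FF midpoint uses `round()` on
  stance-relative indices in both the generator and the labeller, so the
  two agree exactly regardless of the cycle's absolute offset.
* **Degenerate cases:** an all-zero readout row yields an empty peak
  list; a kernel centre whose total importance underflows is marked
  unusable (selection skips it, an error is raised only if none remain);
  a singular normal system at $\gamma = 0$ raises an error naming the
  remedy; standardization guards zero-variance channels.
* **σ-distance** in sweep summaries uses the population SD over the
  swept configurations — they are the whole universe of 35, not a sample.
* **Reservoir reuse:** one reservoir per input size (2, 3, 4) per seed,
  shared across sweep configurations, so location/axes comparisons are
  not confounded by reservoir resampling.
* **Group handling:** models are fitted per group by default (matching
  the per-group peak windows); pooled fitting is a flag
  (`group = "pooled"`), used when cadence diversity is itself the point.

## Problem sizes

The test-suite and acceptance-script runs use desk-scale versions of the
study design, chosen as the smallest sizes at which every property is
informative: 2–10 participants per group, 10–30 s records, the full
100-node reservoir for contract and end-to-end checks and a 30-node one
for structural model-object tests; the variable-cadence check uses
10 + 10 participants × 3 speeds × 30 s pooled, and the planted-location
check 10 dataset seeds × 5 locations. The generator itself defaults to
the study-scale 135-record design.

## Known limitations

* Accuracy values on synthetic data are not comparable to measurements on
  real walkers; only orderings and structural claims (e.g. which location
  wins, kernel ≥ standard under variable cadence) transfer as sanity
  checks.
* The FF event is intrinsically ill-posed under flat mid-stance valleys;
  the midpoint fallback is a convention, and FF errors should be read
  accordingly.
* Hard nearest-centre kernel selection can switch readouts discontinuously
  for records near a midpoint; soft blending would smooth this at the
  cost of attributability.
* The sweep treats the reservoir seed as fixed per input size; results at
  other seeds differ in detail (determinism is per-seed, not
  seed-averaged).
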