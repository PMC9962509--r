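# gaitesn

Predicting ground reaction force and gait events from a single wearable
accelerometer with echo state networks.

## The problem

Measuring the ground reaction force (GRF) and the timing of stance-phase
gait events normally requires an instrumented treadmill or in-ground force
plates. A single inertial measurement unit (IMU) strapped to the lower limb
is far cheaper and works outside the lab — if its acceleration signals can
be mapped to the forces and events a force plate would have measured.
`gaitesn` implements that mapping with reservoir computing, for both
able-bodied walkers and people with medial knee osteoarthritis (MKOA),
and answers the practical question that comes with it: *where on the leg
should the sensor go, and which acceleration axes should it feed the
model?*

Two prediction tasks share one recurrent network:

* **GRF**: the body-weight-normalized force vector
  (anterior–posterior AP, medio-lateral ML, vertical V),
* **GED**: five stance events read off the vertical GRF — heel strike
  (HS, rising edge), heel push (HP, first maximum), foot flat (FF,
  mid-stance minimum, or the HP–TP midpoint when slow/pathological gait
  has no mid-stance valley), toe push (TP, last maximum), toe off (TO,
  falling edge).

## The model

A leaky echo state network (ESN) with fixed random weights:

    x~(t) = tanh( W_in u(t) + W x(t-1) )
    x(t)  = a x~(t) + (1 - a) x(t-1)
    y(t)  = W_out x(t)

with `u(t) = [1, a_axes(t)]` the bias plus the chosen acceleration axes,
N = 100 nodes, leak rate a = 0.1053, recurrent spectral radius 0.7471,
recurrent sparsity 0.21. Only the readout `W_out` is trained, by ridge
regression on the accumulated normal equations

    W_out = (Y X') (X X' + g I)^{-1},   g = 1e-6,

streamed over records. Two training modes are provided:

* **standard** — one readout over all training records;
* **kernel** — a bank of readouts, each fitted with records weighted by
  `exp(-(v - c_k)^2 / 2w^2)` where `v` is the record's temporal parameter
  (cycle duration, stance duration, or stance proportion measured from
  labelled heel strikes and toe offs). At prediction time the readout
  whose centre is nearest the record's *predicted* temporal parameter is
  selected, so the network specializes by walking cadence.

Event predictions are peaks in the 5-row readout output (minimum peak
separation 0.7 × the group's mean training cycle duration); forces are
scored as record-weighted mean absolute error (MAE), overall and in the
weight-acceptance (10–18 %) and push-off (44–52 %) windows of the gait
cycle. A sweep over the 5 sensor locations (top of shoe TS, heel H, medial
malleolus MM, mid-front tibia MFT, medial shank MK) × 7 axis combinations
ranks placements by MAE and by the sigma-distance of the best
configuration below the field.

Because the underlying study data are not public, the package ships a
seeded synthetic gait generator (`generate_dataset()`) reproducing the
statistical structure the analysis needs: double-bump vertical GRF with
known event locations, flat mid-stance plateaus for the MKOA profile,
braking/propulsion AP lobes, five location-specific accelerometer
waveforms locked to the gait cycle (top-of-shoe planted as the most
informative location), healthy ≈ 1.28 m/s vs MKOA ≈ 0.75 m/s speeds, and
three speed conditions per participant.

## Worked example

```r
library(gaitesn)
ds  <- generate_dataset(n_healthy = 4, n_mkoa = 0, duration = 20, seed = 1)
fit <- gait_esn(ds, location = "TS", axes = "AP-V", group = "healthy",
                method = "kernel", kernel_variable = "cycle_duration")
summary(fit)
```

```
Echo-state-network gait model
  input    : TS accelerations, axes AP-V (+bias)
  records  : 12 (healthy)
  reservoir: N=100, leak=0.1053, radius=0.7471
  method   : kernel (cycle_duration)
  peak sep : 1.08 s (0.7 x 1.54 s mean cycle)

Held-out test scores
  Gait events (MAE, ms):
 event  mae_ms n_records n_unmatched                method
    hs  0.0000        12           0              standard
    hp 16.4167        12           0              standard
    ff 22.8611        12           1              standard
    tp 26.6597        12           0              standard
    to  0.6875        12           1              standard
    ...
  GRF (MAE, body-weight fractions):
 axis      mae n_records    zone                method
   ap 0.013175        12 (0,100)              standard
    v 0.060271        12 (0,100)              standard
   ap 0.009949        12 (0,100) kernel:cycle_duration
    v 0.042801        12 (0,100) kernel:cycle_duration
    ...
```

Reading the output: heel strike and toe off are recovered essentially
exactly (0 and 0.7 ms MAE) because their impact transients dominate the
acceleration signal; mid-stance events (HP, FF, TP) are harder, at 9–27 ms.
Vertical force is predicted to 0.043 body-weight fractions over the whole
cycle by the kernel method, which beats standard training on every axis
and zone here (e.g. 0.043 vs 0.060 BW for V) — the cadence-specialized
readouts pay off when cycle durations vary. The derived peak-separation
window (1.08 s) is the 0.7 × mean-cycle rule applied to this sample's
training records.

The location/axes sweep:

```r
res <- run_sweep(ds, sweep_config(groups = "healthy"))
summarize_best(res)       # best (location, axes) per cell + sigma-distance
```

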