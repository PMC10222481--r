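---
title: "Uncertainty-aware detection of sitting-posture asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware detection of sitting-posture asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seatsense)
```

## The monitoring problem

Prolonged static asymmetric sitting loads the intervertebral disks and hip
joints unevenly and is associated with musculoskeletal disorders in
computer-based work. Dynamic movement, by contrast, is not harmful: what a
seat monitor must flag is *sustained* left/right imbalance, while ignoring
brief movements and posture transitions.

seatsense implements the full signal chain of such a monitor for a seat
cushion instrumented with four force-sensing resistors (FSRs) at the
top-left (`Lt`), bottom-left (`Lb`), top-right (`Rt`) and bottom-right
(`Rb`) of the sitting surface ("top" = front, under the thighs; "bottom" =
rear, under the hips). Four sensors is the minimum that resolves left/right
balance separately at the thigh and hip sections. Everything upstream of the
serial frames — cushion, sensors, ADC, microcontroller — is replaced by a
seeded simulator, so the whole chain is testable in software.

## Read-out model

At each sampling tick (every $\Delta t = 0.5$ s) the acquisition reports
four 10-bit ADC codes. Per sensor:

1. **Counts to voltage.** $V_m = c \cdot V_{DC} / (2^{10}-1)$ with
   $V_{DC} = 3.3$ V; the full-scale code maps to the supply.
2. **Voltage to conductance.** The FSR sits in a voltage divider with a
   fixed resistor of conductance $G = 100\ \mu S$; inverting the divider,
   $G_{sens} = G \, V_m / (V_{DC} - V_m)$. A voltage within one count-width
   of the supply means a shorted sensor or corrupt frame and raises a
   saturation error rather than a huge conductance (this margin also keeps
   the denominator away from zero).
3. **Conductance to force.** FSR conductance grows approximately linearly
   with applied force; the fitted calibration is
   $G_{sens} = 0.950\, F + 9.848\ \mu S$ and is inverted for $F$. The
   calibration pair is configurable — the fit could equally be expressed in
   kgf, and the unit cancels after normalization — but newtons are the
   working unit throughout. Conductances below the intercept lie outside
   the fitted (loaded) range; the force is clamped to 0 N and flagged
   rather than reported negative, which would be unphysical.
4. **Type-B uncertainty.** The datasheet accuracy is $a = 2.5\%$ of the
   reading. Treating the error as uniformly distributed in $\pm a$, the
   standard uncertainty is $u = a F / \sqrt{3}$. The accuracy is applied in
   the force domain, where the datasheet states it.

## Moving-average filtering and uncertainty propagation

Each sensor keeps a 5-entry circular queue of force readings; every tick the
monitor emits the 5-point moving average $\bar F_k$, a low-pass filter that
makes 1-tick events perturb the output by exactly one fifth of their
magnitude for exactly five ticks. With $\Delta t = 0.5$ s, a disturbance
must persist for a couple of seconds to move the average appreciably —
which is precisely the distinction between harmful static loading and
harmless movement.

The five per-reading uncertainties combine into the uncertainty $u_k$ of the
filtered value, and the interval $[\bar F_k - u_k,\ \bar F_k + u_k]$ is what
the detector consumes. Two propagation rules are implemented
(`uncertainty_propagation` in `readout_config()`):

* `"sum"` (default): $u_k = \sqrt{\sum_{i=0}^{4} u_{k-i}^2}$ — the
  conservative root-sum-square of the five standard uncertainties.
* `"mean"`: $u_k = \frac{1}{5}\sqrt{\sum u_{k-i}^2}$ — the standard
  propagation for an unweighted mean of independent readings.

The metrologically orthodox rule for a mean is `"mean"`, and it is fully
supported (for constant streams it gives the familiar $u/\sqrt{5}$). The
package nevertheless defaults to `"sum"`, for an operational reason that is
easy to quantify. After normalization, the interval half-width is
$0.025/\sqrt{3}\cdot\sqrt{5} \approx 3.2\%$ under `"sum"` but
$0.025/\sqrt{3}/\sqrt{5} \approx 0.65\%$ under `"mean"`. Sensor noise of
1% (multiplicative, per tick — a realistic figure below the 2.5% accuracy
bound) makes the left-right difference of two normalized 5-point means
fluctuate with a standard deviation near $0.9\%$ once the noise frozen into
the reference is included. Under `"mean"` the decision threshold
($2\times0.65\%$) sits only $1.4\sigma$ out and symmetric sitting
false-flags on roughly 40% of ticks in simulation; under `"sum"` the
threshold ($2\times3.2\%$) sits $\approx 7\sigma$ out and a $10^4$-tick
symmetric run produces no flag at all. A monitor that nags a correctly
seated user is useless, so the conservative rule is the default; the
trade-off is sensitivity (see *Detection threshold* below).

Warm-up is gated: while a queue holds fewer than five entries the filtered
value carries `complete = FALSE` and the detector refuses it. During a
session this matters only for the five initialization frames — the queues
are not cleared when monitoring starts, so the first flag is evaluated on
the very first monitoring tick.

## Initialization and normalization

Nominally identical FSRs differ in gain (fabrication spread) and drift with
temperature, humidity and age. Rather than calibrating each sensor
individually, every session begins with the user holding a correct,
balanced posture while the queues fill; the first complete 5-point average
of each sensor is stored as its **reference**. All subsequent filtered
forces are divided by the reference, so each normalized reading
$n\text{-}Lt, n\text{-}Lb, n\text{-}Rt, n\text{-}Rb$ is $\approx 1$ in the
correct posture regardless of the sensor's absolute response. Re-acquiring
the reference each session (sessions are capped at about 2 h by a soft
guard) keeps slow drift out of the comparison.

The reference is treated as an exact scale factor: the decision intervals
derive from the live measurement only. A config flag
(`propagate_reference_uncertainty`) adds the reference's own uncertainty in
quadrature for sensitivity studies; it widens every interval by the same
relative amount and so only makes the detector more conservative.

Initialization fails loudly if any reference falls below
`min_seated_force` (default 10 N — far below the ~70–170 N a seated adult
puts on each sensor, far above an unloaded sensor's clamped 0 N): either
nobody is seated or a sensor is dead.

## The asymmetry decision

Left and right are compared **within** the top pair and **within** the
bottom pair, never across: shifting load between thighs and hips (moving
the legs, changing knee angle) is not evidence of harmful asymmetry and
must not trigger. The posture is asymmetric exactly when at least one pair
of left/right uncertainty intervals fails to intersect:

$$(n\text{-}Rt^U < n\text{-}Lt^L)\ \lor\ (n\text{-}Rb^U < n\text{-}Lb^L)\ \lor\
  (n\text{-}Lt^U < n\text{-}Rt^L)\ \lor\ (n\text{-}Lb^U < n\text{-}Rb^L)$$

with $L/U$ the lower/upper interval bounds. The inequalities are strict:
intervals that merely touch still count as overlapping, i.e. symmetric.
Flag edges are the events of interest — symmetric→asymmetric opens a
warning (and is recorded), asymmetric→symmetric closes it. The first flag
after initialization is compared against an assumed-symmetric baseline,
since initialization requires the correct posture. Events therefore
strictly alternate, starting with a shift to asymmetric.

**Detection threshold.** Under the default propagation a left/right
normalized gap must exceed $\approx 6.5\%$ to trigger. A leaning posture
that moves the relevant pair's split from 50/50 to 70/30 produces
normalized readings near 1.4 vs 0.6 — a gap of 0.8, an order of magnitude
above threshold — so detection of deliberate postures is robust, while the
false-alarm rate for balanced sitting is negligible.

## The session state machine

A session has exactly two states, initialization and real-time monitoring,
with the single transition initialization→monitoring at the moment the
reference is captured. Malformed serial lines are counted and skipped
without corrupting state (a retry budget during initialization turns
persistent garbage into a connection error). Wall time is derived as
`tick × sampling_interval`, never read from a clock, so identical frame
streams reproduce identical session records bit for bit. Notifications go
through a two-function hook (`open_warning`/`close_warning`) with console
and no-op backends; a GUI or buzzer would attach there.

Shift events are persisted — only for users who registered with explicit
consent — in a local file store (CSV user/session tables plus a JSON-lines
event log) with the recording semantics of a remote monitoring database:
append-only events, per-session alternation enforced as an integrity
constraint, queries returning user ids rather than profile fields. From
the store, `behavior_summary()` computes time-in-asymmetry per session
(spans from each opening event to its closing one; a span still open at
session end counts up to the final tick — the conservative choice for a
health metric) supporting gender/height/weight-informed analyses.

## What the simulator emulates — and what it does not

`generate_trace()` produces frames from a posture schedule by splitting a
total seat load $W$ (default 400 N, roughly the seat-borne share of an
average adult's weight) front/rear (`top_fraction`, default 0.6) and
left/right within each pair, then applying per-sensor gains (fabrication
spread), multiplicative Gaussian noise (default 1%), optional brief
transients, and the forward signal path (calibration → divider → mid-tread
ADC quantization, `counts = round(v (2^{10}-1)/V_{DC})`). The six-posture
protocol — lean forward left/right, lean backward left/right, cross
left/right leg, each followed by a return to the correct posture — is the
standard validation script; the leaning split offset (0.20) and leg-cross
offset (0.25, with a 0.05 front-share increase reflecting the changed knee
angle) are configurable stand-ins chosen to exceed the decision threshold
comfortably at realistic loads, not biomechanical measurements.

The simulator does **not** model real pressure distributions, FSR
hysteresis and creep, temperature/humidity drift within a session, sensor
placement effects, or body-shape variation. Passing tests on simulated
traces therefore demonstrate the correctness of the *algorithmic chain* —
decode, filter, normalize, decide, record — under the stated noise and
split assumptions, not field performance of a physical cushion.

## Numerical and edge-case choices

* Saturation margin: one ADC count-width below the supply; the full-scale
  code always errors, the next one down is accepted.
* Below-calibration conductance clamps to 0 N with a flag (never negative
  force); zero counts on all sensors decode to 0 N ± 0 N.
* Interval tangency counts as overlap (strict inequalities).
* Ties in no other place matter: the flag is a pure OR of four strict
  comparisons.
* Degenerate inputs: empty streams and streams shorter than the queue fail
  initialization with a connection error; a reference below the seating
  guard fails it naming the sensor.
* Tests exercise the chain at deliberately moderate sizes — 10,000-tick
  symmetric property runs, 100 randomized streaming-vs-batch sessions of
  ~30–50 ticks, 250-tick six-posture protocols — sizes at which every
  property is already fully expressed.

## Known limitations

* The `"sum"` default trades sensitivity for specificity: slow, genuine
  asymmetries smaller than ~6.5% of the reference load are not flagged.
  Selecting `"mean"` restores sensitivity at the cost of the false-alarm
  behavior quantified above; the switch exists precisely so that this
  trade-off can be studied.
* The detector is blind to symmetric-but-harmful postures (e.g. slouching
  with even left/right load) by design: only left/right imbalance is in
  scope.
* The per-posture load splits in the simulator are plausible stand-ins;
  absolute detection latencies measured on simulated traces (~2–2.5 s, the
  filter transit) carry over to hardware only insofar as the splits do.
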