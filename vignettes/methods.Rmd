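---
title: "Sprint kinematics from a laser distance trace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sprint kinematics from a laser distance trace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sprintldm)
```

## The measurement

A laser rangefinder stands behind the start line, aimed horizontally at
the athlete's lumbar spine, and reports the distance to that point at a
nominal 100 Hz (internally it measures at 2 kHz and averages), with a
precision of about ±20 mm. Before the run the distance to a vertical bar
on the start line — the calibration distance $L_1$ — is recorded;
displacement past the line is then $x = d - L_1$. Everything this
package computes derives from the sampled pair $(t_i, x_i)$.

The central quantities are the central differences

$$v_i = \frac{x_{i+1}-x_{i-1}}{t_{i+1}-t_{i-1}}, \qquad
  a_i = \frac{v_{i+1}-v_{i-1}}{t_{i+1}-t_{i-1}},$$

with one-sided differences at the ends and the actual (possibly slightly
jittered) sample times in the denominators. Central differencing is
exact for quadratic displacement and second-order accurate otherwise
(for a unit sinusoid at 100 Hz, the error bound is
$h^2/6 \approx 1.7\times10^{-5}$).

## Preprocessing

**Artifacts.** The beam occasionally loses the lower back (arm swing,
low-reflectance fabric, passers-by), producing runs of missing readings
(dropouts) or large positive excursions (spikes — the beam overshoots to
the background). A sample is flagged as a spike when the implied
point-to-point speed both into and out of it exceeds a physical ceiling
(13 m/s by default; elite sprinters peak near 12.5 m/s). Interior
flagged segments are linearly interpolated between clean neighbours;
segments touching either end of the trace are cropped, never
extrapolated.

**Start rule.** The mean and SD of the stationary pre-start signal are
estimated over the first second; the start is the first sample whose raw
displacement exceeds `mean + max(2·SD, 1 cm)` and *remains* above that
threshold for 0.1 s. Three operationalizations were open and are fixed
as follows: (i) the hold duration, unspecified in the rule, is one
smoothing window (0.1 s) — long enough to reject single-sample noise;
(ii) the hold is evaluated on the 0.1 s moving-average trend rather than
on raw samples, because with ±20 mm noise a raw-sample hold fires late
(individual samples keep dipping through the threshold long after the
athlete has left); (iii) the 1 cm floor guards the degenerate noise-free
case where the pre-start SD is zero. A "polynomial" start refinement is
mentioned in descriptions of such systems without a definition; only the
threshold rule is implemented.

**End rule and cropping.** The endpoint is 50 samples after the
displacement first exceeds 60 m (the default measurement range;
configurable to the full race distance — the recovery analyses in the
test-suite crop at 95 m so that all ten 10 m splits stay inside the
window). One second of context is kept on each side and the time axis is
re-zeroed at the detected start.

**Onset time.** For timing purposes the threshold-rule start is biased a
few samples late by construction. The instant of first motion is
estimated by a breakpoint fit around the detected start: flat pre-start
signal, a quadratic rise through the first ground contact, and a second
quadratic switched on at the (grid-searched) end of that contact. The
fit is exact on noise-free traces and has an information-limited SD of
roughly 15 ms at 20 mm noise — early displacement grows like
$\tfrac12 a t^2$ and simply stays under the noise floor for the first
few hundredths of a second, whatever the estimator.

## Smoothing

All smoothing is a centered moving average with edge-clipped windows
(same output length, no phase lag), default window $n = 10$ samples
(0.1 s at 100 Hz). The number of passes is per-variable:

* **displacement** — one pass, to take the edge off sensor noise
  without flattening the step oscillation;
* **velocity (profile stream)** — ten passes. A single 0.1 s window
  attenuates a 4.5 Hz step oscillation only to 70%; ten passes push it
  below 3%, which is what peak-speed, zone and split estimation need.
  The device literature quotes the moving average as "n = 10, m = 10";
  reading m as the pass count is the only interpretation under which
  the filter actually removes the within-step fluctuation it is said to
  remove, so the profile stream defaults to it;
* **detection stream** — one displacement pass plus an $n=3$ velocity
  pass: the step oscillation must survive here.

## Speed zones and splits

The maintenance zone spans from the first to the last sample with
$v \ge (1-\text{tol})\,v_{\max}$ on the hard-smoothed curve
(tol = 2% by default, from the metadata); ascending is everything
before, descending everything after, so the three zones are contiguous
and interior dips stay inside maintenance. Ties on $v_{\max}$ resolve to
the first occurrence.

Split boundaries at 10, 20, … 100 m are crossed between samples; the
crossing times are linearly interpolated, never snapped to the grid. The
time origin is the crease-fit onset (above), so the cumulative time at
100 m is the race time from first motion. The boundary search requires
the displacement to stay above each boundary for a short hold, so noise
wiggle cannot trigger a crossing early.

## Step segmentation

Within a step the horizontal speed of the lumbar point oscillates: it
peaks at the last contact of the push-off leg (toe-off), decreases
through flight under air resistance and gravity, and increases again
from the moment the opposite leg touches down. Touchdowns are therefore
local minima and toe-offs local maxima of the detection velocity.
Candidate extrema are cleaned by (i) merging consecutive same-kind
extrema (keep the more extreme), (ii) removing extremum pairs whose
peak-to-valley amplitude is below 0.05 m/s, and (iii) thinning
touchdowns closer than 0.15 s (sprint step frequency is 3–5 Hz, so
0.15–0.60 s brackets plausible step times). The sprint start is itself
the first ground contact, so a touchdown is seeded at the onset.

Candidate times inherit a systematic shift from smoothing (the smoothed
minimum of an asymmetric kink moves toward the shallower side) and, at
realistic noise, a jitter of tens of milliseconds. Refinement is
two-mode (`refine_method = "auto"` switches on a noise estimate from
second differences of displacement):

* **Crease fit (clean traces).** Each event is a curvature break of
  displacement; a local quadratic-plus-switched-quadratic fit with
  breakpoint grid search and parabolic sub-sample interpolation recovers
  it to well under one sample. This estimator is exact in the noise-free
  limit but information-poor under noise: with ±20 mm white noise the
  per-event Cramér–Rao bound for a *local* kink locator is of the order
  of 100 ms, so no local fit can work there.

* **Matched filter + structural model (noisy traces).** The waveform of
  a whole step repeats from cycle to cycle, so an average cycle template
  (built from the run itself) is slid over each candidate — a
  self-calibrating matched filter using the waveform's entire slope
  energy, accurate to ~10 ms per event. A period tracker alternates with
  a global structural fit — touchdown times are projected onto
  $t_k = \text{poly}_3(k) + a\,(-1)^k$ — which merges duplicate
  detections, fills holes, and makes local phase slips impossible to
  sustain. The left-right alternation amplitude $a$ cannot be taken from
  the template stage (a pooled template encodes the average period and
  shrinks true asymmetry toward zero), so it is re-estimated by a
  dedicated scan: candidate boundaries are laid down, every cycle is
  warped to unit phase and compared against a common Fourier-series
  phase template with free per-cycle gains; wrong alternation shifts odd
  and even cycles' phase origins in opposite directions and inflates the
  residual. A conservative F-type gate against the symmetric null keeps
  the scan's own noise (a few ms) from injecting fake asymmetry into
  every step of a symmetric athlete; asymmetries below roughly ±4 ms of
  alternation (≈ 7% symmetry index at 4.5 Hz) are reported as symmetric
  at full device noise. Absolute event times in this mode retain a
  common group delay of a few tens of ms; all step *durations*, lengths,
  frequencies and symmetry indices are differences and unaffected.

Step metrics follow the phase-time definitions: for touchdowns
$TD_k, TD_{k+1}$ with the toe-off $TO_k$ between them, support
$= TO_k - TD_k$, flight $= TD_{k+1} - TO_k$, step $= TD_{k+1} - TD_k$
(so support + flight = step exactly), length
$= x(TD_{k+1}) - x(TD_k)$ with displacement interpolated at event times,
frequency $= 1/\text{step}$. The first and last steps are flagged as
boundary steps and excluded from symmetry by default. Step length here
is the travel of the lumbar tracking point between touchdowns — a proxy
for foot-to-foot distance, not a ruler measurement. The alternative
toe-off-to-toe-off step convention is available
(`boundary_convention = "toeoff"`); touchdown-to-touchdown is the
default. Braking/propulsion sub-phases within support are not resolved.

The symmetry index is the standard gait convention
$SI = 100\,|\bar v_L - \bar v_R| / \tfrac12(\bar v_L + \bar v_R)$ (no
formula is fixed in the source literature; a signed variant is
available).

## The simulator

The generator emulates exactly the stated world of the method: a 100 m
sprint sampled at 100 Hz with ±20 mm Gaussian noise, beam dropouts
(runs of missing readings) and positive spikes.

* **Base profile** — mono-exponential speed rise
  $v(t) = v_{\max}(1 - e^{-t/\tau})$ with $v_{\max} = 11.5$ m/s and
  $\tau = 1.3$ s (a national-level sprinter: ~10 s over 100 m), times a
  linear decay factor beyond 80 m losing 1.5% of $v_{\max}$ per 10 m —
  the classic terminal deceleration. The decay factor is driven by the
  closed-form undecayed displacement, which keeps the profile explicit
  and continuous.
* **Step cycles** — frequency 4.5 Hz, duty factor 0.45, oscillation
  half-amplitude 0.4 m/s. Each cycle's velocity rises through support
  from the touchdown value $A_k$ to $P_k = A_{k+1} + D_k$ and falls by
  exactly $D_k$ (twice the oscillation amplitude) through flight into
  the next touchdown. The base-speed gain of the cycle therefore rides
  on the support phase — as in real sprinting, where propulsion happens
  on the ground — so every touchdown is a true local minimum and every
  toe-off a true local maximum from the very first step. The touchdown
  offsets solve a forward recursion that makes every cycle's mean speed
  equal the base profile's mean over that cycle, so step-averaged speed,
  split times and the displacement envelope all track the base profile;
  velocity is continuous everywhere and starts at rest.
* **Asymmetry** — left step time $(1 + a/2)$ and right $(1 - a/2)$
  times the base period, so the programmed symmetry index of step time
  is exactly $100|a|$; oscillation amplitude can be made asymmetric the
  same way.
* **Integration** — velocity is integrated on a fine grid (20× the
  sample rate, with every event time as a knot) and sampled; with the
  oscillation off, the sampled displacement matches adaptive quadrature
  of the base profile to better than $10^{-6}$ m.

One seed drives all randomness; the ground truth (start time, every
touchdown/toe-off, per-step table, base peak speed, 100 m time) is
recorded before noise is added and is therefore unaffected by it.

What the simulator does **not** emulate: lateral lane drift and the
angle-induced distance error, body-part-dependent reflections, wind,
block reaction time (motion starts at the first touchdown), within-step
braking/propulsion substructure, and any coupling between fatigue and
step shape beyond the smooth frequency/amplitude drift of the base
profile. A green recovery test therefore establishes correctness of the
*signal-processing chain* under the stated noise model, not validity
against force-plate or motion-capture ground truth.

## Numerical choices and degenerate inputs

* Sample SD (divisor $n-1$); skewness and excess kurtosis from central
  moments with divisor $n$, reported `NA` for $n < 3$ / $n < 4$ or zero
  variance; the mode of continuous data is taken after rounding to two
  decimals, ties resolving to the smallest value; a single observation
  reports `sd = 0` and is flagged degenerate.
* Parsing accepts both text layouts (two long rows: time then distance;
  or two columns), whitespace or semicolon separators, `.` or `,`
  decimals, and a millimeter-input flag; time must be strictly
  increasing with the median interval within 10% of the nominal rate.
* A constant speed curve yields a maintenance zone covering the whole
  run and empty ascending/descending zones; zone segmentation never
  fails on degenerate input (the peak sample is always in-zone).
* All grid searches (crease fits, template shifts, alternation scan)
  refine their discrete minimum by parabolic interpolation and clamp the
  sub-sample correction to one grid step; ordering violations after
  refinement revert to the pre-refinement time.
* Masks covering a whole trace, traces that never reach the end
  distance, runs with fewer than two touchdowns, and symmetry requests
  with an empty side all raise classed conditions
  (`ldm_repair_error`, `ldm_end_not_reached_error`,
  `ldm_no_steps_error`, `ldm_symmetry_unavailable_error`, …) rather
  than returning half-filled objects.

## Known limitations

* At full device noise the left-right asymmetry detection floor is
  about ±4 ms of alternation; smaller true asymmetries are reported as
  symmetric (by design of the significance gate), and per-run symmetry
  indices for *length- and speed-type* variables carry ~1–2 percentage
  points of sensor-noise uncertainty.
* Absolute event times from the noisy-trace path carry a common group
  delay of tens of ms (difference-based quantities do not).
* The structural phase model assumes step frequency varies smoothly
  through the run apart from the left-right alternation; gait patterns
  violating that (e.g. a stumble) will be bridged by the tracker and
  flagged only indirectly through long-gap reporting.
* The onset time is information-limited to ~15 ms SD at 20 mm noise,
  which propagates into the cumulative split times as a common offset.
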