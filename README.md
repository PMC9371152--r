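# sprintldm

Sprint kinematics from laser distance-measurement (LDM) traces.

A laser rangefinder placed behind the start line and aimed at a sprinter's
lower back returns the distance to the athlete at 100 Hz. Subtracting the
calibration distance `L1` (laser to start line, measured against a vertical
bar before the run) turns raw distance `d` into displacement past the start
line, `x = d − L1`, and differencing displacement gives the running speed in
every hundredth of a second:

```
v_i = (x_{i+1} − x_{i−1}) / (t_{i+1} − t_{i−1}),
a_i = (v_{i+1} − v_{i−1}) / (t_{i+1} − t_{i−1}).
```

That one noisy curve carries a remarkable amount of structure, and this
package extracts all of it:

* **Preprocessing** — beam dropouts and spikes are detected and repaired;
  the start is found where the raw displacement rises and remains more
  than 2 SD above the pre-start noise level; the end is a fixed 50 samples
  after the 60 m crossing (configurable to the full 100 m).
* **Velocity profile** — two streams are kept: a hard-smoothed one
  (10 passes of the 0.1 s moving average) for peak speed, the three speed
  zones (ascending / maintenance within 2% of peak / descending) and the
  ten 10 m split times; and a lightly smoothed one that preserves the
  within-step velocity oscillation.
* **Step analysis** — the running speed peaks at the last contact of the
  push-off leg (toe-off), falls through flight, and rises again from the
  opposite leg's first contact (touchdown). Local extrema of the
  oscillation segment the run into steps; event times are refined by a
  breakpoint fit (clean traces) or a self-calibrating matched filter with
  a structural phase model (noisy traces). Per step: support, flight and
  step time, length, frequency, mean speed, left/right side.
* **Symmetry** — the classic symmetry index
  `SI = 100·|mean_L − mean_R| / (0.5·(mean_L + mean_R))` for speed, step
  length, support time, flight time, step frequency and step time.
* **Statistics & report** — mean, median, mode, min, max, SD, skewness,
  excess kurtosis, Pearson correlation; everything bundled into a JSON +
  CSV report with full provenance.
* **Simulator** — synthetic 100 Hz traces with a mono-exponential speed
  rise, terminal deceleration, per-step oscillation, configurable
  left/right asymmetry, ±20 mm Gaussian sensor noise, dropouts and
  spikes — with exact per-step ground truth, so every stage is testable
  without any recorded data.

## Worked example

```r
library(sprintldm)

sim  <- synthesize_trace(sim_config(seed = 42))        # 100 m, 20 mm noise
meta <- measurement_meta(calibration_distance_L1 = 7.3,
                         first_leg_on_start = "L")
res  <- analyze_sprint(sim$trace, meta,
                       start_end = start_end_config(end_distance = 95),
                       seed = 42)
res
#> <sprint_analysis>
#>   run: 102.00 m in 11.14 s, peak speed 11.51 m/s
#>   splits: 10 complete sections, cumulative 10.04 s at 100 m
#>   steps: 46 detected, mean step time 0.224 s, mean length 2.26 m
#>   symmetry index: speed 1.77%, step_length 1.78%, support_time 1.60%,
#>     flight_time 1.46%, step_frequency 0.04%, step_time 0.04%

head(res$splits[, 1:6], 4)
#>   section_from_m section_to_m split_s cumulative_s mean_speed max_speed
#> 1              0           10  1.8676        1.868      5.354     8.832
#> 2             10           20  1.0433        2.911      9.585    10.258
#> 3             20           30  0.9415        3.852     10.621    10.974
#> 4             30           40  0.9045        4.757     11.056    11.232

res$zones
#> <speed_zones> v_max = 11.507 m/s (tol 2%): ascending [1, 583],
#>   maintenance [584, 1037], descending [1038, 1115]
```

The simulated athlete was generated with a base peak speed of 11.5 m/s
and crossed 100 m at 10.02 s (ground truth); the analysis recovers
11.51 m/s and 10.04 s from the noisy trace alone. The step count (46) is
exact, and with no programmed asymmetry the step-time symmetry index
stays at 0.04%. (Step *length* and speed symmetry carry the sensor
noise — roughly ±2% per run at 20 mm noise — which is why they are
nonzero here.)

Real device files are read with `read_ldm()` (two long rows — time then
distance — or two columns; `.` or `,` decimals) and metadata with
`read_meta()`; `analyze_sprint()` takes it from there.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/sprintldm.R", package="sprintldm"))') \
    simulate --seed 3 --out sim/
Rscript ... analyze sim/trace.txt --meta sim/meta.txt --out analysis/ \
    --end-distance 95
```

`analyze` writes `report.json`, `splits.csv`, `steps.csv`, `zones.csv`,
`symmetry.json` and `mask.csv` into the output directory.

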