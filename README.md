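# chemogas

Simulation and signal processing for **pressure-based biogas monitoring**
in multiplexed laboratory anaerobic chemostats.

Bench-scale anaerobic digesters (50–200 mL working volume) can measure
their own ecosystem performance with a single pressure sensor: the sealed
headspace pressurizes as the community produces biogas, and a hysteresis
controller vents it from an upper threshold (1.2 bar) down to a lower one
(1.05 bar), yielding a sawtooth pressure log sampled every 20 s. The gas
produced between two times follows from the ideal-gas law,

V_STP = ΔP_cum · V_head / 1.013 bar · 293.15 K / T,

where ΔP_cum is the rise of the *cumulated* pressure curve (sawtooth drops
stitched back in) and V_STP is the biogas volume at standard conditions
(293.15 K, 1.013 bar). Production rates are the OLS slope of V_STP against
time, reported with r², the slope standard error, and the point count.

The package serves experimentalists running such reactors (and developers
of their acquisition software) with two complementary halves:

* **a reactor digital twin** — ideal-gas headspace physics, the hysteresis
  degassing controller, pulse feed/waste schedules, a quantizing noisy
  sensor model (0.0015 bar steps), Henry-law dissolved-gas
  re-equilibration, and injectable sampling/leak artifacts — producing raw
  logs with exact ground truth (`simulate_reactor()`);
* **the processing pipeline** — degassing-event detection and stitching,
  rate-of-change spike rejection, STP normalization, and rate regression
  (`run_pipeline()`), plus linear pump/sensor calibration
  (`fit_calibration()`) and weekly COD-normalized comparison of replicated
  inocula via tie-corrected Kruskal–Wallis and Dunn post-hoc tests
  (`weekly_rates()`, `compare_weekly()`).

## Worked example

Simulate five days of a mesophilic reactor producing 7.6 mL/d of biogas
into a 50 mL headspace, then recover the rate from its noisy sensor log:

```r
library(chemogas)

cfg <- reactor_config(headspace_volume_mL = 50, temperature_K = 310.15,
                      henry_capacity_mL_per_bar = 0)
sim <- simulate_reactor(cfg, production_profile(7.6), duration_d = 5,
                        seed = 42)
sim
#> <reactor_sim> R1: 21601 samples over 5.00 d, 5 degassing events
#>   produced 38.00 mL STP, degassed 34.58 mL STP, balance residual 7.11e-15 mL

run_pipeline(sim$trace, sim$events, cfg)
#> <pipeline_result> 5 degassing events, 0 spike(s) removed
#> Biogas production rate: 7.589 mL/d (SE 0.0003, r2 1.0000, n = 21601)
```

Reading the output: the twin produced 38.0 mL of gas (7.6 mL/d × 5 d), of
which 34.58 mL was vented over 5 degassing cycles (each 0.15 bar cycle of
this headspace holds ≈7.0 mL STP) and the rest is still pressurizing the
headspace; the mass balance closes to machine precision. The pipeline,
given only the sensor trace and the controller log, recovers
7.589 mL/d — within 0.2% of truth — with a slope standard error of
0.0003 mL/d over 21 601 samples.

The same workflow runs from the shell via the bundled CLI
(`inst/exec/chemogas`): `simulate`, `process`, `calibrate` and `compare`
subcommands exchange plain CSV/YAML files and each run writes a JSON
manifest that reproduces it bit-identically.

## Scope

Production is an exogenous profile (constant, piecewise, or first-order);
no microbial kinetics, gas composition, or thermal dynamics are modelled.
See the methods vignette (`vignettes/pressure-to-biogas.Rmd`) for the
model equations, parameter defaults and the reasoning behind the numerical
design choices.
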