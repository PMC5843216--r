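---
title: "From raw pressure logs to biogas production rates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw pressure logs to biogas production rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemogas)
```

## The measurement principle

Small anaerobic chemostats can quantify biogas production with nothing but a
pressure sensor: the vessel is sealed, gas accumulates in the headspace, and
when the absolute pressure reaches an upper threshold (1.2 bar by default) a
peristaltic pump vents the headspace until the pressure falls to a lower
threshold (1.05 bar). The raw log is therefore a sawtooth. Because the
headspace volume $V_h$ and temperature $T$ are known, the ideal-gas law maps
any accumulated pressure rise $\Delta P$ to a biogas volume at standard
conditions (293.15 K, 1.013 bar):

$$V_\mathrm{STP} = \Delta P \cdot \frac{V_h}{1.013\,\mathrm{bar}} \cdot
  \frac{293.15\,\mathrm{K}}{T}.$$

`chemogas` implements both sides of this measurement chain: a reactor
digital twin that generates realistic raw logs with known ground truth, and
the processing pipeline that converts such logs into cumulative volumes and
least-squares production rates. The twin exists so that every step of the
pipeline can be validated against a known answer — something the physical
system can never provide.

## The reactor model

The simulator tracks the headspace as an STP-equivalent gas volume $G$ (mL),
with $P = G \cdot 1.013 \cdot T / (V_h \cdot 293.15)$. Each sampling
interval (20 s by default, matching the acquisition period):

* production adds $r(t)\,\Delta t$ to $G$, where $r(t)$ is an exogenous
  profile in mL STP d$^{-1}$ — constant, piecewise constant, or first-order
  decaying. No microbial kinetics are modelled: production is an input, not
  a prediction. Defaults span the observed range of roughly 2–64 mL/d for
  mesophilic digesters of this size;
* a dissolved-gas pool $D$ relaxes first-order toward its Henry-law
  equilibrium $D^* = k_H P$ at rate $k_r$ (defaults $k_H = 5$ mL STP/bar,
  $k_r = 1$ h$^{-1}$). After each degassing the drop in $P$ makes the pool
  outgas, reproducing the small post-venting re-equilibration bumps seen in
  real traces (~0.75 mL after a 0.15 bar cycle with the defaults). The
  pipeline deliberately does **not** correct for these bumps: over whole
  cycles the pool has no net trend, and treating outgassed CO₂/CH₄ as
  production is consistent with how such data are analysed in practice;
* while the hysteresis controller is in degassing mode, gas leaves at the
  pump rate (30 mL/min at reactor conditions by default — enough to empty a
  1.2→1.05 bar cycle of a 50 mL headspace within one sample), clamped so
  the pressure stops exactly at the release threshold;
* the sensor adds Gaussian noise (SD = half a quantization step by default)
  and quantizes to multiples of 0.0015 bar, saturating at the sensor's
  3.4 bar rating. The controller acts on the *measured* reading, as the
  real acquisition loop does.

Integration uses explicit Euler steps equal to the sampling interval. The
signals are slow relative to 20 s, and fixed steps keep simulator state
aligned with sensor samples; the bookkeeping is exact, so
produced $= \Delta G + \sum \mathrm{degassed} + \Delta D$ holds to machine
precision for every configuration — a property the test suite asserts at
$10^{-9}$ relative tolerance.

Feed and wasting are hourly pulse schedules (24 × 0.5 mL/d each by
default, i.e. 12 mL/d wasted from a 180 mL working volume — a 15-day
hydraulic retention time). Pulses are logged as events but do not enter the
gas physics: dilution and biology are out of scope.

Artifacts reproduce the technical disturbances of real logs: transient
spikes (deviate, then revert), persistent steps (liquid sampling frees
headspace volume, so the pressure drops and stays down), and slow leak
ramps whose loss persists after the leak is fixed. Persistent steps are the
disturbance that actually corrupts a cumulated signal — a transient
symmetric spike contributes nothing to an OLS slope over thousands of
points — so the filter-ablation validation uses sampling steps.

## The processing pipeline

Three signal-processing steps turn a raw trace into a cumulative volume:

1. **Degassing removal.** Events come either from the controller's own log
   (authoritative) or from the trace signature: a maximal run of
   consecutive negative steps dropping at least 0.05 bar, starting near the
   upper and ending near the lower hysteresis level. By default those
   levels are inferred from the trace quantiles, which makes detection —
   and hence the whole pipeline — invariant to a constant pressure offset.
   Each event's drop is added back as a running offset
   ("cumulated absolute pressure"); samples recorded while the pump ran are
   flagged and bridged by carrying the pre-event value forward rather than
   interpolating, so no signal is invented. The production that occurs
   during the pump-out window itself is genuinely lost to the measurement;
   with a one-sample window this costs at most ~0.3% at 100 mL/d and far
   less at typical rates.

2. **Spike rejection.** Any single-sample increment of the cumulated curve
   larger than a limit is zeroed in one forward pass (the sample is
   flagged; the filter is idempotent; increments across data gaps are held
   to the same limit scaled by the gap duration). Two readings of the limit
   are supported. The *rate* reading (10 mbar min$^{-1}$, i.e. 3.33 mbar
   per 20-s sample) is the stricter historical convention. The package
   defaults to the *per-sample* reading (10 mbar per measurement) for a
   numerical reason worth spelling out: with a 1.5 mbar sensor LSB and
   noise of the same order, legitimate readings occasionally jump three
   quantization cells (4.5 mbar) between samples. Zeroing such a jump does
   not remove a transient — it permanently shifts the cumulated curve by
   4.5 mbar, and those shifts accumulate into percent-level rate errors at
   low production rates. A 10 mbar per-sample limit sits ~9 noise SDs above
   any legitimate single-sample change (the production signal itself is
   < 0.5 mbar/sample even at 100 mL/d) while still catching real artifacts,
   which are 10–15 mbar and larger. Users wanting the strict rate reading
   pass `rate_limit_mbar_min = 10`.

3. **STP normalization** by the ideal-gas formula above, followed by
   ordinary least squares of volume on time (days). The reported quartet is
   slope (mL/d), $r^2$, the slope standard error
   $\sqrt{\hat\sigma^2 / \sum(t_i-\bar t)^2}$, and the point count.

One further numerical choice matters. The reading that *triggers* a
controller transition is selection-biased: degassing starts on the one
sample whose noisy, quantized value happened to cross 1.2 bar (biased
high), and ends on the one that crossed 1.05 bar (biased low). Using those
two readings as the event's endpoints overstates every drop by ~2 mbar,
which at ~one event per 7 mL of gas compounds to a +1.3% rate bias.
`detect_degassing()` therefore estimates each endpoint by fitting a short
local line to the neighbouring samples — excluding the crossing sample —
and evaluating it at the boundary time. On a clean piecewise-linear
sawtooth this is exact; under noise it is unbiased.

Order of operations is fixed: degassing removal strictly precedes spike
filtering, because a 150 mbar degassing drop would otherwise trip any spike
rule (conveniently, this also means a degassing event *missed* by the
detector is caught by the filter as a backstop rather than corrupting the
curve).

## Weekly performance and inoculum comparison

For chemostat experiments, rates are summarized per 7-day window aligned to
the start of the run and normalized by the daily organic load
($\mathrm{OLR} \times V_\mathrm{working}$), giving
mL d$^{-1}$ gCOD$_\mathrm{added}^{-1}$ — comparable across periods with
different substrate loads. Replicated reactors grouped by inoculum origin
are compared per week with a tie-corrected Kruskal–Wallis test implemented
from the rank formula (the chi-square null with $k-1$ df; all-identical
data give $H=0$, $p=1$ by convention), followed — only when the omnibus
test is significant at 0.05, unless forced — by Dunn's pairwise post-hoc
with Holm adjustment by default. The adjustment method is always recorded
in the output, since published workflows often leave it implicit. One
sobering arithmetic fact the tests encode: with four replicates per group,
Dunn's adjacent-pair $|z|$ cannot exceed $4/\sqrt{6.5} \approx 1.57$ even
under perfect separation, so only extreme pairs can reach $p < 0.05$ —
a power constraint inherent to the design, not a software limitation.

## What the simulator does and does not emulate

The twin reproduces the *measurement chain*: sawtooth dynamics, sensor
quantization and noise, controller timing, re-equilibration bumps,
sampling/leak artifacts, pulse schedules. It does not emulate biology
(production is exogenous), gas composition (total biogas only, no CH₄/CO₂
split, no vapor-pressure correction), thermal dynamics (temperature is
constant), or liquid-volume effects of pulses. Consequently, passing
validation demonstrates that the *pipeline* recovers what the *sensor*
could see — it says nothing about whether a real community produces gas at
a given rate, and real data will add slow drifts (temperature, biology)
that the constant-rate scenarios do not contain.

Two scope choices follow from this. First, parameter-recovery scenarios
disable the dissolved pool: a low-rate reactor that never degasses can park
a double-digit percentage of its early production in the liquid transient,
and that is reactor physics, not a pipeline error — the pipeline correctly
reports gas delivered to the headspace. Second, the effective headspace
volume is a required input, not derived from bottle-minus-liquid: tubing
and sensor-line dead volume make the effective value larger than geometry
suggests, which is also why real systems show fewer degassing events per
day than the nominal bottle headspace predicts.

## Problem sizes and reproducibility

Validation runs use 2–5.7 simulated days at 20-s sampling (17 000–25 000
samples per reactor), the scales at which weekly rates are estimated in
practice; the Kruskal–Wallis null calibration uses 10 000 Monte-Carlo
replicates of three groups of ten. All randomness flows from explicit
integer seeds: the same seed reproduces a simulation bit-identically, and
every command-line run writes a JSON manifest (version, seed, configuration
snapshot, paths, flag counts) sufficient to re-run it exactly.

## Known limitations

* Production during a pump-out window is unrecoverable by construction
  (carry-forward bridging); the loss grows linearly with degassing
  frequency (~0.3% at 100 mL/d, one-sample windows).
* The spike filter cannot distinguish a genuine sub-threshold disturbance
  from signal; slow leaks below the limit pass through and bias rates low,
  as they would any pressure-based method.
* The chi-square null for $H$ is asymptotic; at very small group sizes its
  type-I error sits slightly below nominal (≈0.046 at $n=10$ per group).
* Signature-mode event detection assumes drops complete within a run of
  consecutive negative steps; a pump slower than ~2 samples per cycle with
  high noise could fragment a run, though the filter backstop bounds the
  damage.
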