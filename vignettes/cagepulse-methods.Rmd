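---
title: "Methods: from capacitance signals to activity metrics and response durations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from capacitance signals to activity metrics and response durations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagepulse)
```

## The measurement model

A digitally monitored home cage carries a board of 12 planar capacitive
electrodes under the floor, arranged in 4 rows (front to rear) of 3, each
sampled every 250 ms. Animals are dielectric loads: a mouse sitting over an
electrode shifts its capacitance statically, and a mouse *moving* changes it
from one 250 ms sample to the next. The package's basic activity metric is
therefore the thresholded first-order difference: electrode $e$ produces an
*activation event* on the sample pair $(t-1, t)$ when

$$|c_e(t) - c_e(t-1)| > \theta_e,$$

where $\theta_e$ separates electronic noise from movement. All downstream
quantities are counts or fractions of these events. The metric is a
cage-level (group) measure — with five mice per cage no attribution to
individual animals is attempted, and none of the methods here require it.

Three derived quantities are used throughout:

* **activity** of a time bin: events divided by *valid* electrode-pair slots
  in the bin, a fraction in $[0,1]$. The unit is chosen so that reported
  magnitudes (nocturnal peaks around 0.1–0.17) are directly comparable
  across cages regardless of missing data;
* **normalized activity**: activity divided by its mean over a reference
  window, by default the cage-change cycle, giving each window mean 1 — the
  right scale for comparing responses between groups with different base
  rates (e.g. sexes);
* **fraction of activity**: the percentage of total activity falling in a
  part of a partition (day vs night of each 24 h day, or the four floor
  areas). Parts always sum to 100%.

## Thresholds

The threshold policy is $\theta_e = k \times \hat s_e$ with $k = 4$ by
default, where $\hat s_e$ is a robust scale (MAD $\times$ 1.4826) of the
signed first differences in a quiescent window — mid-day (3–9 h after
lights-on), when nocturnal mice rest, so the differences are dominated by
sensor noise. Both per-electrode (default) and pooled variants exist, and a
fixed numeric threshold can be given instead. For pure Gaussian sensor noise
with per-sample SD $\sigma$ the differences are $N(0, 2\sigma^2)$; with a
known-σ threshold $\theta = 4\sigma$ the false-event rate is
$2\Phi(-4/\sqrt2) \approx 0.468\%$ — the analytic limit used to validate the
detector on zero-animal simulations.

## Binning conventions and missing data

A pair of samples forms a differencing slot only if the two samples are at
most `max_pair_gap` (two sampling periods, 500 ms) apart and both are
finite; differencing never spans recording gaps. A pair belongs to the bin
containing its *later* sample, so a fully sampled minute holds 240 slots per
electrode. Bins report both events and valid slots; a bin with zero valid
slots is missing (`NA`), never zero, and all summaries weight by valid
slots. This makes the floor-area decomposition exactly conservative: the
slot-weighted mean of the four area series reproduces the global series to
floating-point accuracy, which the test suite asserts at $10^{-12}$.

Cycle labels follow the husbandry calendar: consecutive cage-change events
delimit cycles ("weeks"), and cycle day 0 is the calendar day of the
cage-change, so a Monday weighing after a Thursday cage-change lands on
cycle day 4.

## Response quantification (FWHM)

Event-locked responses — lights-on, lights-off, cage-change — are measured
on the minute activity series with a full-width-half-maximum block rule:

1. smooth the minute series with a centered 30-min moving average;
2. find the peak within the search window (lights-on ±3 h; lights-off
   0–720 min, the full dark period; cage-change 0–6 h — all configurable);
3. take the contiguous blocks of minutes strictly above half the peak;
4. merge blocks separated by fewer than 5 minutes;
5. the block containing the peak defines the response: its extent is the
   duration, its mean the average response activity.

Numerical choices where the rule needed pinning down: ties at exactly half
peak are excluded (the rule is strictly "larger than half"); peak ties
resolve to the earliest maximum; at the series edges the smoothing window
truncates to the available bins; the duration is the block extent counted in
minute bins (last − first + 1), which reproduces the closed form for a
60-min rectangular pulse (trapezoid after smoothing, half-max width 60 ± 1)
and matches a brute-force block enumerator on randomized series. A 4-min gap
between blocks merges; a 5-min gap does not.

The "90th-percentile" metrics are computed as the 90th percentile of the
smoothed values in the window, with `time_to_p90` the first minute at or
above it. A literal reading — first crossing of $0.9\times$ peak — is
available via `p90_mode = "peak_fraction"`; the quantile reading is the
default because reported p90 values in this kind of analysis sit near 85% of
the peak, inconsistent with the $0.9\times$ reading.

Two aggregation modes exist, and they answer different questions.
`event_responses()` measures each repeat separately (per-week mode, for
longitudinal comparisons); `event_profile()` and `lights_off_profile()`
average the event-locked minute traces across repeats *first* and measure
once (averaged mode). Averaging first matters for duration estimates of
low-amplitude responses: single-trace minute activity is strongly
overdispersed (movement comes in bouts), so a single supra-half-max block
can fragment; averaging across a handful of repeats suppresses this and
makes FWHM recovery stable. The lights-off profile is additionally
normalized so its peak is exactly 1.0 before time-to-peak and p90 metrics
are read off.

## The synthetic cage

No recordings are distributed with the package, so every stage is validated
against a generative model whose ground truth is known — the simulator is a
first-class module, not a test fixture.

**Movement.** Each of the $n$ mice (default 5) is a two-state semi-Markov
walker on the 20 × 25 cm floor (~500 cm²). A resting mouse becomes active
with hazard $\lambda(t)\prod_k g_k(t)$; an active mouse takes reflected
Gaussian steps (SD 2 cm per 250 ms tick, ~8 cm/s when moving) and reverts to
rest with constant hazard $1/30$ s⁻¹ (30 s mean bouts). This is the simplest
mechanism that yields threshold-crossing capacitance differences
proportional to movement; huddling, following and other social couplings are
not modelled — passing tests therefore say nothing about such structure in
real data.

**Circadian template.** $\lambda(\tau)$ is piecewise log-linear over the
24 h day with named knots: pre-dawn rise from 90 min before lights-on, a
burst peaking at lights-on decaying over ~1 h, a flat daytime rest level, a
step up at lights-off ramping to a nocturnal peak `time_to_peak` minutes
into the dark period, and a late-night decline from 8 h after lights-off.
Default hazard levels (rest 0.0008 s⁻¹, lights-on burst 0.008, night onset
0.005, night peak 0.016, late night 0.003) were calibrated once so that
simulated minute activity lands where field systems report it: daytime rest
~0.02–0.04, smoothed nocturnal peak ~0.12–0.2 activations per slot, and
roughly 80% of daily activity at night.

**Presets.** `preset_scenarios()` encodes qualitative site/sex profiles:
`CNR-like` (fast nocturnal ramp, higher gain), `KI-like` (protracted ramp
peaking 440 min after lights-off), `JAX-like` (bi-phasic dark period),
`male-KI-like` (cage-change carry-over decaying over ~1.5 days, lower
overall activity), `biweekly` (14-day cycles), and a `no-intervention`
negative control whose calendar only labels. These are phenomenological
mimics, not fits — the source recordings are unavailable, so no preset
should be read as a quantitative reconstruction of any site.

The KI-type template declines *gradually* for ~2 h after its 440-min peak
rather than dropping straight to the late-night level. This is a deliberate
shape choice: a centered moving average shifts the argmax of a peak with
very asymmetric flanks toward the shallow side by up to
$\tfrac{w}{2}\cdot\tfrac{s_2-s_1}{s_1+s_2}$ (~13 min for the steep-fall
variant), which would bias any time-to-peak recovery regardless of data
volume. With the gradual decline the recovery is unbiased to a few minutes.

**Electrode model.** Electrode $e$ reads
$b_e + \sum_m a_m \exp(-d_{me}^2 / 2\kappa^2) + \varepsilon$, with
per-mouse couplings $a_m$ (log-normal around 2.2), per-electrode noise SD
drawn once per scenario (log-normal around 0.05, recorded in the truth
object), and proximity scale $\kappa = 2.5$ cm. $\kappa$ is deliberately
well below the electrode pitch (~6.5 cm): at pitch-scale blur a mouse over
one electrode row registers on the neighbouring row almost as strongly, and
the floor-area decomposition loses its meaning; at 2.5 cm, mice confined
over the front row produce ≥ 90% of their events there, which is what an
under-floor proximity sensor is supposed to do.

**Events.** Interventions act multiplicatively on $\lambda$:
exponential-decay kernels (cage-change: gain 3 decaying over 2 h; weighing:
gain 2 over 1 h), an optional multi-day carry-over factor for the male-type
response, and rectangular kernels of exact duration for controlled
response-duration recovery experiments. Gains of overlapping events
compose multiplicatively.

**Reproducibility.** All randomness flows from one seed: electrode noise
and state-transition uniforms are pre-drawn vectorized and indexed by tick
(so scenario variants under a common seed are coupled — common random
numbers), walk steps come from the same RNG stream, and multi-day runs are
simulated in daily chunks whose concatenation is *exactly* the monolithic
simulation (verified bitwise in the tests). The raw signal of one day is
~33 MB in memory, which is why the multi-day driver (`run_scenario`)
processes day chunks and keeps only the minute series.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as follows:
4 weeks for the lights-off time-to-peak recovery (27 complete dark periods);
6 daily repeats per condition for the FWHM duration ladder {30, 60, 120,
240} min; 3 weeks for the male carry-over contrast; 50 replicates of 14
days (two 7-day cycles) for the no-intervention exchangeability control,
tested by permutation (199 shuffles of the cycle-day labels of the daytime
week × day cells, α = 0.01); and one hour of zero-mouse signal (≥ 10⁵
pairs) for the analytic noise limit. These sizes were chosen so each check
has comfortable statistical margin (e.g. the time-to-peak estimator's
spread across seeds is ~4 min against a ±20 min acceptance band).

## Known limitations

* The activity unit is a fraction of valid slots; systems that report raw
  activation counts differ by a constant only under complete sampling.
* Thresholds estimated from the mid-day window assume mice actually rest
  then; a cage that is active all day inflates $\theta$ and deflates
  activity.
* The simulator's mice are independent; group dynamics (huddling, chasing)
  and slow drifts in electrode baselines are not emulated, so passing
  recovery tests does not certify behaviour of the pipeline under such
  artefacts.
* The day/night fraction assumes the 12/12 instant light schedule; dawn/dusk
  ramps are out of scope.
* Statistical testing of site/sex/week effects is intentionally excluded:
  the longitudinal table is an export for external rank-based tests, and the
  permutation diagnostic included here is a negative-control check, not an
  inference procedure.
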