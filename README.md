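# cagepulse

Analysis of continuous home-cage activity monitoring for group-housed mice,
recorded with a board of 12 capacitive electrodes (4 rows × 3 columns)
mounted under the cage floor and sampled at 4 Hz. Moving animals perturb the
capacitance of nearby electrodes; `cagepulse` turns those raw signals into
quantitative behavioural read-outs for husbandry and phenotyping studies:
diurnal activity rhythms, floor-area usage, and the magnitude and duration
of responses to lights-on, lights-off and cage-change interventions.

## The metric and the response measure

The basic activity metric is the thresholded first-order difference of each
electrode signal: an *activation event* on electrode *e* at sample pair
*(t−1, t)* is

|c_e(t) − c_e(t−1)| > θ_e,

with θ_e = k·(robust noise scale) estimated from the mid-day rest period
(k = 4 by default). Binned **activity** is the fraction of valid
electrode-pair slots in a bin that carry an event; **normalized activity**
divides by the mean over a cage-change cycle; **fractions** allocate
activity across day/night or the four floor areas (front → rear rows of
three electrodes).

Event-locked responses are quantified with a full-width-half-maximum (FWHM)
rule on the 30-min-smoothed minute series: find the peak in the search
window, take contiguous blocks of minutes strictly above half the peak,
merge blocks separated by fewer than 5 minutes, and report the peak block's
extent (duration), its mean (average response activity), the time to peak,
and 90th-percentile value/time. The dark-period profile is additionally
averaged across weeks and normalized to peak = 1.0 before time-to-peak is
read off.

Because raw recordings of this kind are rarely shareable, the package ships
a stochastic cage simulator (two-state random-walk mice over a Gaussian
proximity-kernel electrode model, circadian hazard template, multiplicative
intervention kernels) with full ground truth, so the entire pipeline is
validated by parameter recovery. See the methods vignette
(`vignettes/cagepulse-methods.Rmd`) for the model and all numerical
conventions.

## Worked example

Two simulated weeks of a slow-nocturnal-ramp cage (five mice, weekly
Thursday cage-change, Monday weighing), then the standard read-outs:

```r
library(cagepulse)
scenario <- preset_scenarios()[["KI-like"]]
run <- run_scenario(scenario, weeks = 2, seed = 42)

activity_fraction(run$activity, "phase", per = "all")
#>    day_pct night_pct
#> 1 16.80136  83.19864

lights_off_profile(run$activity, light_schedule())
#> <lights_off_profile> cage KI-like: 13 dark period(s)
#>   time to peak 439 min; p90 0.737 at 397 min; peak 0.1779 activations

cc <- run$calendar$events$time[run$calendar$events$type == "cage_change"]
event_responses(run$activity, cc, "cage_change")[,
  c("peak_value", "time_to_peak", "fwhm_duration", "average_in_fwhm")]
#>   peak_value time_to_peak fwhm_duration average_in_fwhm
#> 1 0.04622685           34            57      0.03347385
#> 2 0.05414352           23            77      0.04475604
```

Read: the cage does 83% of its activity at night; the averaged dark-period
trace peaks 439 min after lights-off (the scenario's generative truth is
440), at 0.178 activations per electrode-pair slot; each weekly cage-change
triggers a response lasting roughly an hour at about double the daytime
baseline.

`run_scenario()` is a convenience driver; the pieces compose explicitly as
`simulate_cage()` / `read_signal()` → `detect_activations()` →
`bin_activity()` / `spatial_group()` → `normalize_activity()`,
`activity_fraction()`, `smooth_series()` + `find_response()`,
`heatmap_matrix()`, `actigram()`, `build_longitudinal_table()`.

A thin command-line interface covers the same chain for shell use
(`inst/exec/cagepulse`): `validate`, `simulate`, `activity`, `respond`,
`summarize`.

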