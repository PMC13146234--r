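---
title: "Estimating secondhand-smoke exposure opportunity from passive Wi-Fi sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating secondhand-smoke exposure opportunity from passive Wi-Fi sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shscount)
```

## The problem

Designated outdoor smoking areas sit in public space: smoke drifts, and
nonsmokers walk through the affected zone. Concentration studies measure
*how much* smoke is present; survey studies measure *who reports*
exposure. `shscount` addresses a third, operational question: **how many
people are present within a plausible exposure range** over a day — an
exposure-opportunity count. The instrument is a passive Wi-Fi packet
sensor that logs probe requests (timestamp, salted-hash device id,
vendor OUI, RSSI) from phones near an outdoor smoking area adjacent to a
pedestrian corridor, calibrated by a single brief manual observation.

The measurement model has three structural facts to respect:

* **devices ≠ people** — not everyone carries a detectable phone (at a
  child-oriented event, far fewer than one device per passerby), and not
  every phone is captured;
* **RSSI ≈ proximity** — smokers linger a few metres from the sensor and
  produce strong signals; passersby cross a corridor 13–17 m away and
  produce weak ones;
* **most devices are seen once** — a 20–30 s crossing usually yields
  zero or one probe burst, so only a small minority of identifiers ever
  form a presence episode with a measurable dwell.

## Pipeline and assumptions

**Funnel.** Detections outside local business hours [10:00, 22:00) are
dropped (half-open interval: 10:00:00 is in, 22:00:00 is out — the
half-open convention avoids double-counting boundary seconds and its
effect is negligible). Any OUI observed transmitting out of hours is
treated as fixed infrastructure and excluded *at vendor granularity*;
a visitor phone sharing a prefix with an access point is collaterally
excluded, which the simulator lets us measure rather than hide. Per
device, detections separated by ≤ 600 s join one episode; dwell is last
minus first detection. Devices seen once have undefined dwell and never
form episodes. Episodes with dwell ≤ 6 min are eligible — the screen is
inclusive at the boundary, and 6 min is an operational upper bound for
short smoking and crossing events (airport smoking-room stays average
5.6–6.5 min). The gap threshold is not empirically identified by the
data; 600 s is longer than any plausible inter-burst interval and
shorter than a plausible revisit, and it is exposed in the configuration
and perturbed by the sensitivity analysis.

**Funnel accounting.** Stages mix units (detections, then identifiers,
then episodes), so every stage is expressed as a percentage of *total
detections*, the only denominator that is consistent across all five
stages. Percentages are rounded half-up to one decimal; person counts
half-up to integers. (Base R's `round()` is half-to-even; the package
uses `round_half_up()` throughout so that, e.g., 528 × 7.4 = 3907.2
reports as 3907 and 0.45 as 0.5.) A zero detection total defines all
percentages as 0.

**Classification.** The band rule compares the episode's **mean** RSSI —
the summary statistic is a deliberate choice; a per-detection or
max-based rule would be noisier for bursty emission — against inclusive
integer bands: [−75, −46] dBm likely smoker, [−88, −76] dBm likely
passerby, anything else unclassified. Unclassified episodes are excluded
from calibration and estimation. Band validity (passerby upper edge
strictly below smoker lower edge) is enforced at configuration load and
at every sensitivity grid point; an overlapping perturbation is flagged
invalid, never silently skipped.

**Calibration.** For each class, multiplier = observed persons /
classified devices in the validation window, rounded to **one decimal
before scaling**; day persons = round(devices × multiplier). Rounding
the multiplier first is the convention under which integer device
counts, one-decimal multipliers and integer person totals are mutually
consistent (131 × 2.0 = 262; 528 × 7.4 = 3907.2 → 3907; 131 + 528 =
659). Window membership is defined the same way on both sides of the
ratio: a person is counted when they *enter* the zone during the window,
an episode when it *starts* during the window. Counting flows
consistently matters: if the observer tally were interpreted as
"present at any moment of the window" while devices were counted by
episode start, the multiplier would inherit an upward bias of roughly
(mean stay / window length) for the lingering class. Hourly profiles
scale hourly device counts by the class multiplier and are rescaled
proportionally so they sum exactly to the rounded day total. Point
estimates only: with a single 30-minute calibration window there is no
honest internal replication to build intervals from; a bootstrap hook
is a documented extension, off by default.

**Degenerate inputs.** A zero manual count or zero classified device
count makes calibration undefined for that class and raises an error
naming the class — scaling by a ratio estimated from zero events would
be arbitrary. Empty logs produce empty, well-typed outputs everywhere
else.

**Exploratory classifier.** A random forest (10 trees, maximum depth 5,
minimum terminal node size 1, i.e. any node with ≥ 2 samples may split)
on dwell, mean RSSI and RSSI standard deviation ("variability" is the
sample SD — another explicit choice). The forest is fitted with
`ranger`, which exposes the depth cap directly; the evaluation
arithmetic (confusion-matrix metrics, class-size-weighted averages,
rank-statistic AUC with ties counted one half) is implemented in the
package and cross-checked against an independent pairwise oracle and
`pROC` in the tests. The test split is a stratified hold-out
(default fraction 0.4, echoing a 42-of-104-stay test set); 5-fold CV
accuracy on the training portion is reported alongside. Metrics with an
empty-class denominator are reported `NA`, not 0.

## What the simulator emulates — and what it does not

`generate_scenario()` produces a full day of probe traffic with known
per-person ground truth:

| parameter | default | rationale |
|---|---|---|
| arrivals | hourly Poisson, per class | simplest process consistent with per-hour reporting; smoker profile bimodal (noon, 16:00, ~260/day), passerby midday-peaked (> 500/h late morning–afternoon, ~4,000/day) |
| smoker stays | log-normal, median 6 min, sdlog 0.5 | several-minute smoking stays; median at the dwell screen |
| passerby presence | corridor length / speed ≈ 25 s at 1.2 m/s | lateral crossing of a 30 m corridor |
| carriage | smoker 0.5, passerby 0.135 | person/device ratios bracketing 2.0 and 7.4; the low passerby value absorbs children without explicit age structure |
| probe emission | exponential inter-burst, mean 30 s; 1–4 probes/burst | a 6-min stay yields ~10–40 detections; a crossing often none |
| path loss | P₀ = −40 dBm at 1 m, exponent 3.5, shadowing SD 4 dB | places the smoking area (≈ 1.6–5 m) inside the smoker band and the corridor (13–17 m) inside the passerby band; the on-site RSSI–distance law was never characterized, so these are generic, tunable values, not a fit |
| geometry | 2-D horizontal distances | at ≥ 2 m range the 2.4 m sensor height contributes little |
| fixed devices | 3 roster OUIs, 24 h emission | exercises the out-of-hours exclusion rule |
| RNG | one master stream; per-person sub-seeds drawn from it | same (config, seed) ⇒ byte-identical logs |

Timestamps are floored to whole seconds (the records' declared
resolution), so multiple probes of one burst may share a second —
deliberately kept as legitimate duplicates.

Passing tests on this synthetic world show that the *pipeline logic* is
correct and that the *estimator recovers known truth under its own
assumptions*. They do not show that the RSSI bands, the 6-minute screen
or the carriage rates transfer to any real site: the simulator has no
MAC randomization churn, no multipath or weather effects, an eight-vendor
OUI pool (so vendor-level exclusion is far blunter than in reality), and
behavioral classes that are cleanly separated by construction — which is
why the exploratory forest scores near-perfectly on simulated episodes,
unlike on real validation data.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
episode construction against a loop-based brute-force grouper (1,000
random small logs of 2–12 detections, plus 200 more in the module
tests); AUC against exhaustive pairwise comparison and `pROC`; the hash
against a frozen reference digest; Monte-Carlo RSSI means against the
closed form (10,000 draws); stay medians at n ≈ 1,000 persons; Poisson
arrival totals at mean 1,000.

Calibrated day-total recovery is checked on five fixed seeds of a
high-traffic scenario (100 smokers/h and 300 passersby/h over 11 hours —
over 1,000 true persons per class — with carriage 0.9/0.4 and median
stay 4 min), comparing the across-seed mean estimate with the mean truth
at ±25%. Two properties of the ratio estimator dictated that design.
First, arrivals end an hour before closing: otherwise stays spilling
past 22:00 put phone OUIs out of hours and the vendor-level exclusion
deletes one-eighth of all devices at a stroke (a real artefact of the
rule, measured separately, but one that masks the recovery property).
Second, the window must yield roughly 25 or more classified devices per
class: the estimator multiplies by 1/D<sub>window</sub>, so its
small-sample (Jensen) bias grows like 1/E[D], and with fewer than ~10
window devices the bias alone approaches the tolerance. With one
30-minute window the per-seed spread is irreducible (≈ 18% SD for
passersby), which is why the criterion is evaluated on the across-seed
mean — and why the single-window calibration of any real deployment
should be read as provisional.

Default-scale runs (a few thousand simulated persons, ~17,000
detections) complete in about a second; the full suite in about a
minute.

## Known limitations

* Exposure opportunity, not dose: no pollutant measurement is modelled.
* One site, one day, one calibration window; multi-day or multi-site
  pooling is out of scope.
* OUI-level exclusion can remove human devices sharing a vendor prefix;
  the package measures this on synthetic data but does not prevent it.
* MAC-randomization de-aliasing is not attempted; a phone rotating
  identifiers mid-stay would fragment episodes.
* The funnel percentage convention (half-up, one decimal, total
  detections as denominator) can differ by 0.1 point from other rounding
  rules — e.g. a business-hours share of 90.37% reports here as 90.4.
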