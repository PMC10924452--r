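---
title: "A patient-level simulation of Crohn's disease surveillance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A patient-level simulation of Crohn's disease surveillance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crohnsim)
```

crohnsim is a discrete-event, patient-level microsimulation for comparing two
surveillance strategies in Crohn's disease (CD) with small-bowel involvement:
video capsule endoscopy (VCE) versus the standard of care (SOC:
ileocolonoscopy, with MR enteroscopy added for the small bowel). The model
produces budget-impact comparisons in four cost buckets, bootstrap and
one-way cost sensitivity analyses, and an external-validation statistic that
summarises how often replicated model runs land near an empirical outcome.

This vignette documents the model, its assumptions, the parameters that
matter, and the numerical decisions taken where the design was genuinely
open. It states no empirical result that the package's tests and acceptance
script do not themselves compute.

## Disease model

Disease activity is tracked on the Crohn's Disease Activity Index (CDAI),
discretised into four bands: remission (CDAI < 150), mild
(150 &le; CDAI < 220), moderate (220 &le; CDAI < 450), and severe
(CDAI &ge; 450). Bands are lower-inclusive and upper-exclusive, matching the
standard interval notation. `classify_cdai()` implements the mapping.

Severity evolves as a semi-Markov process with *monthly* transitions nested
inside *3-month* model cycles, so a patient can escalate and resolve within
a single cycle — e.g. mild in month 1, a flare to severe, resolution, and
remission by month 3. Any within-cycle escalation raises a flare signal for
that cycle, whether or not it resolves; this is the event that can trigger
an unscheduled physician visit. The semi-Markov aspect is realised as
time-in-state tracking with (by default) duration-independent rows; the
hook exists for duration-modified rows, but none are shipped because no
published duration dependence is available to calibrate them.

Each treatment line (conventional therapy, immunomodulator, biologic) has
its own monthly 4x4 row-stochastic matrix. **The shipped matrices are
synthetic defaults**: the improvement probabilities rise with treatment
line and the flare probabilities are small and monthly, values chosen once
as clinically plausible for a CD clinic population and exposed entirely
through the configuration. Nothing in the test suite asserts outcomes that
depend on their particular values except through self-consistency and
calibration properties that hold for any valid row-stochastic matrix.

Complications (stricture, abscess, fistula) onset independently each month
with a base probability (defaults: 0.004, 0.002, 0.002 per month) scaled by
a severity multiplier of 0/1/2/4 for remission/mild/moderate/severe.
Complications track inflammatory activity; the exact dependence is not
published, so the multiplier is config-exposed. On a band change the CDAI
score is resampled uniformly within the new band (the severe band is capped
at 600); the model's semantics live at band level and the score is only
used for band classification and the remission definitions.

There is no mortality in the model; the `alive_in_model` flag exists to
support future extensions and is always true.

## Care pathway

Per cycle, each patient is checked for a scheduled surveillance visit
(default every 2 cycles, i.e. semiannual). Without one, a flare signal
triggers an unscheduled visit. In both cases a fecal-calprotectin (fCal)
marker test is performed first — the marker is applied at scheduled visits
too, since the workflow conducts it "in both scenarios". Scheduled patients
proceed to endoscopy regardless of the marker; flare-triggered patients
proceed only on a positive marker.

The latent truth for all diagnostic draws is *disease activity*: severity
at mild or above, or any active complication. fCal has no numeric threshold
in the model; its published sensitivity/specificity operate directly on
this truth.

Endoscopy by arm:

* **SOC** — ileocolonoscopy on the colon (never the small bowel), plus MR
  enteroscopy on the small bowel when involved.
* **VCE** — a single capsule study covering both segments, billed once,
  with segment-specific sensitivity/specificity (overall 83%/88%;
  small bowel 97%/87%).

An incomplete capsule study or ileocolonoscopy triggers exactly one MR
enteroscopy follow-on, billed. This fallback is a modelling decision: a
completion rate below 1 must have a billable consequence, and MR
enteroscopy is the radiological complement in this pathway.

Diagnosis: *complication* when an active complication is detected by a
positive, complete test covering its segment; else *active disease* when
any test is positive; else *no active disease*. Complications are located
in the small bowel when the patient has small-bowel involvement (the whole
study population, under the default cohort), otherwise the colon — this is
what makes the small-bowel operating characteristics of each arm the
mechanism for earlier or later complication detection. False-positive
endoscopies escalate treatment (a cost consequence) but can never invent a
complication, so specificity drives budget impact without creating
phantom surgeries.

Treatment routing:

* Complication &rarr; surgery. Stricture: elective with probability 0.7,
  else emergency; abscess and fistula: emergency (fistula billed as a
  fistula repair). Surgery uses resection semantics: active complications
  are cleared and severity resets to the remission band.
* Active disease that *persists* — the current band is the same or worse
  than at the previous completed assessment (the baseline work-up counts
  as the first) — escalates: bottom-up strategies advance one line,
  top-down strategies start a biologic immediately.
* Disease locations are static in this model, so the
  "adjust for new pathology" action defined in the event vocabulary is
  never produced by the default pathway.

Maintenance medication accrues every cycle at the current line's per-cycle
cost (interventions bucket).

## Costs

Every billable event is priced from a catalogue into exactly one of four
buckets: monitoring, interventions, adverse events, surgery. The four
procedure tariffs (fCal 12.05, VCE 850.00, ileocolonoscopy 74.00, MR
enteroscopy 160.10 euros) are published values; **surgery, medication and
adverse-event amounts are synthetic defaults** chosen as plausible DRG-like
magnitudes, because the full tariff schedule behind the source model is not
public. Capsule retention with a patency capsule is 0%, and the patency
capsule itself is a zero-cost catalogue item by default.

Currency arithmetic is carried in integer cents internally, so the
total-equals-sum-of-buckets invariant is exact to the cent; amounts are
reported in euros. Costs are not discounted: no discounting is described
for the source analysis, and the `discount_rate` configuration hook
defaults to 0.

The budget-impact report aggregates 4 cycles per year (the 5-year budget
horizon uses 20 cycles; outcome validation uses the first 18 cycles, i.e.
the 4.5-year follow-up). The headline saving is computed as the difference
of arm means, which equals the mean of per-patient differences at equal n.

## Randomness and pairing

All randomness flows from one master seed. Each patient receives two child
streams derived by stable indices — one for the latent disease path, one
for diagnostic/treatment draws — and both arms reuse the same stream seeds.
The arms therefore share disease-path randomness and differ only through
the pathway, realising a paired-cohort comparison: an A/A run (identical
arms) yields exactly zero budget impact, which the test suite asserts.

## Synthetic cohort

The generator emulates the baseline table of a single-centre CD cohort with
small-bowel involvement (276 retained records in the source population).
Defaults, all config-exposed and chosen once as plausible clinic values:
truncated-normal age (mean 40, sd 13, bounds 16–80); baseline CDAI mixture
over the severity bands with shares 0.25/0.35/0.30/0.10 and uniform scores
within bands; small-bowel involvement prevalence 1.0; colonic involvement
0.6; stricturing 0.15; abscess 0.05; top-down strategy share 0.2; treatment
line shares 0.40/0.35/0.25; exponential years-since-diagnosis with mean 8.

What the generator does *not* emulate: covariate correlations (age by
disease duration, severity by treatment line), temporal trends over two
decades of recruitment, missing data, or the matched-cohorts structure of
the source study. Passing tests therefore demonstrate that the machinery is
correct and calibrated to its configured inputs — not that the synthetic
population reproduces the real cohort's euro outcomes, which additionally
depend on unpublished transition and cost schedules. For that reason the
package's acceptance checks target the analytically reproducible
quantities (the Beta-posterior validity construction, replication
arithmetic, diagnostic calibration) and structural invariants, never
specific euro results.

`replicate_cohort()` copies each record with a `base:replicate` id encoding
(276 × 10 = 2760 simulation records; 276 × 100 = 27 600 validation
records), so validation can group replicates of the same baseline record.
Validation replicates share baselines; only the stochastic paths redraw.

## Sensitivity analyses

**Bootstrap.** Per-patient annual cost differences (VCE − SOC) are
resampled with replacement into 1000 populations of 500 patients; each
population is summarised by its mean, and the median, interquartile range
and central 95% interval are taken over the population means (the
per-patient savings fraction is reported separately, over individuals).
Quantiles use linear interpolation between order statistics. The interval
is taken over population means rather than individual patients because the
bootstrap is a sampling-uncertainty analysis of the cohort-level result.
The default eligibility filter keeps only patients with at least one
completed capsule study in the VCE arm — the closest literal reading of
"patients who had changed management practices, with single capsule
endoscopy being a criterion" — and can be disabled.

**Tornado.** Each catalogue amount is scaled by ±20% with the simulated
event streams held fixed, and both arms are re-priced. Because pricing is
separate from event generation and the events are seed-fixed, this is
identical to re-running the model with the scaled amount, and the response
is exactly linear in the unit cost — the property the test suite checks
against an analytic count-based oracle. Entries are ordered by descending
width with alphabetical tie-breaks.

## External validation

Outcomes are extracted on a semiannual grid (2 cycles per interval, 9
intervals over 4.5 years) under two definitions:

| | permissive | restrictive |
|---|---|---|
| biologic use | any fully covered 6-month interval | a covered run of ≥ 12 months |
| surgeries | all types | elective and emergency only |
| remission | ≥ 6 months with CDAI ≤ 150 | ≥ 12 months with CDAI ≤ 150 |

A remission period must immediately follow active disease: the preceding
interval (or the baseline record, for the first interval) must contain a
CDAI above 150. A patient quiet from baseline onward therefore never counts
as *entering* remission. Cumulative incidence at interval *t* is the
fraction of patients whose first qualifying interval is at or before *t*.

The acceptance statistic follows a Beta-posterior construction: a prior
with mean 50% (uniform, Beta(1,1)) represents a decision maker equally
likely to accept or reject the model; k of n = 100 replicates landing
within a proximity band of the empirical value (relative bands of 1%, 5%,
10%, 20%, boundary inclusive; the "true value" row uses the empirical
uncertainty interval supplied by the caller) gives posterior mean
(k+1)/(n+2) and an equal-tailed 95% credible interval from the
Beta(k+1, n−k+1) quantiles. Percentages are rounded to one decimal only at
the reporting layer. When the empirical value is zero, a configurable
absolute tolerance replaces the relative band. A variant prior with mean
80% (Beta(1.6, 0.4), prior strength 2) is exposed for the
"80% target acceptance" analysis; its exact construction in the source
method is not published, so it is a configuration option only.

## Numerical choices and degenerate inputs

* Transition rows must sum to 1 within 1e-9; validation reports every
  violated key rather than stopping at the first.
* Probability-1 and probability-0 inputs are honoured exactly (degenerate
  matrices, guaranteed complications, perfect tests), which the tests use
  to force worked examples.
* The complication-onset multiplier at probability 1 and severity severe
  saturates (p > 1 behaves as certainty).
* Proximity counting is boundary-inclusive (a replicate exactly 20% away
  counts at 20%).
* Child seeds are derived with integer arithmetic kept inside the 32-bit
  range.

## Problem sizes used by the tests

The suite exercises cohorts of 10–40 patients with up to 25 replicates for
end-to-end properties, 50 000 records for generator-calibration checks,
100 000 draws for diagnostic-calibration checks, and 10 000–20 000
bootstrap populations for the quantile-convergence oracle — sizes at which
the three-standard-error bands are tight enough to detect real
miscalibration while keeping the default suite quick on one CPU.

## Known limitations

* Transition matrices, non-procedure costs, and cohort marginals are
  synthetic; euro-denominated outputs characterise the machinery, not the
  source population.
* Disease location is static, so the new-pathology treatment action never
  fires by default.
* fCal operates on the latent activity truth, not a concentration
  threshold.
* No competing-risk or proportional-hazards testing of the cumulative
  series — by design, cumulative series are presented for comparison only.
* No cost-effectiveness (QALY) layer; the model reports budget impact
  only.
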