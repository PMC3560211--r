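---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data do and do not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The decision problem

Primary prevention of ischaemic heart disease (IHD) and stroke with blood
pressure-lowering drugs and statins can be targeted three ways: at people
who already take the drugs (current practice), at people crossing
single-risk-factor thresholds (the existing guideline synthesis), or at
people above an absolute-risk cutoff. The model quantifies, for a closed
cohort of adults aged 35–84 with no CVD history, the lifetime consequences
of each rule relative to no intervention: discounted QALYs gained,
intervention costs to government and patients, and disease treatment costs
averted, combined into an ICER judged against $50,000/QALY.

## Risk engine

Five-year absolute risk uses the 1991 Framingham (Anderson) CVD equation, a
Weibull accelerated failure-time model. The coefficient file
`inst/extdata/framingham_1991_cvd.csv` is the single source of truth (a
checksum test guards it); the code only evaluates what the file declares.
Left-ventricular hypertrophy is a covariate of the published equation that
survey-style records do not carry; it defaults to absent.

Three surrounding conventions:

* **Treated-level adjustment.** People already on treatment have their
  measured levels back-adjusted to untreated equivalents before scoring
  (+9.1 mmHg systolic, +5.5 diastolic; total cholesterol ÷ (1 − 0.171),
  triglycerides ÷ (1 − 0.093), HDL ÷ (1 + 0.033)). The inverse mapping is
  exact, and a test verifies the round trip to 1e−9.
* **Calibration.** Predicted risk is multiplied by one factor per
  age-band × sex cell, chosen so the weighted cell mean equals the
  five-year event probability implied by the incidence schedule,
  1 − exp(−5·(i_IHD + i_stroke)) averaged at individual ages. A per-cell
  multiplicative factor is the simplest scheme consistent with a one-line
  description of calibrating a risk distribution to known incidence;
  a baseline-survival shift would be an alternative but is not implemented.
  Because factors are always re-derived from uncalibrated risk, calibration
  is idempotent (verified to 1e−10).
* **Clipping.** Calibrated risks are clipped to [1e−9, 1 − 1e−9] to protect
  downstream logarithms; the five-to-ten-year conversion
  p10 = 1 − (1 − p5)² is the constant-hazard extension over two periods and
  reproduces the guideline rule of thumb (5% → ~10%, 10% → ~20%).

## Eligibility rules

"Blood pressure > 140/90 mmHg" is read with standard hypertension-guideline
OR semantics (systolic > 140 *or* diastolic > 90), isolated in one predicate
(`bp_rule()`) that also defines "hypertension" wherever the lipid criteria
reference it. "Post-menopausal women < 75 years" is operationalised as
female with 50 ≤ age < 75: menopause status is not a survey field and 50 is
the conventional proxy; the age is a parameter. Absolute-risk thresholds
are inclusive ("at least 5%"), and BP and statin cutoffs are independent so
the headline mixed rule (BP at ≥ 5%, statins at ≥ 10%) is expressible.
Screening reach — GP attendance by age band and sex times GP participation
in risk assessment (default 0.65) — is applied as a deterministic fractional
weight rather than per-record random draws: cohort accounting stays exact
and parameter uncertainty is the PSA's job. Under the new rules treatment
follows the rule; currently treated people below threshold count as "no
longer eligible" (no grandfathering by default).

## Treatment and costs

New BP prescriptions follow a fixed cost-effective order — diuretic, then
calcium channel blocker, then ACE inhibitor — with beta-blockers excluded
from new prescriptions (they are dominated by the alternatives on current
effect estimates) though retained in the current-practice pooled mix. The
number of BP drugs (1–3) follows a configurable distribution (default
0.55/0.35/0.10), and per-drug relative risks combine multiplicatively.
Current practice instead uses pooled effects,
E[RR] = Σₖ P(k)·(Σ_d w_d RR_d)ᵏ over the count distribution and class mix,
and the aggregate PBS expenditure cost lines.

Discontinuation (40% at 12 months) is modelled as stratum composition:
starters split into long-term adherers and first-year-only members who get
full year-1 cost and full year-1 risk reduction, then contribute nothing —
the simplest reading of "discontinue at 12 months" (a half-year accrual
variant would halve both and is deliberately not the default). Intervention
costs per person-year are drug costs plus the GP-visit/blood-test pattern
for the treatment pattern and year; screening visits for people found
ineligible carry no cost (risk assessment is assumed to happen within
routine attendance). Disease costs are government-side, first-year vs
subsequent-years per disease, with the combined IHD+stroke state paying
both subsequent-year costs. All prices are constant 2008 A$.

## Markov engine

Annual cycles from the baseline year until death or age 100, no half-cycle
correction (the discrete-time formulation is taken literally). Five states
are implemented: the four primary states WELL, IHD, STROKE, DEAD plus
IHD+STROKE, a bookkeeping extension required because second-event risks
(stroke in IHD, IHD in stroke; sex-specific multipliers) are parameterised
separately. Numerical conventions, each covered by a test:

* Cause-specific rates convert to probabilities jointly by the exponential
  competing-risks split: P(any) = 1 − exp(−ΣR), shares ∝ rates.
* Case fatality routes its share of incident events to DEAD within the
  event cycle (a 28-day case-fatality convention: fatal events spend no
  time in the disease state); first-year disease costs attach to all
  incident events, fatal included.
* Scenario relative risks scale first-event (WELL→) incidence only;
  second-event rates carry the comorbid multipliers but no treatment
  effect, a conservative reading since the drugs are primary prevention.
* Trends multiply incidence and case fatality by (1 + δ)^(cycle−1); the
  default δ = −2%/year for both is an illustrative synthetic value.
* Background mortality applies to all alive states; the combined state
  carries no additional excess mortality beyond having had both events
  (a known simplification).
* QALYs weight end-of-cycle person-years by the age/sex utility weight and
  by (1 − disability weight) per disease, multiplied together in the
  combined state; deaths during a cycle accrue nothing that cycle.
* Comparator incidence is back-calculated cross-sectionally:
  i_base = i_obs / (Σ_p cov_p·RR_p + 1 − Σ_p cov_p) per age × sex cell with
  current-use coverage (held flat above age 84) and pooled current-practice
  relative risks, so re-applying observed treatment reproduces observed
  rates exactly (tested to 1e−12).
* Conservation (occupancy sums to cohort size) holds to 1e−9 relative over
  a full lifetime run, and the vectorised engine is tested cell-by-cell
  against explicit transition-matrix products and against a Monte-Carlo
  microsimulation of the same matrices.

## Synthetic data: what it does and does not emulate

The population generator draws (SBP, DBP, log TC, log HDL, log TG) from a
multivariate normal per age-band × sex stratum, truncated to physiologic
ranges — preserving the positive correlations that the single-risk-factor
rules and the Framingham score jointly exploit, with log-scale lipids kept
positive. Smoking declines and diabetes rises with age; current drug use
(defaults: 12% BP, 12% lipid, 8% both, so ~16% any and half of users on
both classes) rises with age and with the individual's own SBP or TC
percentile via prevalence-preserving weights. That *imperfect but
non-random targeting* is essential: the interesting finding — mismatch
between who is treated and who is eligible — disappears if current use is
either random or perfectly targeted. Population weights are equal per
record, scaled to a configurable total (default 9.5 million persons).

The epidemiological schedule is log-linear in age (exponential rates) by
construction, with case fatality validated ≤ 1 at age 100 at load time.
Utility weights decline linearly with age from 0.95; disability weights are
0.15 (IHD) and 0.30 (stroke). These, the trends and the rate levels are
synthetic stand-ins chosen once to be realistic in shape for a high-income
population, because the national registry inputs and the original utility
and disability sources are not redistributable. Consequently the tests
demonstrate *structural* correctness (conservation, monotonicity,
round-trips, oracle agreement), not numerical agreement with any particular
country's burden of disease. The generator also does not emulate survey
design effects: no sampling weights, clustering or non-response.

## Probabilistic sensitivity analysis

All uncertain inputs are sampled jointly but independently per draw (no
correlation structure is asserted): relative risks lognormally with
SE = |log CI width|/(2·1.96); second-event relative risks lognormally with
the delta-method SE/mean; disease costs uniformly within ±25%; GP
participation and discontinuation from beta distributions moment-matched to
mean and SE. The printed beta-blocker confidence intervals are inconsistent
with their means (bounds apparently transposed); the means are kept as
printed, the SE is taken from the absolute CI width, and the rows are
flagged. Each draw re-runs the entire pipeline including back-calculation
(the comparator depends on sampled relative risks). The point estimate is
the run at distribution means, degenerate spreads collapse the uncertainty
intervals onto it (tested to 1e−9), and the population records and
calibrated risks are held fixed across draws so the PSA isolates parameter
uncertainty from sampling noise. The function default is 2,000 draws; the
analysis scripts use 500 and the acceptance script 200, sizes at which the
percentile intervals on the fixture population are stable while the full
workflow stays interactive.

## Problem sizes and reproducibility

The shipped workflow uses 10,000 synthetic records representing 9.5 million
people; the test fixtures use 2,000 records, with 50,000-record draws for
distribution-recovery checks and a 2,000-individual microsimulation for
engine validation. Every stochastic step is seeded; identical seeds give
byte-identical populations, draws and PSA output.

## Known limitations

Closed cohort (no new 35-year-olds enter); no aspirin, dose titration or
adverse events; no repeat screening or risk re-assessment; no treatment
effect on second events; no excess mortality in the combined disease state
beyond its two case-fatality gates; no non-CVD cost offsets in added
life-years; constant prices without inflation. The ten-year Framingham
variants used in UK/European guidelines are out of scope — the five-year
equation is the one used for antipodean absolute-risk guidelines, and the
five↔ten-year mapping provided is explicitly a rule of thumb.
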