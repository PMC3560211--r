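# cvdprevent

Cost-effectiveness modelling of primary cardiovascular disease (CVD)
prevention with blood pressure-lowering drugs and statins, for health
economists and epidemiologists comparing screening strategies at population
scale.

Many countries are moving from prescribing preventive drugs to everyone with
"high blood pressure" or "high cholesterol" towards prescribing on *absolute
risk* — the probability, from all risk factors jointly, of a first ischaemic
heart disease (IHD) or stroke event within five years. This package models
what that switch does to lifetime population health (quality-adjusted life
years, QALYs), government and patient spending, and treatment costs averted,
for an Australian-style adult population aged 35–84 with no CVD history.

## What the model does

1. **Absolute risk scoring.** The 1991 Framingham (Anderson) CVD equation,
   a Weibull accelerated failure-time model: with linear predictor μ over
   log(age), log(SBP), log(TC/HDL), smoking, diabetes and sex terms, and
   σ = exp(θ₀ + θ₁μ), the five-year event probability is
   p = 1 − exp(−exp((log 5 − μ)/σ)).
   Profiles of people already on treatment are first back-adjusted to
   untreated levels (+9.1/+5.5 mmHg; total cholesterol ÷ (1 − 0.171), etc.),
   and predictions are calibrated per age-band × sex so the cell-mean risk
   matches the incidence schedule (target 1 − exp(−5·(i_IHD + i_stroke))).
2. **Screening and eligibility.** Three scenarios: *current practice*
   (self-reported drug use), the *single-risk-factor* guideline synthesis
   (BP > 140/90 mmHg rules plus seven lipid criteria), and *absolute risk*
   (inclusive thresholds, e.g. BP drugs at ≥ 5% and statins at ≥ 10%
   five-year risk). Screening reach is GP attendance × GP participation
   (0.65) applied as a fractional weight.
3. **Treatment.** Up to three BP drugs in a fixed cost-effective order
   (diuretic → calcium channel blocker → ACE inhibitor) plus a statin;
   per-drug relative risks combine multiplicatively; 40% discontinue after
   the first year. Costs split PBS/MBS-style into government and patient
   components, year 1 vs later years.
4. **Markov cohort model.** Annual cycles to age 100 over states WELL, IHD,
   STROKE, IHD+STROKE, DEAD, with competing-risk rate→probability
   conversion, case fatality inside the event cycle, sex-specific
   second-event relative risks, secular trends in incidence and case
   fatality, utility- and disability-weighted person-years, and 3%
   discounting. Comparator incidence is back-calculated to strip current
   treatment out of observed rates: i_base = i_obs / (cov·RR + (1 − cov)).
5. **Decision metrics and PSA.** ICER = (government + patient + averted
   costs) / QALYs gained vs a $50,000/QALY threshold; multivariate
   probabilistic sensitivity analysis re-runs the whole pipeline per joint
   parameter draw (lognormal relative risks, ±25% uniform disease costs,
   beta participation/discontinuation) for empirical 95% uncertainty
   intervals and the cost-effectiveness plane.

The restricted survey microdata behind the original analyses are not
redistributable, so the package ships a tested synthetic-population
generator (correlated risk factors, age/sex prevalence gradients,
imperfectly targeted current drug use) and a synthetic epidemiological
schedule; both are user-replaceable via plain CSV.

## Worked example

```r
library(cvdprevent)
pop    <- generate_population(5000, seed = 1)       # synthetic survey
adj    <- untreated_profile(pop)                    # strip treatment effects
sch    <- generate_epi_schedule()
params <- calibrate(adj, sch)                       # per-cell calibration
risk5  <- five_year_risk(adj, params)
summary(100 * risk5)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#>  0.01116  0.76423  2.09805  5.56508  6.84059 51.53802

inp  <- model_inputs()
base <- back_calculate_schedule(sch, pop, inp)      # no-intervention rates
sp   <- screening_parameters(scenario = "absolute_risk",
                             bp_threshold = 0.05, statin_threshold = 0.10)
res  <- run_scenario(pop, risk5, sp, base, inp)
res
#> <scenario_result> absolute_risk: 742894 QALYs gained; gov $6973M,
#>   patient $2250M, averted $-6995M; ICER $3000/QALY

cp <- run_scenario(pop, risk5,
                   screening_parameters(scenario = "current_practice"),
                   base, inp, res$comparator)
(cp$gov_cost - res$gov_cost) / 1e9
#> [1] 2.5   # $ billion the government saves vs current practice
```

Read: on the synthetic population, treating everyone at ≥ 5% five-year risk
with BP drugs (statins from ≥ 10%) gains ~743,000 discounted lifetime QALYs
over no intervention at a net ~$3,000 per QALY — cheaper for government than
today's poorly targeted prescribing, which gains fewer QALYs at higher cost.
Magnitudes depend on the synthetic epidemiology; the structure, not the
point values, is the claim.

The numbered drivers in `analysis/` run the full study sequence
(population → risk and eligibility flows → scenario table → PSA) and write
their tables under `results/`.

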