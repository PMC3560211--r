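#!/usr/bin/env Rscript
# Deterministic lifetime cost-effectiveness of each prevention scenario
# against the no-intervention comparator: current practice, the single-risk-
# factor guideline synthesis, and absolute-risk screening at three
# thresholds, including the headline mixed rule (BP drugs at >= 5% risk,
# statins restricted to >= 10%) and its New Zealand statin-price variant.

library(cvdprevent)

pop <- read_population("results/population.csv")
sch <- read_epi_schedule("results/epi_schedule.csv")
adj <- untreated_profile(pop)
risk5 <- five_year_risk(adj, calibrate(adj, sch))

inp <- model_inputs()
base <- back_calculate_schedule(sch, pop, inp)
cmp <- comparator_trace(pop, base, inp)
message("No-intervention comparator simulated; conservation error ",
        format(conservation_error(cmp), digits = 3))

run1 <- function(scenario, bp = 0.05, statin = 0.05, inputs = inp) {
  sp <- screening_parameters(scenario = scenario, bp_threshold = bp,
                             statin_threshold = statin)
  run_scenario(pop, risk5, sp, base, inputs, cmp)
}
res <- list(
  current_practice = run1("current_practice"),
  single_risk_factor = run1("single_risk_factor"),
  absolute_risk_15 = run1("absolute_risk", 0.15, 0.15),
  absolute_risk_10 = run1("absolute_risk", 0.10, 0.10),
  absolute_risk_5_statin10 = run1("absolute_risk", 0.05, 0.10),
  absolute_risk_5_statin10_nz = run1("absolute_risk", 0.05, 0.10,
                                     inputs = model_inputs(nz_statin_price = TRUE))
)
report <- scenario_report(res)
write.csv(report, "results/scenario_results.csv", row.names = FALSE)
print(report, row.names = FALSE)

sav <- (res$current_practice$gov_cost - res$absolute_risk_5_statin10$gov_cost) / 1e9
sav_nz <- (res$current_practice$gov_cost -
             res$absolute_risk_5_statin10_nz$gov_cost) / 1e9
message(sprintf("Government spend under the mixed absolute-risk rule is $%.1fb lower than current practice ($%.1fb with NZ statin prices)",
                sav, sav_nz))
message("Wrote results/scenario_results.csv")
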