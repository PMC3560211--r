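#!/usr/bin/env Rscript
# Score five-year absolute CVD risk (treated-level adjusted, calibrated to
# the schedule's incidence) and compare who is treated now with who would be
# eligible under the guideline rules and the absolute-risk thresholds.

library(cvdprevent)

pop <- read_population("results/population.csv")
sch <- read_epi_schedule("results/epi_schedule.csv")

adj <- untreated_profile(pop)
rp <- calibrate(adj, sch)
write_calibration(rp, "results/calibration_factors.csv")
risk5 <- five_year_risk(adj, rp)

message(sprintf("Median five-year risk %.1f%%; %.1f%% of adults at >= 5%%, %.1f%% at >= 15%%",
                100 * median(risk5), 100 * mean(risk5 >= 0.05),
                100 * mean(risk5 >= 0.15)))

treated_now <- pop$on_bp_drugs | pop$on_lipid_drugs
screened <- screened_fraction(pop$age, pop$sex, screening_parameters())
srf <- single_risk_factor_eligibility(adj)
rules <- list(
  single_risk_factor = srf$bp_eligible | srf$lipid_eligible,
  absolute_risk_5pct = risk5 >= 0.05,
  absolute_risk_10pct = risk5 >= 0.10,
  absolute_risk_15pct = risk5 >= 0.15
)
flows <- do.call(rbind, lapply(names(rules), function(nm) {
  f <- eligibility_flows(pop, treated_now, rules[[nm]], screened)
  data.frame(rule = nm, t(f / 1e6))
}))
names(flows)[2:4] <- paste0(c("already_treated", "newly_eligible",
                              "no_longer_eligible"), "_millions")
write.csv(flows, "results/eligibility_flows.csv", row.names = FALSE)
message("Eligibility flows (millions of people):")
print(flows, row.names = FALSE, digits = 3)
message("Wrote results/calibration_factors.csv and results/eligibility_flows.csv")
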