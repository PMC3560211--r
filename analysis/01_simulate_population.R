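#!/usr/bin/env Rscript
# Build the synthetic study inputs: an individual-level risk-factor survey
# population (age 35-84, never-CVD) and the age/sex epidemiological schedule
# the Markov model runs on.

library(cvdprevent)

dir.create("results", showWarnings = FALSE)
seed <- 1
n <- 10000

pop <- generate_population(n, seed = seed)
write_population(pop, "results/population.csv")
message(sprintf("Simulated %d records representing %.1f million people", n,
                sum(pop$weight) / 1e6))
message(sprintf("Current preventive drug use: %.1f%% (both classes: %.1f%%)",
                100 * mean(pop$on_bp_drugs | pop$on_lipid_drugs),
                100 * mean(pop$on_bp_drugs & pop$on_lipid_drugs)))

sch <- generate_epi_schedule()
write_epi_schedule(sch, "results/epi_schedule.csv")
message(sprintf("IHD incidence, males: %.4f at 45 vs %.4f at 75 per person-year",
                schedule_lookup(sch, "incidence_ihd", 45, "male"),
                schedule_lookup(sch, "incidence_ihd", 75, "male")))
message("Wrote results/population.csv and results/epi_schedule.csv")
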