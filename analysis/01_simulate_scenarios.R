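#!/usr/bin/env Rscript

## Step 1: the nine data-generating scenarios.
##
## Simulates trial datasets (600 subjects, 300 per arm) under each scenario
## of the study grid -- illness-death with recovery vs. progressive
## structure, gamma-frailty or entry-time Markov violations, random vs.
## state-dependent censoring -- and records the per-scenario data loads:
## how many subjects end censored, how many die, and how heavy the
## recurrent-event burden gets. Writes results/scenario_summaries.csv and
## one example dataset in the package's long CSV format.

library(recmstate)

dir.create("results", showWarnings = FALSE)
reps <- 50L
seed <- 20260923L

cat("Scenario grid:\n")
for (cfg in scenario_catalog()) print(cfg)

rows <- lapply(1:9, function(id) {
  cfg <- scenario_config(id)
  s <- vapply(seq_len(reps), function(r) {
    d <- dataset_summary(simulate_dataset(cfg, rep = r, seed = seed))
    c(d$n_censored, d$n_dead, d$n_admissions, d$max_rehosp)
  }, numeric(4))
  data.frame(scenario = id,
             structure = cfg$structure,
             frailty = cfg$frailty,
             censoring = cfg$censoring,
             mean_censored = mean(s[1, ]),
             mean_dead = mean(s[2, ]),
             mean_admissions = mean(s[3, ]),
             mean_max_rehosp = mean(s[4, ]))
})
summ <- do.call(rbind, rows)
write.csv(summ, "results/scenario_summaries.csv", row.names = FALSE)
cat("\nPer-scenario means over", reps, "datasets of 600 subjects:\n")
print(summ, digits = 4, row.names = FALSE)

cat("\nNote: the frailty scenarios (2, 4, 6, 8) carry fewer censored",
    "subjects and heavier event loads than the Markov scenarios, and the",
    "entry-time scenario 9 carries more censoring -- a direct consequence",
    "of the printed transition-hazard formulas (see the methods vignette).\n")

h <- simulate_dataset(scenario_config(2, n = 100), rep = 1, seed = seed)
write_event_history(h, "results/example_scenario2.csv")
cat("\nWrote an example 100-subject scenario-2 dataset to",
    "results/example_scenario2.csv\n")
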