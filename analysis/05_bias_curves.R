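#!/usr/bin/env Rscript

## Step 5: when is the Nelson-Aalen estimand disturbed by censoring?
##
## Averages the Nelson-Aalen home->hospital curve over many simulated
## datasets: in the Markov scenarios (1, 3) the mean curve overlays the
## true cumulative hazard 0.002 t under both random and state-dependent
## censoring; in the frailty scenarios the estimand is the partly
## conditional rate, which random censoring (scenario 2) leaves intact but
## state-dependent censoring (scenario 4) biases downward -- the central
## cautionary result. Writes results/mean_hazard_curves.csv.

library(recmstate)

dir.create("results", showWarnings = FALSE)
R <- 100L
seed <- 20260923L
grid <- c(250, 500, 1000, 1500, 2000, 2500)

mean_curve <- function(id) {
  cfg <- scenario_config(id)
  acc <- numeric(length(grid))
  for (r in seq_len(R)) {
    acc <- acc + eval_step(nelson_aalen(simulate_dataset(cfg, rep = r,
                                                         seed = seed),
                                        0L, 1L), grid)
  }
  acc / R
}

tab <- data.frame(time = grid, truth_markov = 0.002 * grid)
for (id in 1:4) tab[[paste0("scenario_", id)]] <- mean_curve(id)
write.csv(tab, "results/mean_hazard_curves.csv", row.names = FALSE)

cat("Mean Nelson-Aalen curves over", R, "datasets:\n\n")
print(tab, digits = 4, row.names = FALSE)
cat("\nScenarios 1 and 3 track 0.002*t; scenario 4 (frailty +",
    "state-dependent censoring) falls below scenario 2 (frailty + random",
    "censoring) at late times: state-dependent censoring preferentially",
    "\nremoves event-prone subjects and biases the partly conditional rate.\n")
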