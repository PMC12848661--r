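#!/usr/bin/env Rscript

## Step 4: the simulation study of the Markov-probe Wald tests (desk scale).
##
## For each of the nine null scenarios, simulates R datasets, fits the
## mapped model (AG for the illness-death scenarios with the
## previous-hospitalization probe; PWP for the progressive scenarios with
## the entry-time probe), and counts 5%-level Wald rejections -- model 1
## with treatment + probe, model 2 with treatment only. The full study uses
## R = 1000 (scripts/acceptance.R recomputes the headline cells at that
## size); this driver runs a reduced grid by default. Pass a replication
## count as the first argument to change it.

library(recmstate)

dir.create("results", showWarnings = FALSE)
args <- commandArgs(trailingOnly = TRUE)
R <- if (length(args) >= 1) as.integer(args[1]) else 100L
seed <- 20260923L

cat("Null-scenario rejection grid, R =", R, "replications per scenario\n\n")
grid <- table_rejections(R = R, seed = seed)
write.csv(grid, "results/rejection_grid.csv", row.names = FALSE)
print(grid, row.names = FALSE)

band <- qbinom(c(0.0005, 0.9995), R, 0.05)
cat("\nReading guide: treatment columns should stay near the nominal 5%",
    sprintf("(central 99.9%% binomial band at R = %d: [%d, %d]).", R,
            band[1], band[2]),
    "\nThe Markov probe saturates in the frailty illness-death scenarios",
    "(2, 4) and the entry-time scenario (9), but misses the frailty",
    "violation in the progressive scenarios (6, 8): stratifying on the",
    "\nevent count absorbs most of the frailty-induced history dependence,",
    "so the entry-time probe has little left to detect.\n")
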