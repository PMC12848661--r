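#!/usr/bin/env Rscript

## Step 3: the semiparametric model ladder on one trial.
##
## Fits, on the same simulated trial as step 2 (true home->hospital hazard
## ratio 0.85 for the treated arm), the sequence of regression models from
## time-to-first-event to recurrent events:
##   - Cox cause-specific model for the first hospitalization,
##   - Andersen-Gill (AG) for recurrent hospitalizations, without and with
##     the previous-hospitalization count (the Markov probe),
##   - Ghosh-Lin proportional rates model (IPCW for censoring, death kept
##     in the risk population),
##   - Prentice-Williams-Peterson (PWP), stratified by the number of
##     previous hospitalizations, without and with the entry-time probe.
## Writes one row per (model, covariate) to results/model_ladder.csv.

library(recmstate)

dir.create("results", showWarnings = FALSE)
h <- simulate_dataset(scenario_config(2, alternative = TRUE), rep = 1,
                      seed = 20260923L)
d <- augment_markov_covariate(h, "prev_count")

row_of <- function(model, fit, covariate) {
  w <- wald_test(fit, covariate)
  data.frame(model = model, covariate = covariate,
             estimate = w$estimate, se_robust = w$se,
             ratio = w$ratio, ci_low = w$ci[1], ci_high = w$ci[2], p = w$p)
}

rows <- list()

## Cox model, first hospitalization only (censor at death or first event)
first <- d[d$prev_count == 0, ]
cox1 <- cox_fit(first, "Z")
rows[[1]] <- row_of("Cox (first hospitalization)", cox1, "Z")

ag <- cox_fit(d, "Z")
rows[[2]] <- row_of("AG", ag, "Z")
ag_probe <- cox_fit(d, c("Z", "prev_count"))
rows[[3]] <- row_of("AG + prev. hosp.", ag_probe, "Z")
rows[[4]] <- row_of("AG + prev. hosp.", ag_probe, "prev_count")

## rate model restricted to the first 2000 days: beyond that the censoring
## survival estimate is small and the IPCW weights become volatile
gl <- ghosh_lin_fit(h, "Z", horizon = 2000)
rows[[5]] <- row_of("Ghosh-Lin (to day 2000)", gl, "Z")

pwp <- cox_fit(d, "Z", strata = "prev_count")
rows[[6]] <- row_of("PWP", pwp, "Z")
pwp_probe <- cox_fit(d, c("Z", "entry_time"), strata = "prev_count")
rows[[7]] <- row_of("PWP + entry time", pwp_probe, "Z")
rows[[8]] <- row_of("PWP + entry time", pwp_probe, "entry_time")

tab <- do.call(rbind, rows)
write.csv(tab, "results/model_ladder.csv", row.names = FALSE)
cat("Model ladder (robust SEs; true treatment HR on home->hospital = 0.85):\n\n")
print(tab, digits = 3, row.names = FALSE)

cat("\nReading guide: a significant previous-hospitalization or entry-time",
    "\neffect flags a violation of the Markov assumption (here induced by",
    "the gamma frailty). With the day-2000 horizon the Ghosh-Lin rate",
    "\nratio lands next to the AG and PWP hazard ratios; without a horizon",
    "the IPCW weights of the latest events dominate the estimating",
    "\nequation and the rate estimate becomes erratic (see the methods",
    "vignette).\n")
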