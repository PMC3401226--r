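#!/usr/bin/env Rscript
# Main experiment: bias of five abundance analyses under trap loss.
#
# 100 simulated datasets at the field parameters; each is manipulated to
# lose 0/5/10/15/20% of its 300 points under three scenarios: during high
# activity in the high-abundance treatments ("high_catch"), during low
# activity in the low-abundance treatments ("low_catch"), and uniformly at
# random. Five analyses are fitted to every manipulated dataset:
#   M1  traditional standardization to 100 trap-days, Gaussian
#   M2  Gaussian, seasonality + effort as offsets (known seasonality)
#   M3  Gaussian, seasonality as a free factor (unknown seasonality)
#   M4  negative binomial, seasonality + effort as offsets
#   M5  negative binomial, seasonality as a free factor
# The headline metric is the mean (over simulations) log-scale bias of the
# treatment means, summed over the three treatments.

library(trapbias)

args <- commandArgs(trailingOnly = TRUE)
master_seed <- if (length(args)) as.integer(args[[1]]) else 1L

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

t0 <- Sys.time()
grid <- run_grid(
  parameter_sets()["field"],
  scenarios = c("high_catch", "low_catch", "random"),
  loss_pcts = c(0, 5, 10, 15, 20),
  n_sims = 100, master_seed = master_seed
)
cat("Fitted 5 models x 3 scenarios x 5 loss levels x 100 simulations in",
    format(round(Sys.time() - t0, 1)), "\n\n")

s <- grid$summary
s$mean_bias <- round(s$mean_bias, 3)
s$se_bias <- round(s$se_bias, 3)
write.csv(s, "results/bias_summary_field.csv", row.names = FALSE)
q <- prediction_quantiles(grid$records)
for (col in c("q25", "median", "q75", "lower_whisker", "upper_whisker")) {
  q[[col]] <- round(q[[col]], 4)
}
write.csv(q, "results/prediction_quantiles_field.csv", row.names = FALSE)
write.csv(grid$records, "scratch/records_field.csv", row.names = FALSE)

cat("Mean summed log-scale bias (field parameters):\n")
wide <- reshape(s[, c("scenario", "loss_pct", "model_id", "mean_bias")],
                idvar = c("scenario", "loss_pct"), timevar = "model_id",
                direction = "wide")
names(wide) <- sub("mean_bias.", "", names(wide))
print(wide, row.names = FALSE)

hi20 <- grid$records[grid$records$scenario == "high_catch" & grid$records$loss_pct == 20, ]
cat(sprintf(
  "\nTraditional standardization at 20%% high-catch loss: estimated increase of\nT2 over T1 = +%.1f%% (true +100%%) and T3 over T1 = +%.1f%% (true 4x).\n",
  percent_increase(hi20, "M1_trad_normal", 2),
  percent_increase(hi20, "M1_trad_normal", 3)
))
cat("The negative binomial models keep a small negative bias at every loss level;\n")
cat("the Gaussian models swing with the loss scenario.\n")
cat("\nWrote results/bias_summary_field.csv, results/prediction_quantiles_field.csv\n")
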