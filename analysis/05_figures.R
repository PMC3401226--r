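#!/usr/bin/env Rscript
# Box-and-whisker figures of predicted catch per model, treatment and loss
# level, plus mean-bias profiles, from the summaries written by
# 03_trap_loss_bias.R (run that first).

library(trapbias)
suppressMessages(library(ggplot2))

q <- read.csv("results/prediction_quantiles_field.csv")
s <- read.csv("results/bias_summary_field.csv")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

truth <- data.frame(
  treatment = 1:3,
  value = unname(treatment_truth(parameter_sets()[["field"]]))
)

for (sc in unique(q$scenario)) {
  qs <- q[q$scenario == sc, ]
  p <- ggplot(qs, aes(x = factor(loss_pct), ymin = lower_whisker, lower = q25,
                      middle = median, upper = q75, ymax = upper_whisker)) +
    geom_boxplot(stat = "identity", fill = "grey85") +
    geom_hline(data = truth, aes(yintercept = value), linewidth = 0.3) +
    facet_grid(model_id ~ treatment, scales = "free_y",
               labeller = labeller(treatment = function(x) paste("Treatment", x))) +
    labs(x = "Trap loss (% of design)", y = "Predicted catch per 100 trap-days",
         title = paste("Predicted catch under", sc, "trap loss"),
         subtitle = "Horizontal lines: true simulated abundance per treatment") +
    theme_bw(base_size = 9)
  ggsave(sprintf("results/figures/predicted_catch_%s.pdf", sc), p,
         width = 7, height = 9)
}

pb <- ggplot(s, aes(x = loss_pct, y = mean_bias, colour = model_id)) +
  geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
  geom_line() +
  geom_pointrange(aes(ymin = mean_bias - 2 * se_bias, ymax = mean_bias + 2 * se_bias),
                  size = 0.2) +
  facet_wrap(~scenario) +
  labs(x = "Trap loss (% of design)", y = "Mean summed log-scale bias",
       colour = "Model") +
  theme_bw(base_size = 10)
ggsave("results/figures/mean_bias.pdf", pb, width = 8, height = 3.5)

cat("Wrote figures under results/figures/\n")
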