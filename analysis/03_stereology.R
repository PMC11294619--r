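#!/usr/bin/env Rscript
# Step 3 — optical-fractionator estimates of nigral neuron number.
#
# Each hemisphere is a 6000 x 4000 x 3000 um field: control hemispheres
# hold 12 000 neurons, lesioned hemispheres 8 640 (a 28% loss). Fields are
# cut into 50 um sections, a 1-in-12 series is sampled, and neurons are
# counted in 100 x 80 um unbiased frames on a 600 x 400 um grid — an
# overall multiplier of 360. Estimates are expressed as a percentage of the
# control mean and contrasted with the bootstrapped mean difference.

suppressMessages(library(nigraquant))
dir.create("results", showWarnings = FALSE)
design <- read.csv("results/simulated/cohort_design.csv")

des <- stereology_design()
n_true <- ifelse(design$group == "lesioned", round(12000 * 0.72), 12000)

est <- vapply(seq_len(nrow(design)), function(i) {
  f <- generate_neuron_field(c(6000, 4000, 3000), n_true[i], 50, 12,
                             seed = design$base_seed[i])
  run_stereology(f$series, des, seed = design$base_seed[i] + 17L)$n_hat
}, numeric(1))

tab <- data.frame(design[c("group", "hemisphere")],
                  true_n = n_true, n_hat = est)
tab$pct_of_control <- percent_of_control(tab$n_hat,
                                         tab$n_hat[tab$group == "control"])
write.csv(tab, "results/stereology_per_hemisphere.csv", row.names = FALSE)

b <- bootstrap_mean_diff(tab$n_hat[tab$group == "control"],
                         tab$n_hat[tab$group == "lesioned"],
                         n_resamples = 5000, seed = 42)
tt <- unpaired_t(tab$n_hat[tab$group == "lesioned"],
                 tab$n_hat[tab$group == "control"])
loss_pct <- 100 * (1 - mean(tab$n_hat[tab$group == "lesioned"]) /
                     mean(tab$n_hat[tab$group == "control"]))

cat(sprintf("Control N_hat: %.0f +/- %.0f; lesioned: %.0f +/- %.0f\n",
            mean(tab$n_hat[tab$group == "control"]),
            sd(tab$n_hat[tab$group == "control"]),
            mean(tab$n_hat[tab$group == "lesioned"]),
            sd(tab$n_hat[tab$group == "lesioned"])))
cat(sprintf("Estimated neuron loss: %.1f%% (true 28%%)\n", loss_pct))
cat(sprintf("Mean difference %.0f, 95%% CI [%.0f, %.0f]; t = %.3f, p = %.4g\n",
            b$mean_diff, b$ci_low, b$ci_high, tt$t, tt$p))
write.csv(data.frame(loss_pct = loss_pct, mean_diff = b$mean_diff,
                     ci_low = b$ci_low, ci_high = b$ci_high,
                     t = tt$t, p = tt$p),
          "results/stereology_group_comparison.csv", row.names = FALSE)
cat("Wrote results/stereology_*.csv\n")
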