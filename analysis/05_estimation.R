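#!/usr/bin/env Rscript
# Step 5 — estimation statistics across every endpoint: Gardner-Altman
# plot data per variable and the control-referenced z-score profile.
#
# All per-hemisphere endpoints from steps 2-4 are gathered into one long
# table; each is contrasted (lesioned vs control) with a t-test and a
# bootstrapped mean difference, exported as Gardner-Altman plot data, and
# standardised against the control group into the z-score profile matrix
# (controls collapsed to their mean row).

suppressMessages(library(nigraquant))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)

puncta <- read.csv("results/puncta_per_hemisphere.csv")
stereo <- read.csv("results/stereology_per_hemisphere.csv")
dab <- read.csv("results/dab_per_hemisphere.csv")
iron <- read.csv("results/iron_per_hemisphere.csv")

long <- rbind(
  data.frame(group = stereo$group, hemisphere = stereo$hemisphere,
             variable = "stereo_TH_SN", value = stereo$n_hat),
  do.call(rbind, lapply(c("caudate", "putamen"), function(r) {
    s <- dab[dab$region == r, ]
    data.frame(group = s$group, hemisphere = s$hemisphere,
               variable = paste0("TH_surface_", r), value = s$surface_ratio)
  })),
  data.frame(group = iron$group, hemisphere = iron$hemisphere,
             variable = "iron_SN_ppm", value = iron$mean_ppm),
  do.call(rbind, lapply(c("n_whole", "n_peri", "n_cyto"), function(v) {
    data.frame(group = puncta$group, hemisphere = puncta$hemisphere,
               variable = paste0("LAMP2_", v), value = puncta[[v]])
  })))
long$group <- ifelse(long$group == "lesioned", "test", "control")
write_measurement_table(long, "results/all_endpoints_long.csv")

# per-variable comparisons + Gardner-Altman bundles
comp_rows <- list(); bundles <- list()
for (v in unique(long$variable)) {
  lv <- long[long$variable == v, ]
  b <- bootstrap_mean_diff(lv$value[lv$group == "control"],
                           lv$value[lv$group == "test"],
                           n_resamples = 5000, seed = 42)
  bundles[[v]] <- export_gardner_altman(b)
  comp_rows[[v]] <- data.frame(
    variable = v, control_mean = b$means["control"],
    test_mean = b$means["test"], mean_diff = b$mean_diff,
    ci_low = b$ci_low, ci_high = b$ci_high, t = b$t, p = b$p)
}
comparisons <- do.call(rbind, comp_rows)
write.csv(comparisons, "results/estimation_comparisons.csv",
          row.names = FALSE)
jsonlite::write_json(
  lapply(bundles, function(ga) ga[c("mean_diff", "ci_low", "ci_high",
                                    "ci_level", "diff_axis_origin")]),
  "results/gardner_altman_summaries.json", auto_unbox = TRUE, digits = NA)

# example rendered estimation plot (scratch: not a deliverable)
pdf("scratch/figures/gardner_altman_stereo.pdf", width = 7, height = 4)
plot_gardner_altman(bundles[["stereo_TH_SN"]], main = "stereo_TH_SN")
dev.off()

# z-score profile, controls pulled as mean
pr <- zscore_profile(long)
write.csv(data.frame(observation = rownames(pr$z), pr$z,
                     check.names = FALSE),
          "results/zscore_profile.csv", row.names = FALSE)

cat("Per-variable contrasts (test - control):\n")
print(comparisons, row.names = FALSE, digits = 4)
cat("\nZ-score profile (rows = hemispheres, controls pulled as mean):\n")
print(round(pr$z, 2))
cat("Wrote results/estimation_comparisons.csv, results/zscore_profile.csv\n")
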