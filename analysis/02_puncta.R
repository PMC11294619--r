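#!/usr/bin/env Rscript
# Step 2 — per-cell lysosomal-puncta quantification across the cohort.
#
# Ten cells per hemisphere are generated with Poisson-distributed per-cell
# puncta counts: control cells average 6 perinuclear + 6 cytosolic puncta,
# lesioned cells 12 perinuclear + 8 cytosolic — emulating the reported
# increase in lysosome number with a preferential perinuclear accumulation,
# with cell-to-cell biological variability. Cells are quantified with the
# default pipeline
# (per-cell Otsu threshold, 2 um perinuclear band, 2:1 QC ratio), averaged
# per hemisphere, and the group contrast is estimated with the bootstrapped
# mean difference.

suppressMessages(library(nigraquant))
dir.create("results", showWarnings = FALSE)
design <- read.csv("results/simulated/cohort_design.csv")

cells_per_hemi <- 10L
images <- list(); meta <- list()
for (i in seq_len(nrow(design))) {
  lesioned <- design$group[i] == "lesioned"
  set.seed(design$base_seed[i])
  n_peri <- rpois(cells_per_hemi, if (lesioned) 12 else 6)
  n_cyto <- rpois(cells_per_hemi, if (lesioned) 8 else 6)
  for (j in seq_len(cells_per_hemi)) {
    p <- cell_image_params(
      n_perinuclear = n_peri[j], n_cytosolic = n_cyto[j],
      gaussian_noise_sd = 10, poisson_noise = TRUE,
      seed = design$base_seed[i] + j)
    img <- generate_cell_image(p)$image
    img$cell_id <- sprintf("%s_c%02d", design$hemisphere[i], j)
    images[[length(images) + 1L]] <- img
    meta[[length(meta) + 1L]] <- data.frame(
      cell_id = img$cell_id, group = design$group[i],
      hemisphere = design$hemisphere[i])
  }
}
meta <- do.call(rbind, meta)

res <- run_puncta_pipeline(images, metadata = meta)
write.csv(res$metrics, "results/puncta_per_cell.csv", row.names = FALSE)
write.csv(res$puncta, "results/puncta_per_punctum.csv", row.names = FALSE)
write.csv(res$summary, "results/puncta_per_hemisphere.csv", row.names = FALSE)

cat(sprintf("Quantified %d cells (%d excluded by QC/errors)\n",
            nrow(res$metrics), nrow(res$exclusions)))

# group contrast on per-hemisphere whole-cell counts
s <- res$summary
comparisons <- lapply(c("n_whole", "n_peri", "n_cyto"), function(v) {
  b <- bootstrap_mean_diff(s[[v]][s$group == "control"],
                           s[[v]][s$group == "lesioned"],
                           n_resamples = 5000, seed = 42)
  data.frame(variable = v,
             control_mean = b$means["control"], test_mean = b$means["test"],
             mean_diff = b$mean_diff, ci_low = b$ci_low, ci_high = b$ci_high,
             t = b$t, p = b$p)
})
comparisons <- do.call(rbind, comparisons)
write.csv(comparisons, "results/puncta_group_comparisons.csv",
          row.names = FALSE)
cat("Group contrasts (lesioned - control, per-hemisphere means):\n")
print(comparisons, row.names = FALSE, digits = 4)
cat("Wrote results/puncta_*.csv\n")
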