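#!/usr/bin/env Rscript
# Step 1 — simulate the study's raw inputs and write example artifacts.
#
# The synthetic cohort mirrors the study layout: a control group of 6
# hemispheres and a lesioned group of 4 hemispheres. This script writes one
# example annotated cell image (TIFF + JSON sidecar) with its ground-truth
# catalogue, an example DAB image summary, an example elemental map, and
# the cohort design table that the later steps share. Later steps
# regenerate their inputs from the seeds recorded here, so nothing large
# needs to be stored.

suppressMessages(library(nigraquant))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

SEED <- 20260924L

design <- data.frame(
  group = rep(c("control", "lesioned"), c(6, 4)),
  hemisphere = c(sprintf("ctrl_h%d", 1:6), sprintf("les_h%d", 1:4)),
  # per-hemisphere base seeds for every generator downstream
  base_seed = SEED + seq_len(10) * 101L)
write.csv(design, "results/simulated/cohort_design.csv", row.names = FALSE)

# one example cell image, written in the exchange format
g <- generate_cell_image(cell_image_params(seed = SEED))
write_annotated_image(g$image, "results/simulated/example_cell")
write_ground_truth(g$truth[c("n_perinuclear", "n_cytosolic")],
                   "results/simulated/example_cell_truth.json")
write.csv(g$truth$puncta_catalog,
          "results/simulated/example_cell_catalog.csv", row.names = FALSE)

d <- generate_dab_image(c(200, 200), 0.30, 180, 40, 10, seed = SEED)
m <- generate_elemental_map(c(100, 100), 5, 150, 10, seed = SEED)

cat("Simulated cohort design: 6 control + 4 lesioned hemispheres\n")
cat(sprintf("Example cell: %d puncta catalogued (%d perinuclear, %d cytosolic)\n",
            nrow(g$truth$puncta_catalog), g$truth$n_perinuclear,
            g$truth$n_cytosolic))
cat(sprintf("Example DAB image: stained fraction %.4f (target 0.30)\n",
            d$truth$achieved_fraction))
cat(sprintf("Example elemental map: %.0f x %.0f um, mean %.1f ppm\n",
            map_extent_um(m)[1], map_extent_um(m)[2],
            roi_mean_concentration(m)$mean_ppm))
cat("Wrote results/simulated/\n")
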