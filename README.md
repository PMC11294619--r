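# nigraquant

Quantitative post-mortem image analysis of nigral dopaminergic neurons,
for neuropathologists and imaging scientists who need the measurement
chain of a primate neurodegeneration study as tested, reproducible code:

* **Puncta quantification** — detection of lysosomal-related fluorescent
  puncta inside a labelled-neuron mask, with subcellular localisation
  into perinuclear and cytosolic compartments, per-cell QC, and
  per-punctum distances to the nucleus.
* **Stereology** — the optical fractionator,
  N̂ = ΣQ⁻ / (ssf · asf · tsf), with unbiased counting frames
  (inclusion top/right, forbidden left/bottom lines) on a systematic
  uniform random grid.
* **Densitometry** — ROI mean grey level, thresholded stained-surface
  ratio (surface / total ROI surface), percent-of-control scaling, and
  elemental-map (ppm) ROI averaging.
* **Estimation statistics** — pooled-variance Student t-tests,
  bootstrapped mean differences with percentile / BCa / studentized 95%
  CIs (Gardner–Altman plot data), and control-referenced z-score
  profiles, z = (x − mean_ctrl)/sd_ctrl.

Because the tissue data behind such studies cannot be redistributed, the
package ships a **synthetic-data generator** that emulates every input —
single-cell images with catalogued puncta, sectioned 3-D neuron fields,
DAB images with an exactly known stained fraction, elemental maps, and
two-group measurement tables — and the whole pipeline is validated
against that ground truth.

## Worked example

Generate one synthetic neuron, quantify its puncta, and estimate a
neuron total and a group effect:

```r
library(nigraquant)

g   <- generate_cell_image(cell_image_params(seed = 1))
img <- g$image
det <- detect_puncta(apply_cell_mask(img, "puncta"), img$pixel_size_um,
                     mask = img$soma_mask)
cmp <- partition_compartments(img$soma_mask, img$nucleus_mask,
                              img$pixel_size_um, perinuclear_band_um = 2)
qc  <- qc_ratio_filter(img$soma_mask, img$nucleus_mask)
puncta_metrics(det$records, cmp, cell_id = img$cell_id, qc = qc)
#>           cell_id channel qc_ratio qc_pass n_whole n_peri n_cyto
#> 1 synthetic_seed1  puncta     5.01    TRUE      15     10      5
#>   mean_area_whole mean_area_peri mean_area_cyto total_area
#> 1            0.61           0.61           0.61       9.15
```

The cell passes QC (cytoplasm:nucleus ratio 5.01 ≥ 2); all 15 catalogued
puncta are recovered, 10 perinuclear and 5 cytosolic exactly as placed,
with a mean punctum area of 0.61 µm².

```r
des <- stereology_design()   # 100 x 80 um frames, 600 x 400 um grid, 1-in-12
f   <- generate_neuron_field(c(6000, 4000, 3000), 12000, 50, 12, seed = 1)
run_stereology(f$series, des, seed = 2)
#> <stereology_estimate> sum_Q = 32 -> N_hat = 11520.0
```

32 neurons counted in the sampled frames scale by the design multiplier
360 to an estimate of 11 520 against a true 12 000 (the estimator is
unbiased; single-field spread at this design is ~18% CV).

```r
gt <- generate_group_table(6, 4, control_mean = 100, effect = -30, sd = 8,
                           seed = 1)
bootstrap_mean_diff(gt$table$value[gt$table$group == "control"],
                    gt$table$value[gt$table$group == "test"], seed = 3)
#> <group_comparison> mean diff (test - control) = -26.78, 95% CI [-33.48, -20.94] (percentile, 5000 resamples)
#>   t = -6.498, p = 0.0001885; n = 6 vs 4
```

The observed difference of −26.8 (true effect −30) comes with its
bootstrap CI and the pooled t-test of the same comparison;
`export_gardner_altman()` turns this object into the data bundle of a
two-panel estimation plot.

## Analysis workflow

`analysis/01_simulate.R` … `05_estimation.R` run a complete synthetic
cohort study (6 control vs 4 lesioned hemispheres: puncta accumulation,
28% neuron loss, reduced striatal staining, 3-fold nigral iron) end to
end, writing per-hemisphere tables, group contrasts and the z-score
profile under `results/`. Run them in order from the repository root with
`Rscript analysis/01_simulate.R`, etc.

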