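test_that("cell masking is the identity inside and zero outside", {
  g <- default_cell(seed = 1)
  img <- g$image
  masked <- apply_cell_mask(img, "puncta")
  expect_true(all(masked[!img$soma_mask] == 0))
  expect_equal(masked[img$soma_mask], img$channels$puncta[img$soma_mask])
  expect_error(apply_cell_mask(img, "nope"), "unknown channel")

  # adversarial: puncta rendered outside the soma are removed by the mask
  ch <- img$channels$puncta
  ch[1:20, 1:20] <- 500  # bright blob far outside the soma
  img2 <- annotated_image(list(puncta = ch), img$pixel_size_um,
                          img$soma_mask, img$nucleus_mask)
  det <- detect_puncta(apply_cell_mask(img2, "puncta"), img2$pixel_size_um,
                       mask = img2$soma_mask)
  lab_outside <- det$labels[!img2$soma_mask]
  expect_true(all(lab_outside == 0L))
})

test_that("detection recovers the noiseless catalogue exactly", {
  g <- default_cell(seed = 7)
  q <- quantify_cell(g)
  cat_ <- g$truth$puncta_catalog
  expect_equal(nrow(q$det$records), nrow(cat_))
  # centroids within 1 px of the catalogued centres
  for (i in seq_len(nrow(q$det$records))) {
    d <- sqrt(min((cat_$centre_row_um - q$det$records$centroid_row_um[i])^2 +
                    (cat_$centre_col_um - q$det$records$centroid_col_um[i])^2))
    expect_lt(d, g$image$pixel_size_um)
  }
})

test_that("detection handles blank grids, size floors and degenerate histograms", {
  blank <- matrix(5, 40, 40)
  det <- detect_puncta(blank, 0.1, threshold_method = "fixed",
                       threshold_value = 10, mask = matrix(TRUE, 40, 40),
                       smooth_sigma_px = 0)
  expect_equal(nrow(det$records), 0L)

  # two 1-px specks below the min-size floor
  speck <- matrix(0, 40, 40); speck[10, 10] <- 100; speck[30, 30] <- 100
  det2 <- detect_puncta(speck, 0.1, threshold_method = "fixed",
                        threshold_value = 50, min_area_px = 2L,
                        mask = matrix(TRUE, 40, 40), smooth_sigma_px = 0)
  expect_equal(nrow(det2$records), 0L)
  det3 <- detect_puncta(speck, 0.1, threshold_method = "fixed",
                        threshold_value = 50, min_area_px = 1L,
                        mask = matrix(TRUE, 40, 40), smooth_sigma_px = 0)
  expect_equal(nrow(det3$records), 2L)

  expect_error(detect_puncta(blank, 0.1, threshold_method = "otsu",
                             mask = matrix(TRUE, 40, 40),
                             smooth_sigma_px = 0),
               "degenerate.*fixed threshold")
})

test_that("component labelling is 8-connected with scan-order labels", {
  m <- matrix(0, 10, 10)
  m[2, 2] <- 100; m[3, 3] <- 100   # diagonal pair: one component
  m[7, 7] <- 100; m[7, 8] <- 100   # second component
  det <- detect_puncta(m, 1, threshold_method = "fixed", threshold_value = 50,
                       min_area_px = 1L, mask = matrix(TRUE, 10, 10),
                       smooth_sigma_px = 0)
  expect_equal(nrow(det$records), 2L)
  expect_equal(det$records$area_px, c(2L, 2L))
  # scan order: the (2,2) component is label 1
  expect_equal(det$labels[2, 2], 1L)
  expect_equal(det$labels[3, 3], 1L)
  expect_equal(det$labels[7, 7], 2L)
})

test_that("detected stained area is monotone non-increasing in a fixed threshold", {
  g <- default_cell(seed = 13)
  masked <- apply_cell_mask(g$image, "puncta")
  areas <- vapply(c(20, 40, 60, 80), function(t) {
    det <- detect_puncta(masked, 0.1, threshold_method = "fixed",
                         threshold_value = t, mask = g$image$soma_mask,
                         min_area_px = 1L, smooth_sigma_px = 0)
    sum(det$records$area_um2)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("noise robustness: count error stays small at peak-SNR 5", {
  errs <- vapply(0:29, function(s) {
    g <- generate_cell_image(cell_image_params(seed = s,
                                               gaussian_noise_sd = 20))
    det <- detect_puncta(apply_cell_mask(g$image, "puncta"), 0.1,
                         mask = g$image$soma_mask)
    abs(nrow(det$records) - 15) / 15
  }, numeric(1))
  expect_lte(mean(errs), 0.05)
})

test_that("compartment partition tiles the cytoplasm and matches the annulus area", {
  # concentric discs: nucleus r = 10 um, soma r = 30 um, band 5 um, 0.1 um/px
  soma <- disc_mask(700, c(350, 350), 300)
  nuc <- disc_mask(700, c(350, 350), 100)
  cmp <- partition_compartments(soma, nuc, 0.1, 5)
  # exact partition
  expect_true(all(xor(cmp$perinuclear, cmp$cytosolic) == cmp$cytoplasm))
  expect_false(any(cmp$perinuclear & cmp$cytosolic))
  # annulus area pi (15^2 - 10^2)
  a <- sum(cmp$perinuclear) * 0.1^2
  expect_lt(abs(a - pi * (15^2 - 10^2)) / (pi * (15^2 - 10^2)), 0.03)

  # saturation: band wider than the soma -> cytosolic empty
  cmp2 <- partition_compartments(soma, nuc, 0.1, 100)
  expect_equal(sum(cmp2$cytosolic), 0L)
  expect_equal(sum(cmp2$perinuclear), sum(cmp2$cytoplasm))

  # vanishing band -> one-pixel shell around the nucleus
  cmp3 <- partition_compartments(soma, nuc, 0.1, 1e-9)
  d <- as.matrix(EBImage::distmap(!nuc))
  expect_equal(which(cmp3$perinuclear), which(cmp3$cytoplasm & d <= 1))

  expect_error(partition_compartments(soma, soma, 0.1, 5), "cytoplasm")
  expect_error(partition_compartments(soma, matrix(FALSE, 700, 700), 0.1, 5),
               "nucleus")
})

test_that("QC area-ratio filter implements the 2:1 criterion", {
  cases <- list(c(1.0, FALSE), c(1.5, FALSE), c(2.0, TRUE), c(3.0, TRUE))
  for (cs in cases) {
    m <- ratio_masks(cs[1L])
    qc <- qc_ratio_filter(m$soma, m$nucleus)
    expect_equal(qc$qc_ratio, cs[1L])
    expect_identical(qc$qc_pass, as.logical(cs[2L]))
  }
  expect_error(qc_ratio_filter(ratio_masks(2)$soma, matrix(FALSE, 60, 60)),
               "zero nucleus")
})

test_that("nucleus ellipse fit matches known shapes and is rotation invariant", {
  # circle radius 10 um at 0.1 um/px
  circ <- disc_mask(300, c(150, 150), 100)
  e <- fit_nucleus_ellipse(circ, 0.1)
  expect_lt(abs(e$semi_major_um - 10) / 10, 0.02)
  expect_lt(abs(e$semi_minor_um - 10) / 10, 0.02)
  expect_lt(abs(e$mean_radius_um - 10) / 10, 0.02)

  # axis-aligned ellipse a = 4, b = 2 um on a dense raster
  ell <- nigraquant:::rasterise_ellipse(c(300, 300), c(150, 150), c(80, 40))  # px, 0.05 um/px
  e2 <- fit_nucleus_ellipse(ell, 0.05)
  expect_lt(abs(e2$semi_major_um - 4) / 4, 0.02)
  expect_lt(abs(e2$semi_minor_um - 2) / 2, 0.02)
  expect_lt(abs(e2$mean_radius_um - 3) / 3, 0.02)

  # rotation invariance of the fitted axes
  ell37 <- nigraquant:::rasterise_ellipse(c(300, 300), c(150, 150), c(80, 40),
                             theta = 37 * pi / 180)
  e3 <- fit_nucleus_ellipse(ell37, 0.05)
  expect_lt(abs(e3$semi_major_um - e2$semi_major_um), 0.05)
  expect_lt(abs(e3$semi_minor_um - e2$semi_minor_um), 0.05)

  expect_error(fit_nucleus_ellipse(matrix(FALSE, 10, 10), 0.1), ">= 5")
  line <- matrix(FALSE, 20, 20); line[5, 3:12] <- TRUE
  expect_error(fit_nucleus_ellipse(line, 0.1), "degenerate")
})

test_that("punctum-to-nucleus distances follow the mean-radius convention", {
  circ <- disc_mask(300, c(150, 150), 100)  # r = 10 um at 0.1 um/px
  e <- fit_nucleus_ellipse(circ, 0.1)
  ctr <- e$centre_um
  at_centre <- distance_to_nucleus(ctr, e)
  expect_equal(at_centre$dist_centre_um, 0)
  expect_equal(at_centre$dist_border_um, -e$mean_radius_um)

  p15 <- distance_to_nucleus(ctr + c(15, 0), e)
  expect_equal(p15$dist_centre_um, 15)
  expect_lt(abs(p15$dist_border_um - 5), 0.25)  # circle: 15 - 10

  # direct arithmetic: mean radius 3, distance 5 -> border distance 2
  e_syn <- structure(list(centre_um = c(0, 0), semi_major_um = 4,
                          semi_minor_um = 2, orientation_rad = 0,
                          mean_radius_um = 3), class = "nucleus_ellipse")
  expect_equal(distance_to_nucleus(c(3, 4), e_syn)$dist_border_um, 2)
})

test_that("per-cell metrics conserve counts and aggregate areas correctly", {
  g <- default_cell(seed = 17)
  q <- quantify_cell(g)
  m <- q$metrics
  expect_equal(m$n_whole, m$n_peri + m$n_cyto)
  expect_equal(m$n_whole, 15L)
  expect_equal(m$n_peri, 10L)
  expect_equal(m$n_cyto, 5L)
  expect_equal(m$total_area, sum(q$det$records$area_um2))

  # empty records: zero counts, missing means
  m0 <- puncta_metrics(q$det$records[0, ], q$cmp)
  expect_equal(m0$n_whole, 0L)
  expect_true(is.na(m0$mean_area_whole))

  # constancy: all puncta the same area -> every mean equals it
  rec <- q$det$records
  rec$area_um2 <- 0.5
  mc <- puncta_metrics(rec, q$cmp)
  expect_equal(mc$mean_area_whole, 0.5)
  expect_equal(mc$mean_area_peri, 0.5)
  expect_equal(mc$mean_area_cyto, 0.5)

  # centroid outside the cell is a hard error
  rec_bad <- q$det$records[1, ]
  rec_bad$centroid_row_um <- 0.05
  rec_bad$centroid_col_um <- 0.05
  expect_error(puncta_metrics(rec_bad, q$cmp), "masking bug")
})
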