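test_that("cell generator honours counts, geometry and the empty case", {
  # empty case: background only, empty catalogue
  g0 <- generate_cell_image(cell_image_params(n_perinuclear = 0,
                                              n_cytosolic = 0, seed = 5))
  expect_equal(nrow(g0$truth$puncta_catalog), 0L)
  expect_true(all(g0$image$channels$puncta == 10))  # background only

  g <- default_cell(seed = 11)
  cat_ <- g$truth$puncta_catalog
  expect_equal(nrow(cat_), 15L)
  expect_equal(sum(cat_$compartment == "perinuclear"), 10L)
  expect_equal(sum(cat_$compartment == "cytosolic"), 5L)

  # catalogue consistency: centres inside soma, outside nucleus
  img <- g$image
  r_idx <- floor(cat_$centre_row_um / img$pixel_size_um) + 1L
  c_idx <- floor(cat_$centre_col_um / img$pixel_size_um) + 1L
  expect_true(all(img$soma_mask[cbind(r_idx, c_idx)]))
  expect_false(any(img$nucleus_mask[cbind(r_idx, c_idx)]))

  # placement respects compartment geometry relative to the nucleus border
  d_nuc <- as.matrix(EBImage::distmap(!img$nucleus_mask)) * img$pixel_size_um
  d <- d_nuc[cbind(r_idx, c_idx)]
  expect_true(all(d[cat_$compartment == "perinuclear"] <= 2))
  expect_true(all(d[cat_$compartment == "cytosolic"] > 2))

  # minimum separation between puncta centres: 2.5 radii
  dm <- as.matrix(dist(cbind(cat_$centre_row_um, cat_$centre_col_um)))
  expect_gte(min(dm[upper.tri(dm)]), 2.5 * 0.5)
})

test_that("cell generator is deterministic and validates its parameters", {
  a <- generate_cell_image(cell_image_params(seed = 21))
  b <- generate_cell_image(cell_image_params(seed = 21))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$puncta_catalog, b$truth$puncta_catalog)

  expect_error(cell_image_params(n_perinuclear = -1), "non-negative")
  expect_error(cell_image_params(punctum_radius_um = 3,
                                 perinuclear_band_um = 2), "band")
  expect_error(cell_image_params(punctum_intensity = 5,
                                 background_level = 10), "exceed")
  # infeasible placement: far more puncta than the band can hold
  expect_error(
    generate_cell_image(cell_image_params(n_perinuclear = 400, seed = 1)),
    "placement failure.*perinuclear")
})

test_that("neuron field sectioning conserves neurons and sampling has the right rate", {
  f0 <- generate_neuron_field(c(1000, 1000, 500), 0, 50, 12, seed = 1)
  expect_equal(nrow(f0$series$points), 0L)

  f <- generate_neuron_field(c(6000, 4000, 3000), 12000, 50, 12, seed = 2)
  expect_equal(f$series$n_sections, 60L)  # 3000 / 50
  expect_equal(f$truth$true_neuron_count, 12000L)
  # conservation: every neuron in exactly one section
  expect_equal(nrow(f$series$points), 12000L)
  expect_true(all(f$series$points$section >= 1L &
                    f$series$points$section <= 60L))
  expect_equal(sum(table(f$series$points$section)), 12000L)
  expect_equal(sum(f$series$sampled), 5L)  # 60 / 12

  # expected neurons on sampled sections ~ n / period over seeds
  ns <- vapply(1:100, function(s) {
    fs <- generate_neuron_field(c(6000, 4000, 3000), 12000, 50, 12, seed = s)
    sum(fs$series$points$section %in% which(fs$series$sampled))
  }, numeric(1))
  expect_lt(abs(mean(ns) - 1000), 3 * sd(ns) / sqrt(100))

  expect_error(generate_neuron_field(c(-1, 10, 10), 5, 5, 2, seed = 1),
               "positive")
})

test_that("DAB generator hits the requested stained fraction exactly", {
  n <- 120L * 120L
  for (f in c(0, 0.3, 1)) {
    d <- generate_dab_image(c(120, 120), f, 180, 40, 0, seed = 9)
    expect_equal(sum(d$truth$stain_mask), round(f * n))
    expect_equal(d$truth$achieved_fraction, round(f * n) / n)
  }
  d0 <- generate_dab_image(c(50, 50), 0, 180, 40, 0, seed = 1)
  expect_true(all(d0$image == 40))
  d1 <- generate_dab_image(c(50, 50), 1, 180, 40, 0, seed = 1)
  expect_true(all(d1$image == 180))
  expect_error(generate_dab_image(c(50, 50), 1.2, 180, 40, 0, seed = 1),
               "\\[0, 1\\]")
})

test_that("elemental map has the stated physical extent and statistics", {
  m <- generate_elemental_map(c(100, 100), 5, 150, 10, seed = 3)
  expect_equal(map_extent_um(m), c(500, 500))
  # CLT bound on the ROI mean: 3 * sd / sqrt(n)
  expect_lt(abs(roi_mean_concentration(m)$mean_ppm - 150), 3 * 10 / 100)

  m0 <- generate_elemental_map(c(20, 30), 5, 80, 0, seed = 3)
  expect_true(all(m0$grid == 80))
  expect_error(generate_elemental_map(c(10, 10), 5, -5, 1, seed = 1), ">= 0")
})

test_that("group table generator encodes the requested effect", {
  g <- generate_group_table(6, 4, 100, -30, 8, seed = 4)
  expect_equal(nrow(g$table), 10L)
  expect_equal(sort(unique(g$table$group)), c("control", "test"))
  expect_equal(g$truth$true_mean_difference, -30)

  # degenerate sd -> 0: observed difference is exact
  gd <- generate_group_table(3, 3, 10, 5, 0, seed = 1)
  expect_equal(mean(gd$table$value[gd$table$group == "test"]) -
                 mean(gd$table$value[gd$table$group == "control"]), 5)

  # Monte-Carlo: mean observed difference ~ effect over 500 seeds
  diffs <- vapply(1:500, function(s) {
    gt <- generate_group_table(6, 4, 100, -30, 8, seed = s)$table
    mean(gt$value[gt$group == "test"]) - mean(gt$value[gt$group == "control"])
  }, numeric(1))
  expect_lt(abs(mean(diffs) + 30), 1)

  expect_error(generate_group_table(1, 4, 0, 0, 1, seed = 1), "n >= 2")
})
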