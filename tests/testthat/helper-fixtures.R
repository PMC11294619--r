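# Fixtures shared across test files. Everything is generated in code; no
# binary fixtures are stored.

# a small noiseless default cell, cached per test run
default_cell <- local({
  cache <- new.env()
  function(seed = 1L, ...) {
    key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cell_image(cell_image_params(seed = seed, ...))
    }
    cache[[key]]
  }
})

# rectangular soma/nucleus masks with exact cytoplasm:nucleus pixel ratios
ratio_masks <- function(ratio, nucleus_px = 100L, dim_px = c(60L, 60L)) {
  nuc <- matrix(FALSE, dim_px[1L], dim_px[2L])
  nuc[21:30, 21:30] <- TRUE                     # 100 px nucleus
  soma <- nuc
  need <- as.integer(round(ratio * nucleus_px)) # cytoplasm pixels wanted
  # grow a rectangle rightwards of the nucleus with exactly `need` pixels
  full_cols <- need %/% 10L
  rem <- need %% 10L
  if (full_cols > 0L) soma[21:30, 31:(30L + full_cols)] <- TRUE
  if (rem > 0L) soma[21:(20L + rem), 31L + full_cols] <- TRUE
  list(soma = soma, nucleus = nuc)
}

# disc mask of radius r_px centred in a square image
disc_mask <- function(dim_px, centre, r_px) {
  r <- matrix(seq_len(dim_px), dim_px, dim_px)
  c_ <- t(r)
  (r - centre[1L])^2 + (c_ - centre[2L])^2 <= r_px^2
}

# match detected records to a ground-truth catalogue by nearest centre;
# returns the catalogue compartment for each detected punctum
matched_truth_compartment <- function(records, catalog) {
  vapply(seq_len(nrow(records)), function(i) {
    d <- (catalog$centre_row_um - records$centroid_row_um[i])^2 +
      (catalog$centre_col_um - records$centroid_col_um[i])^2
    catalog$compartment[which.min(d)]
  }, character(1))
}

# run detection + compartment metrics on one generated cell
quantify_cell <- function(gen, band_um = 2, ...) {
  img <- gen$image
  det <- detect_puncta(apply_cell_mask(img, "puncta"), img$pixel_size_um,
                       mask = img$soma_mask, ...)
  cmp <- partition_compartments(img$soma_mask, img$nucleus_mask,
                                img$pixel_size_um, band_um)
  m <- puncta_metrics(det$records, cmp, cell_id = img$cell_id)
  list(det = det, cmp = cmp, metrics = m)
}
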