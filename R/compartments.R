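#' Partition the cytoplasm into perinuclear and cytosolic compartments
#'
#' The perinuclear compartment is the set of cytoplasm pixels whose
#' Euclidean distance to the nucleus region does not exceed the band width;
#' the cytosolic compartment is the remaining cytoplasm. The two masks tile
#' the cytoplasm exactly. The distance threshold is floored at one pixel so
#' that in the limit of a vanishing band the perinuclear compartment is the
#' one-pixel shell around the nucleus.
#'
#' @param soma_mask,nucleus_mask Logical matrices; nucleus inside soma.
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @param perinuclear_band_um Band width in micrometres, > 0.
#' @return Object of class `compartment_masks`: list(whole_cell, nucleus,
#'   cytoplasm, perinuclear, cytosolic, pixel_size_um).
#' @export
partition_compartments <- function(soma_mask, nucleus_mask, pixel_size_um,
                                   perinuclear_band_um) {
  soma_mask <- as_mask(soma_mask); nucleus_mask <- as_mask(nucleus_mask)
  if (any(nucleus_mask & !soma_mask)) stop("nucleus mask must lie inside soma mask")
  if (perinuclear_band_um <= 0) stop("perinuclear_band_um must be > 0")
  if (sum(nucleus_mask) == 0L) stop("empty nucleus mask")
  cytoplasm <- soma_mask & !nucleus_mask
  if (sum(cytoplasm) == 0L) stop("empty cytoplasm (soma equals nucleus)")
  d_px <- EBImage::imageData(EBImage::distmap(!nucleus_mask))
  thr_px <- max(perinuclear_band_um / pixel_size_um, 1)
  perinuclear <- cytoplasm & (d_px <= thr_px)
  cytosolic <- cytoplasm & !perinuclear
  structure(
    list(whole_cell = soma_mask, nucleus = nucleus_mask,
         cytoplasm = cytoplasm, perinuclear = perinuclear,
         cytosolic = cytosolic, pixel_size_um = pixel_size_um),
    class = "compartment_masks")
}

#' Cytoplasm-to-nucleus area QC filter
#'
#' Computes the ratio of cytoplasmic to nuclear ROI area and flags whether
#' the cell passes the minimum-ratio criterion (default 2:1, read as
#' ratio >= 2). Cells failing it are excluded from per-cell analysis to
#' prevent bias from cells captured with too little visible cytoplasm.
#'
#' @param soma_mask,nucleus_mask Logical matrices.
#' @param min_ratio Minimum acceptable cytoplasm:nucleus area ratio.
#' @return List: `qc_ratio` (float), `qc_pass` (logical).
#' @export
qc_ratio_filter <- function(soma_mask, nucleus_mask, min_ratio = 2.0) {
  soma_mask <- as_mask(soma_mask); nucleus_mask <- as_mask(nucleus_mask)
  n_nuc <- sum(nucleus_mask)
  if (n_nuc == 0L) stop("zero nucleus area: QC ratio undefined")
  n_cyto <- sum(soma_mask & !nucleus_mask)
  ratio <- n_cyto / n_nuc
  list(qc_ratio = ratio, qc_pass = ratio >= min_ratio)
}
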