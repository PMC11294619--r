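#' Detect fluorescent puncta in a masked channel
#'
#' Standard spot calling: optional Gaussian pre-smoothing, automatic (Otsu)
#' or fixed thresholding computed on within-mask pixels only, binarisation,
#' and 8-connected component labelling with a minimum-size floor. Areas and
#' centroids are reported in micrometres (pixel-centre convention).
#'
#' Otsu is computed per cell on the within-mask intensity histogram so that
#' the (typically dominant) extracellular background cannot drive the
#' threshold. A degenerate within-mask histogram (fewer than two distinct
#' values) cannot support automatic thresholding and raises an error
#' suggesting a fixed threshold.
#'
#' @param masked_grid Numeric matrix, typically the output of
#'   [apply_cell_mask()].
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param threshold_method "otsu" or "fixed".
#' @param threshold_value Threshold intensity, required when
#'   `threshold_method = "fixed"`; pixels strictly above it are foreground.
#' @param min_area_px Minimum component area in pixels (default 2: rejects
#'   single-pixel specks).
#' @param mask Logical matrix restricting the analysis (and the Otsu
#'   histogram); defaults to `masked_grid != 0`, i.e. the applied cell mask.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels (0 = none).
#'   Smoothing suppresses pixel noise before thresholding, the usual
#'   practice for diffraction-limited spot detection.
#' @return List with `labels` (integer matrix, contiguous positive labels in
#'   row-major scan order) and `records` (data.frame: label, area_px,
#'   area_um2, centroid_row_um, centroid_col_um).
#' @export
detect_puncta <- function(masked_grid, pixel_size_um,
                          threshold_method = c("otsu", "fixed"),
                          threshold_value = NULL, min_area_px = 2L,
                          mask = NULL, smooth_sigma_px = 1) {
  threshold_method <- match.arg(threshold_method)
  if (length(masked_grid) == 0L) stop("empty grid")
  if (is.null(mask)) mask <- masked_grid != 0
  mask <- as_mask(mask)

  g <- masked_grid
  if (smooth_sigma_px > 0) {
    g <- EBImage::imageData(EBImage::gblur(EBImage::Image(g), sigma = smooth_sigma_px))
  }

  vals <- g[mask]
  if (threshold_method == "otsu") {
    if (length(unique(vals)) < 2L) {
      stop("within-mask histogram is degenerate (fewer than 2 distinct values); use a fixed threshold")
    }
    thr <- otsu_threshold(vals)
  } else {
    if (is.null(threshold_value)) stop("threshold_value required for fixed thresholding")
    thr <- threshold_value
  }

  fg <- (g > thr) & mask
  labels <- label_components_8(fg)

  if (max(labels) == 0L) {
    return(list(labels = labels, threshold = thr, records = empty_puncta_records()))
  }
  area_px <- tabulate(labels[labels > 0L])
  keep <- which(area_px >= min_area_px)
  # relabel kept components contiguously, preserving scan order
  remap <- integer(length(area_px))
  remap[keep] <- seq_along(keep)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  if (length(keep) == 0L) {
    return(list(labels = labels, threshold = thr, records = empty_puncta_records()))
  }

  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- tabulate(lab)
  cr <- tapply(px_centre_um(rows, pixel_size_um), lab, mean)
  cc <- tapply(px_centre_um(cols, pixel_size_um), lab, mean)
  records <- data.frame(
    label = seq_along(area),
    area_px = area,
    area_um2 = area * pixel_size_um^2,
    centroid_row_um = as.numeric(cr),
    centroid_col_um = as.numeric(cc))
  list(labels = labels, threshold = thr, records = records)
}

empty_puncta_records <- function() {
  data.frame(label = integer(0), area_px = integer(0), area_um2 = numeric(0),
             centroid_row_um = numeric(0), centroid_col_um = numeric(0))
}

# Otsu threshold of an intensity sample, via EBImage on a rescaled 1-row image
otsu_threshold <- function(vals) {
  rng <- range(vals)
  scaled <- (vals - rng[1L]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1L)),
                       range = c(0, 1), levels = 256L)
  rng[1L] + t01 * diff(rng)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally, then relabel contiguously in row-major scan order.
label_components_8 <- function(fg) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
    nr <- nrow(lab); nc <- ncol(lab)
    for (off in list(c(1L, 1L), c(1L, -1L))) {
      r1 <- seq_len(nr - 1L); c1 <- if (off[2L] > 0) seq_len(nc - 1L) else 2L:nc
      a <- lab[r1, c1, drop = FALSE]
      b <- lab[r1 + 1L, c1 + off[2L], drop = FALSE]
      hit <- which(a > 0L & b > 0L & a != b)
      if (length(hit)) {
        pairs <- unique(cbind(a[hit], b[hit]))
        for (i in seq_len(nrow(pairs))) union_(pairs[i, 1L], pairs[i, 2L])
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  relabel_scan_order(lab)
}

# contiguous labels ordered by first pixel in row-major scan order
relabel_scan_order <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ord <- order(rows, cols)
  first <- !duplicated(lab[idx][ord])
  remap <- integer(max(lab))
  remap[lab[idx][ord][first]] <- seq_len(sum(first))
  lab[idx] <- remap[lab[idx]]
  lab
}
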