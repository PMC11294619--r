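#' Mean grey level within a region of interest
#'
#' Arithmetic mean of pixel intensities inside the ROI mask — the optical
#' density readout used for regional immunostaining comparisons.
#'
#' @param image Numeric matrix.
#' @param roi_mask Logical matrix, same shape, non-empty.
#' @param region Region name carried into the result.
#' @return Object of class `region_measure`: region, mean_grey, n_pixels.
#' @export
mean_grey <- function(image, roi_mask, region = "roi") {
  roi_mask <- as_mask(roi_mask)
  if (!identical(dim(image), dim(roi_mask))) stop("image/ROI shape mismatch")
  n <- sum(roi_mask)
  if (n == 0L) stop("empty ROI")
  structure(list(region = region, mean_grey = mean(image[roi_mask]),
                 n_pixels = n),
            class = "region_measure")
}

#' Stained-surface ratio within a region of interest
#'
#' Fraction of ROI pixels at or above the stain threshold — the "surface"
#' readout of DAB immunostaining, expressed as a ratio of the total surface
#' of the area of interest. The threshold is a stored configuration value
#' meant to be applied unchanged to every image of a stain, so comparisons
#' across groups are made under identical settings.
#'
#' @param image Numeric matrix (inverted-brightfield convention: stain
#'   brighter than background).
#' @param roi_mask Logical matrix, same shape, non-empty.
#' @param threshold Stain-positive intensity threshold (pixels >= threshold
#'   count as stained).
#' @param region Region name carried into the result.
#' @return Object of class `region_measure`: region, surface_ratio in
#'   [0, 1], n_pixels.
#' @export
surface_fraction <- function(image, roi_mask, threshold, region = "roi") {
  roi_mask <- as_mask(roi_mask)
  if (!identical(dim(image), dim(roi_mask))) stop("image/ROI shape mismatch")
  n <- sum(roi_mask)
  if (n == 0L) stop("empty ROI")
  structure(list(region = region,
                 surface_ratio = sum(image[roi_mask] >= threshold) / n,
                 n_pixels = n),
            class = "region_measure")
}

#' Express values as a percentage of the control-group mean
#'
#' @param values Numeric vector of measurements.
#' @param control_values Numeric vector of control-group measurements with
#'   non-zero mean.
#' @return Numeric vector: 100 * values / mean(control_values).
#' @export
percent_of_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) stop("control mean is zero or undefined")
  100 * values / m
}

#' Mean elemental concentration over a region of interest
#'
#' @param map An `elemental_map`.
#' @param roi_mask Optional logical matrix (same shape as the map grid);
#'   NULL averages the whole map.
#' @param region Region name carried into the result.
#' @return Object of class `region_measure`: region, element, mean_ppm,
#'   n_pixels.
#' @export
roi_mean_concentration <- function(map, roi_mask = NULL, region = "roi") {
  stopifnot(inherits(map, "elemental_map"))
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(map$grid), ncol(map$grid))
  roi_mask <- as_mask(roi_mask)
  if (!identical(dim(map$grid), dim(roi_mask))) stop("map/ROI shape mismatch")
  n <- sum(roi_mask)
  if (n == 0L) stop("empty ROI")
  structure(list(region = region, element = map$element,
                 mean_ppm = mean(map$grid[roi_mask]), n_pixels = n),
            class = "region_measure")
}

#' @export
print.region_measure <- function(x, ...) {
  val <- x[setdiff(names(x), c("region", "element", "n_pixels"))]
  cat(sprintf("<region_measure> %s: %s = %.4g (%d px)\n", x$region,
              names(val)[1L], val[[1L]], x$n_pixels))
  invisible(x)
}
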