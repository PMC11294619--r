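#' Fit an ellipse to the nuclear ROI by moment matching
#'
#' Computes the ellipse whose second central moments match those of the
#' binary region: for a solid ellipse the variance along a principal axis is
#' (semi-axis)^2 / 4, so the semi-axes are 2 * sqrt(eigenvalues) of the
#' pixel-coordinate covariance. The mean radius — used as the nucleus
#' "average radius" when converting centre distances to border distances —
#' is (semi-major + semi-minor) / 2.
#'
#' @param nucleus_mask Logical matrix with at least 5 pixels set.
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @return Object of class `nucleus_ellipse`: list(centre_um (row, col),
#'   semi_major_um, semi_minor_um, orientation_rad, mean_radius_um).
#' @export
fit_nucleus_ellipse <- function(nucleus_mask, pixel_size_um) {
  nucleus_mask <- as_mask(nucleus_mask)
  idx <- which(nucleus_mask)
  if (length(idx) < 5L) stop("nucleus region must have >= 5 pixels")
  nr <- nrow(nucleus_mask)
  r_um <- px_centre_um((idx - 1L) %% nr + 1L, pixel_size_um)
  c_um <- px_centre_um((idx - 1L) %/% nr + 1L, pixel_size_um)
  centre <- c(mean(r_um), mean(c_um))
  # population covariance plus the within-pixel variance (px^2 / 12)
  n <- length(idx)
  dr <- r_um - centre[1L]; dc <- c_um - centre[2L]
  cov <- matrix(c(sum(dr * dr), sum(dr * dc), sum(dr * dc), sum(dc * dc)),
                2L, 2L) / n
  raw_ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(raw_ev) <= 1e-9 * max(raw_ev)) {
    stop("degenerate (collinear) nucleus region")
  }
  diag(cov) <- diag(cov) + pixel_size_um^2 / 12
  e <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(e$values[1L]); b <- 2 * sqrt(e$values[2L])
  structure(
    list(centre_um = centre, semi_major_um = a, semi_minor_um = b,
         orientation_rad = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
         mean_radius_um = (a + b) / 2),
    class = "nucleus_ellipse")
}

#' Distances from a punctum centroid to the nucleus centre and border
#'
#' The border distance is the centre distance minus the mean radius of the
#' fitted nuclear ellipse; it is negative when the centroid lies over the
#' nucleus.
#'
#' @param centroid_um Numeric pair (row, col) in micrometres.
#' @param ellipse A [fit_nucleus_ellipse()] result.
#' @return List: `dist_centre_um` (>= 0), `dist_border_um`.
#' @export
distance_to_nucleus <- function(centroid_um, ellipse) {
  stopifnot(inherits(ellipse, "nucleus_ellipse"))
  dc <- sqrt(sum((centroid_um - ellipse$centre_um)^2))
  list(dist_centre_um = dc, dist_border_um = dc - ellipse$mean_radius_um)
}
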