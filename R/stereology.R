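#' Optical-fractionator sampling design
#'
#' Bundles the sampling fractions of the optical fractionator: counting
#' frames of `frame_w_um` x `frame_h_um` placed on a systematic grid spaced
#' `grid_dx_um` x `grid_dy_um` (area sampling fraction asf = frame area /
#' grid-cell area), a 1-in-`section_period` section series (section sampling
#' fraction ssf = 1/period), and a thickness sampling fraction tsf (default
#' 1: planar counting with no guard zones). Defaults follow a standard
#' primate nigral design: 100 x 80 um frames spaced 600 x 400 um, 1-in-12
#' sections, giving an overall multiplier of 1/(ssf * asf) = 12 * 30 = 360.
#'
#' @param frame_w_um,frame_h_um Counting-frame width and height, um.
#' @param grid_dx_um,grid_dy_um Grid spacing, um; must be >= frame size.
#' @param section_period Sections sampled 1 in every `section_period`.
#' @param tsf Thickness sampling fraction in (0, 1].
#' @return Object of class `stereology_design` with derived `asf` and `ssf`.
#' @export
stereology_design <- function(frame_w_um = 100, frame_h_um = 80,
                              grid_dx_um = 600, grid_dy_um = 400,
                              section_period = 12L, tsf = 1.0) {
  if (frame_w_um <= 0 || frame_h_um <= 0) stop("frame dimensions must be > 0")
  if (grid_dx_um < frame_w_um || grid_dy_um < frame_h_um) {
    stop("grid spacing must be at least the frame size")
  }
  section_period <- as.integer(section_period)
  if (section_period < 1L) stop("section_period must be >= 1")
  if (tsf <= 0 || tsf > 1) stop("tsf must lie in (0, 1]")
  asf <- (frame_w_um * frame_h_um) / (grid_dx_um * grid_dy_um)
  structure(
    list(frame_w_um = frame_w_um, frame_h_um = frame_h_um,
         grid_dx_um = grid_dx_um, grid_dy_um = grid_dy_um,
         section_period = section_period,
         asf = asf, ssf = 1 / section_period, tsf = tsf),
    class = "stereology_design")
}

#' @export
print.stereology_design <- function(x, ...) {
  cat(sprintf(
    "<stereology_design> frame %g x %g um on %g x %g um grid (asf %.4g); 1-in-%d sections (ssf %.4g); tsf %g; multiplier %.4g\n",
    x$frame_w_um, x$frame_h_um, x$grid_dx_um, x$grid_dy_um, x$asf,
    x$section_period, x$ssf, x$tsf, 1 / (x$ssf * x$asf * x$tsf)))
  invisible(x)
}

#' Place a systematic grid of counting frames over a region
#'
#' Frames sit at `grid_offset + k * (dx, dy)`; a frame belongs to the layout
#' when its origin (lower-left corner) falls inside the region bounds, so a
#' region of exactly one grid cell always carries exactly one frame. The
#' offset is drawn uniformly at random within one grid cell (systematic
#' uniform random sampling) when not supplied.
#'
#' @param region_bounds_um Numeric pair (width, height) of the region, um.
#' @param design A [stereology_design].
#' @param offset_um Optional numeric pair in [0, dx) x [0, dy); drawn from
#'   the current RNG state when NULL.
#' @return data.frame of frame rectangles: x0, y0, w, h (um).
#' @export
place_sampling_grid <- function(region_bounds_um, design, offset_um = NULL) {
  stopifnot(inherits(design, "stereology_design"))
  W <- region_bounds_um[1L]; H <- region_bounds_um[2L]
  if (W < design$frame_w_um || H < design$frame_h_um) {
    stop("region smaller than one counting frame")
  }
  if (is.null(offset_um)) {
    offset_um <- c(stats::runif(1, 0, design$grid_dx_um),
                   stats::runif(1, 0, design$grid_dy_um))
  }
  x0 <- seq(offset_um[1L], W, by = design$grid_dx_um)
  y0 <- seq(offset_um[2L], H, by = design$grid_dy_um)
  x0 <- x0[x0 < W]; y0 <- y0[y0 < H]
  g <- expand.grid(x0 = x0, y0 = y0)
  g$w <- design$frame_w_um; g$h <- design$frame_h_um
  g
}

#' Count points in an unbiased counting frame
#'
#' Applies the forbidden-line rule: a point is counted when it lies strictly
#' inside the frame or on the inclusion edges (top and right); points on the
#' exclusion edges (left and bottom, with their extensions) are not counted.
#' Tiling the plane with abutting frames under this rule counts every point
#' exactly once.
#'
#' @param points_um Matrix or data.frame with columns x, y (um).
#' @param frame Numeric: x0, y0, w, h (one frame rectangle).
#' @return Integer count.
#' @export
count_frame <- function(points_um, frame) {
  if (NROW(points_um) == 0L) return(0L)
  x <- points_um[, 1L]; y <- points_um[, 2L]
  x0 <- frame[[1L]]; y0 <- frame[[2L]]; w <- frame[[3L]]; h <- frame[[4L]]
  sum(x > x0 & x <= x0 + w & y > y0 & y <= y0 + h)
}

#' Optical-fractionator total estimate from a raw count
#'
#' N_hat = sum_Q / (ssf * asf * tsf): the total count over sampled frames
#' scaled up by the inverse sampling fractions.
#'
#' @param sum_Q Total number of counted cells over all sampled frames (>= 0).
#' @param design A [stereology_design].
#' @param per_section_counts Optional integer vector of per-section counts.
#' @return Object of class `stereology_estimate`: sum_Q, n_hat,
#'   per_section_counts.
#' @export
fractionator_estimate <- function(sum_Q, design, per_section_counts = NULL) {
  stopifnot(inherits(design, "stereology_design"))
  if (sum_Q < 0) stop("sum_Q must be >= 0")
  f <- design$ssf * design$asf * design$tsf
  if (f <= 0) stop("zero sampling fraction")
  structure(
    list(sum_Q = sum_Q, n_hat = sum_Q / f,
         per_section_counts = per_section_counts, design = design),
    class = "stereology_estimate")
}

#' @export
print.stereology_estimate <- function(x, ...) {
  cat(sprintf("<stereology_estimate> sum_Q = %d -> N_hat = %.1f\n",
              as.integer(x$sum_Q), x$n_hat))
  invisible(x)
}

#' Run the optical fractionator over a sampled section series
#'
#' For each sampled section a fresh uniform-random grid offset is drawn and
#' the section's neuron reference points are counted in all frames under
#' the unbiased-counting-frame rule; counts are accumulated over sampled
#' sections only and scaled by the inverse sampling fractions.
#'
#' @param series A `section_series` from [generate_neuron_field()].
#' @param design A [stereology_design]; its `section_period` should match
#'   the series' sampling period for the ssf to be correct.
#' @param seed Integer seed controlling the per-section grid offsets.
#' @return A `stereology_estimate` with per-section counts.
#' @export
run_stereology <- function(series, design, seed) {
  stopifnot(inherits(series, "section_series"),
            inherits(design, "stereology_design"))
  sampled <- which(series$sampled)
  if (length(sampled) == 0L) stop("no sampled sections in the series")
  set.seed(as.integer(seed))
  W <- series$region_size_um[1L]; H <- series$region_size_um[2L]
  per_section <- integer(length(sampled))
  for (i in seq_along(sampled)) {
    ox <- stats::runif(1, 0, design$grid_dx_um)
    oy <- stats::runif(1, 0, design$grid_dy_um)
    pts <- series$points[series$points$section == sampled[i], , drop = FALSE]
    if (nrow(pts) == 0L) next
    # frame of each point under the periodic grid; counted when that
    # frame's origin lies in the region and the point passes the edge rule
    kx <- floor((pts$x_um - ox) / design$grid_dx_um)
    ky <- floor((pts$y_um - oy) / design$grid_dy_um)
    fx <- ox + kx * design$grid_dx_um
    fy <- oy + ky * design$grid_dy_um
    counted <- fx >= 0 & fx < W & fy >= 0 & fy < H &
      pts$x_um > fx & pts$x_um <= fx + design$frame_w_um &
      pts$y_um > fy & pts$y_um <= fy + design$frame_h_um
    per_section[i] <- sum(counted)
  }
  names(per_section) <- sampled
  fractionator_estimate(sum(per_section), design,
                        per_section_counts = per_section)
}
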