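#' Generate a synthetic elemental concentration map
#'
#' Emulates a raster-scanned X-ray fluorescence elemental map: a grid of
#' per-pixel concentrations (ppm, i.e. micrograms per gram of dry weight)
#' drawn i.i.d. normal around a mean, truncated at zero (concentrations are
#' non-negative). The physical extent of the map is grid_shape * step_um,
#' e.g. a 100 x 100 grid at a 5 um step covers 500 x 500 um.
#'
#' @param grid_shape Integer pair (rows, cols).
#' @param step_um Scan step (= beam size) in micrometres, > 0.
#' @param mean_ppm Mean concentration, >= 0.
#' @param sd_ppm Per-pixel SD of the concentration, >= 0.
#' @param seed Integer seed.
#' @param element Element name carried in the map metadata.
#' @return Object of class `elemental_map`: list(element, grid, step_um).
#' @export
generate_elemental_map <- function(grid_shape, step_um, mean_ppm, sd_ppm,
                                   seed, element = "Fe") {
  if (mean_ppm < 0) stop("mean_ppm must be >= 0")
  if (sd_ppm < 0) stop("sd_ppm must be >= 0")
  if (step_um <= 0) stop("step_um must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1L)) stop("grid_shape must be positive")
  set.seed(as.integer(seed))
  g <- matrix(stats::rnorm(prod(grid_shape), mean_ppm, sd_ppm),
              grid_shape[1L], grid_shape[2L])
  g[g < 0] <- 0
  structure(list(element = element, grid = g, step_um = step_um),
            class = "elemental_map")
}

#' Physical extent of an elemental map
#'
#' @param map An `elemental_map`.
#' @return Numeric pair: (rows, cols) extent in micrometres.
#' @export
map_extent_um <- function(map) {
  stopifnot(inherits(map, "elemental_map"))
  dim(map$grid) * map$step_um
}

#' @export
print.elemental_map <- function(x, ...) {
  ext <- map_extent_um(x)
  cat(sprintf("<elemental_map> %s: %d x %d px @ %g um -> %g x %g um; mean %.1f ppm\n",
              x$element, nrow(x$grid), ncol(x$grid), x$step_um,
              ext[1L], ext[2L], mean(x$grid)))
  invisible(x)
}
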