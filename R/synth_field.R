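#' Generate a sectioned 3-D neuron field with known total count
#'
#' Places `n_neurons` reference points (nucleolus proxies) uniformly at
#' random in a cuboidal tissue region, slices the region into consecutive
#' serial sections of the stated thickness along z, and marks every
#' `section_period`-th section as sampled, starting at a random phase
#' (systematic uniform random sampling of sections). Each neuron belongs to
#' exactly one section: the section containing its reference point. This is
#' the test bed for the optical-fractionator estimator.
#'
#' @param region_size_um Numeric triple (x, y, z extents in micrometres),
#'   all strictly positive.
#' @param n_neurons Number of neurons to place (>= 0).
#' @param section_thickness_um Section thickness in micrometres (> 0).
#' @param section_period Sample 1 section in every `section_period` (>= 1).
#' @param seed Integer seed controlling placement and the sampling phase.
#' @return List with `series` (class `section_series`: per-neuron points with
#'   section assignment, per-section sampled flags, region geometry) and
#'   `truth` (list with `true_neuron_count`).
#' @export
generate_neuron_field <- function(region_size_um, n_neurons,
                                  section_thickness_um, section_period,
                                  seed) {
  if (length(region_size_um) != 3L || any(region_size_um <= 0)) {
    stop("region_size_um must be three strictly positive extents")
  }
  if (n_neurons < 0L) stop("n_neurons must be >= 0")
  if (section_thickness_um <= 0) stop("section thickness must be > 0")
  section_period <- as.integer(section_period)
  if (section_period < 1L) stop("section_period must be >= 1")
  set.seed(as.integer(seed))

  n_sections <- as.integer(ceiling(region_size_um[3L] / section_thickness_um))
  x <- stats::runif(n_neurons, 0, region_size_um[1L])
  y <- stats::runif(n_neurons, 0, region_size_um[2L])
  z <- stats::runif(n_neurons, 0, region_size_um[3L])
  section <- pmin(floor(z / section_thickness_um) + 1L, n_sections)

  phase <- sample.int(section_period, 1L)
  sampled <- rep(FALSE, n_sections)
  sampled[seq(phase, n_sections, by = section_period)] <- TRUE

  series <- structure(
    list(points = data.frame(x_um = x, y_um = y, z_um = z,
                             section = as.integer(section)),
         n_sections = n_sections,
         section_thickness_um = section_thickness_um,
         section_period = section_period,
         sampling_phase = phase,
         sampled = sampled,
         region_size_um = region_size_um),
    class = "section_series")
  list(series = series, truth = list(true_neuron_count = as.integer(n_neurons)))
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf(
    "<section_series> %d neurons in %.0f x %.0f x %.0f um; %d sections (%g um), 1-in-%d sampled (phase %d)\n",
    nrow(x$points), x$region_size_um[1L], x$region_size_um[2L],
    x$region_size_um[3L], x$n_sections, x$section_thickness_um,
    x$section_period, x$sampling_phase))
  invisible(x)
}
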