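#' Generate a synthetic DAB-like image with a known stained-surface fraction
#'
#' Produces a single-channel image in which an exactly known fraction of the
#' pixels carries the stain level, arranged as smooth blobs rather than salt
#' and pepper: a Gaussian-smoothed random field is thresholded at its k-th
#' largest value, where k = round(surface_fraction * n_pixels), so the
#' stained area is exact to one pixel. Intensities follow an
#' inverted-brightfield convention (stain brighter than background); optional
#' additive Gaussian noise.
#'
#' @param size_px Integer pair (rows, cols).
#' @param surface_fraction Target stained fraction in [0, 1].
#' @param stain_level Intensity of stained pixels (> background_level).
#' @param background_level Intensity of unstained pixels.
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @param blob_sigma_px Smoothing sigma of the latent field, in pixels;
#'   larger values give larger stained blobs.
#' @return List with `image` (numeric matrix) and `truth` (list:
#'   `true_surface_fraction` as requested, `achieved_fraction` = k/n after
#'   pixel quantisation, `stain_mask` logical matrix).
#' @export
generate_dab_image <- function(size_px, surface_fraction, stain_level,
                               background_level, noise_sd, seed,
                               blob_sigma_px = 4) {
  if (surface_fraction < 0 || surface_fraction > 1) {
    stop("surface_fraction must lie in [0, 1]")
  }
  if (stain_level <= background_level) {
    stop("stain_level must exceed background_level")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  size_px <- as.integer(size_px)
  n <- prod(size_px)
  k <- round(surface_fraction * n)

  stain <- matrix(FALSE, size_px[1L], size_px[2L])
  if (k >= n) {
    stain[] <- TRUE
  } else if (k > 0L) {
    latent <- matrix(stats::rnorm(n), size_px[1L], size_px[2L])
    latent <- EBImage::imageData(EBImage::gblur(EBImage::Image(latent),
                                       sigma = blob_sigma_px))
    cut <- sort(as.numeric(latent), decreasing = TRUE)[k]
    stain <- latent >= cut
    # continuous field: ties have measure zero, but guard anyway
    if (sum(stain) != k) {
      ord <- order(latent, decreasing = TRUE)
      stain[] <- FALSE
      stain[ord[seq_len(k)]] <- TRUE
    }
  }
  img <- matrix(background_level, size_px[1L], size_px[2L])
  img[stain] <- stain_level
  if (noise_sd > 0) img <- img + stats::rnorm(n, 0, noise_sd)
  list(image = img,
       truth = list(true_surface_fraction = surface_fraction,
                    achieved_fraction = sum(stain) / n,
                    stain_mask = stain))
}
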