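#' Parameters for the synthetic single-cell image generator
#'
#' Bundles the geometry, puncta layout and noise model of one synthetic
#' neuron image. The soma and nucleus are (optionally rotated) ellipses; the
#' nucleus must lie strictly inside the soma. Puncta are placed in the
#' cytoplasm with a controlled perinuclear/cytosolic split: perinuclear
#' centres lie within `perinuclear_band_um` of the nucleus border, cytosolic
#' centres lie farther out but inside the soma.
#'
#' @param image_size_px Integer pair, image dimension in pixels (rows, cols).
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @param soma_centre_px,soma_axes_px Soma ellipse centre and semi-axes, px.
#' @param nucleus_centre_px,nucleus_axes_px Nucleus ellipse centre and
#'   semi-axes, px; the rasterised nucleus must be strictly inside the soma.
#' @param n_perinuclear,n_cytosolic Number of puncta to place in each
#'   compartment (non-negative integers).
#' @param punctum_radius_um True punctum radius in micrometres (> 0); must be
#'   smaller than `perinuclear_band_um` so placement margins are feasible.
#' @param punctum_intensity Peak intensity of a punctum above background.
#' @param background_level Uniform background intensity (>= 0).
#' @param gaussian_noise_sd Additive Gaussian read-noise SD (>= 0).
#' @param poisson_noise Apply Poisson shot noise to the signal first?
#' @param perinuclear_band_um Width of the perinuclear band, micrometres.
#' @param cell_fill_intensity Intensity of the cell-marker channel inside the
#'   soma, above background.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A validated list of class `cell_image_params`.
#' @export
cell_image_params <- function(image_size_px = c(300L, 300L),
                              pixel_size_um = 0.1,
                              soma_centre_px = c(150, 150),
                              soma_axes_px = c(120, 100),
                              nucleus_centre_px = c(150, 140),
                              nucleus_axes_px = c(50, 40),
                              n_perinuclear = 10L,
                              n_cytosolic = 5L,
                              punctum_radius_um = 0.5,
                              punctum_intensity = 100,
                              background_level = 10,
                              gaussian_noise_sd = 0,
                              poisson_noise = FALSE,
                              perinuclear_band_um = 2,
                              cell_fill_intensity = 50,
                              seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_size_um = pixel_size_um,
            soma_centre_px = soma_centre_px, soma_axes_px = soma_axes_px,
            nucleus_centre_px = nucleus_centre_px,
            nucleus_axes_px = nucleus_axes_px,
            n_perinuclear = as.integer(n_perinuclear),
            n_cytosolic = as.integer(n_cytosolic),
            punctum_radius_um = punctum_radius_um,
            punctum_intensity = punctum_intensity,
            background_level = background_level,
            gaussian_noise_sd = gaussian_noise_sd,
            poisson_noise = isTRUE(poisson_noise),
            perinuclear_band_um = perinuclear_band_um,
            cell_fill_intensity = cell_fill_intensity,
            seed = as.integer(seed))
  if (any(p$image_size_px < 8L)) stop("image too small")
  if (p$pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (p$n_perinuclear < 0L || p$n_cytosolic < 0L) {
    stop("puncta counts must be non-negative")
  }
  if (p$punctum_radius_um <= 0) stop("punctum_radius_um must be > 0")
  if (p$punctum_radius_um >= p$perinuclear_band_um) {
    stop("punctum radius must be smaller than the perinuclear band width")
  }
  if (p$punctum_intensity <= p$background_level) {
    stop("punctum_intensity must exceed background_level")
  }
  if (p$background_level < 0 || p$gaussian_noise_sd < 0) {
    stop("background and noise SD must be non-negative")
  }
  class(p) <- "cell_image_params"
  p
}

# rasterise an axis pair/centre ellipse on an nr x nc grid (1-based indices)
rasterise_ellipse <- function(size_px, centre, axes, theta = 0) {
  r <- matrix(seq_len(size_px[1L]), size_px[1L], size_px[2L])
  c_ <- matrix(seq_len(size_px[2L]), size_px[1L], size_px[2L], byrow = TRUE)
  dr <- r - centre[1L]; dc <- c_ - centre[2L]
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  (u / axes[1L])^2 + (v / axes[2L])^2 <= 1
}

#' Generate a synthetic single-cell image with catalogued puncta
#'
#' Renders a two-channel fluorescence image of one neuron: a cell-marker
#' channel filling the soma ellipse and a puncta channel containing
#' Gaussian-profile spots (sigma = radius/2, truncated at 3 sigma) at
#' catalogued positions, over a uniform background, with optional
#' Poisson-then-Gaussian camera noise. Returns the image with its soma and
#' nucleus masks plus the ground-truth puncta catalogue.
#'
#' Placement is by rejection sampling (at most 1000 retries per punctum) on
#' pixels that (i) lie in the cytoplasm at least one punctum radius from the
#' soma border, (ii) fall clearly on the intended side of the perinuclear
#' band (a two-pixel class margin keeps ground-truth compartments
#' unambiguous under centroid-based assignment), and (iii) keep a
#' centre-to-centre distance of at least 2.5 radii from all other puncta so
#' that noiseless detection is unambiguous.
#'
#' @param params A [cell_image_params] object.
#' @return List with elements `image` (an [annotated_image] with channels
#'   `cell` and `puncta`) and `truth` (list: `puncta_catalog` data frame with
#'   columns label, centre_row_um, centre_col_um, radius_um, compartment;
#'   plus the generating parameters).
#' @export
generate_cell_image <- function(params) {
  stopifnot(inherits(params, "cell_image_params"))
  p <- params
  set.seed(p$seed)
  sz <- p$image_size_px
  px <- p$pixel_size_um

  soma <- rasterise_ellipse(sz, p$soma_centre_px, p$soma_axes_px)
  nucleus <- rasterise_ellipse(sz, p$nucleus_centre_px, p$nucleus_axes_px)
  if (!all(soma[nucleus])) stop("nucleus ellipse not inside soma ellipse")
  if (sum(nucleus) == 0L) stop("nucleus rasterises to zero pixels")

  # distances in um: to the nucleus region and to the soma border
  d_nuc <- as.numeric(EBImage::distmap(!nucleus)) * px
  d_edge <- as.numeric(EBImage::distmap(soma)) * px
  dim(d_nuc) <- dim(d_edge) <- sz
  cyto <- soma & !nucleus

  margin <- 2 * px  # class margin: centroid rounding cannot flip compartment
  r_um <- p$punctum_radius_um
  fit <- cyto & d_edge >= r_um + px
  cand_peri <- which(fit & d_nuc <= p$perinuclear_band_um - margin)
  cand_cyto <- which(fit & d_nuc > p$perinuclear_band_um + margin)

  placed <- matrix(numeric(0), ncol = 2)  # centres in um (row, col)
  compartments <- character(0)
  min_sep <- 2.5 * r_um
  place_in <- function(cand, compartment, n) {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        if (length(cand) == 0L) break
        k <- cand[sample.int(length(cand), 1L)]
        rc <- c((k - 1L) %% sz[1L] + 1L, (k - 1L) %/% sz[1L] + 1L)
        ctr <- px_centre_um(rc, px)
        if (nrow(placed) == 0L ||
            min(sqrt(rowSums(sweep(placed, 2, ctr)^2))) >= min_sep) {
          placed <<- rbind(placed, ctr)
          compartments <<- c(compartments, compartment)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "placement failure in the %s compartment: could not place punctum %d of %d within 1000 retries",
          compartment, i, n))
      }
    }
  }
  place_in(cand_peri, "perinuclear", p$n_perinuclear)
  place_in(cand_cyto, "cytosolic", p$n_cytosolic)

  # render puncta: isotropic Gaussian spots, sigma = r/2, truncated at 3 sigma
  puncta_ch <- matrix(p$background_level, sz[1L], sz[2L])
  sigma <- r_um / 2
  w_px <- ceiling(3 * sigma / px)
  if (nrow(placed) > 0L) {
    for (i in seq_len(nrow(placed))) {
      ctr <- placed[i, ]
      rc <- um_to_px(ctr, px)
      rows <- max(1L, rc[1L] - w_px):min(sz[1L], rc[1L] + w_px)
      cols <- max(1L, rc[2L] - w_px):min(sz[2L], rc[2L] + w_px)
      dr <- px_centre_um(rows, px) - ctr[1L]
      dc <- px_centre_um(cols, px) - ctr[2L]
      d2 <- outer(dr^2, dc^2, "+")
      spot <- p$punctum_intensity * exp(-d2 / (2 * sigma^2))
      spot[d2 > (3 * sigma)^2] <- 0
      puncta_ch[rows, cols] <- puncta_ch[rows, cols] + spot
    }
  }
  cell_ch <- matrix(p$background_level, sz[1L], sz[2L])
  cell_ch[soma] <- cell_ch[soma] + p$cell_fill_intensity

  add_noise <- function(ch) {
    if (p$poisson_noise) ch[] <- stats::rpois(length(ch), lambda = pmax(ch, 0))
    if (p$gaussian_noise_sd > 0) {
      ch <- ch + stats::rnorm(length(ch), 0, p$gaussian_noise_sd)
    }
    ch
  }
  puncta_ch <- add_noise(puncta_ch)
  cell_ch <- add_noise(cell_ch)

  catalog <- data.frame(
    label = seq_len(nrow(placed)),
    centre_row_um = if (nrow(placed)) placed[, 1L] else numeric(0),
    centre_col_um = if (nrow(placed)) placed[, 2L] else numeric(0),
    radius_um = rep(r_um, nrow(placed)),
    compartment = compartments,
    stringsAsFactors = FALSE)

  img <- annotated_image(
    channels = list(cell = cell_ch, puncta = puncta_ch),
    pixel_size_um = px, soma_mask = soma, nucleus_mask = nucleus,
    cell_id = sprintf("synthetic_seed%d", p$seed))
  truth <- list(puncta_catalog = catalog,
                n_perinuclear = p$n_perinuclear,
                n_cytosolic = p$n_cytosolic,
                params = p)
  list(image = img, truth = truth)
}
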