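#' Annotated multi-channel cell image
#'
#' Container for a 2-D multi-channel fluorescence acquisition of a single
#' labelled neuron, together with its manually drawn soma and nucleus masks
#' and the physical pixel size. All grids share one shape; the nucleus mask
#' must be contained in the soma mask. Pixel (r, c) (1-based matrix indices)
#' is centred at physical position ((r - 0.5), (c - 0.5)) * pixel_size_um.
#'
#' @param channels Named list of numeric matrices (intensity grids), all of
#'   identical dimension.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @param soma_mask Logical or 0/1 matrix marking the soma (whole-cell) ROI.
#' @param nucleus_mask Logical or 0/1 matrix marking the nuclear ROI; must be
#'   a subset of `soma_mask`.
#' @param z_plane_id Identifier of the z-plane the masks were drawn on.
#' @param cell_id Identifier of the cell.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(channels, pixel_size_um, soma_mask, nucleus_mask,
                            z_plane_id = "z0", cell_id = "cell") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) stop("all channels must share one shape")
  soma_mask <- as_mask(soma_mask)
  nucleus_mask <- as_mask(nucleus_mask)
  if (!identical(dim(soma_mask), dim(channels[[1L]])) ||
      !identical(dim(nucleus_mask), dim(channels[[1L]]))) {
    stop("masks must match channel dimensions")
  }
  if (any(nucleus_mask & !soma_mask)) {
    stop("nucleus mask must be contained in the soma mask")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         soma_mask = soma_mask, nucleus_mask = nucleus_mask,
         z_plane_id = z_plane_id, cell_id = cell_id),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf(
    "<annotated_image> %s: %d x %d px @ %.3g um/px; channels: %s\n",
    x$cell_id, d[1L], d[2L], x$pixel_size_um,
    paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  soma %d px, nucleus %d px\n",
              sum(x$soma_mask), sum(x$nucleus_mask)))
  invisible(x)
}

# coerce to logical matrix, preserving dim
as_mask <- function(m) {
  if (is.null(dim(m)) || length(dim(m)) != 2L) stop("mask must be a matrix")
  mode(m) <- "logical"
  m
}

#' Apply the soma mask to an image channel
#'
#' Zeroes every pixel outside the cell mask, leaving pixels inside unchanged.
#' This restricts downstream puncta detection to the labelled neuron.
#'
#' @param image An [annotated_image].
#' @param channel Name of the channel to mask.
#' @return Numeric matrix with out-of-soma pixels set to zero.
#' @export
apply_cell_mask <- function(image, channel) {
  stopifnot(inherits(image, "annotated_image"))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(names(image$channels), collapse = ", ")))
  }
  g <- image$channels[[channel]]
  g[!image$soma_mask] <- 0
  g
}

# physical centre (um) of 1-based pixel indices
px_centre_um <- function(idx, pixel_size_um) (idx - 0.5) * pixel_size_um

# 1-based pixel index containing a physical position (um)
um_to_px <- function(u, pixel_size_um) floor(u / pixel_size_um) + 1L
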