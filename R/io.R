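#' Write an annotated image to multi-page TIFF with a JSON sidecar
#'
#' Channels are written as one multi-page 32-bit float TIFF (one page per
#' channel, intensities rescaled to [0, 1] with the scale recorded in the
#' sidecar), masks as 8-bit label TIFFs, and the metadata (pixel size,
#' channel names and scale, identifiers) as a JSON sidecar next to them.
#'
#' @param image An [annotated_image].
#' @param path_prefix Output path prefix; files `<prefix>_channels.tif`,
#'   `<prefix>_soma.tif`, `<prefix>_nucleus.tif`, `<prefix>.json` are
#'   written.
#' @return The sidecar path, invisibly.
#' @export
write_annotated_image <- function(image, path_prefix) {
  stopifnot(inherits(image, "annotated_image"))
  lo <- min(vapply(image$channels, min, numeric(1)))
  hi <- max(vapply(image$channels, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(image$channels, function(ch) (ch - lo) / scale)
  tiff::writeTIFF(unname(pages), paste0(path_prefix, "_channels.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(image$soma_mask * 1, paste0(path_prefix, "_soma.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(image$nucleus_mask * 1, paste0(path_prefix, "_nucleus.tif"),
                  bits.per.sample = 8L)
  sidecar <- paste0(path_prefix, ".json")
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um,
         channel_names = names(image$channels),
         intensity_offset = lo, intensity_scale = scale,
         z_plane_id = image$z_plane_id, cell_id = image$cell_id),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an annotated image written by [write_annotated_image()]
#'
#' @param path_prefix The prefix used at write time.
#' @return An [annotated_image].
#' @export
read_annotated_image <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path_prefix, "_channels.tif"), all = TRUE)
  channels <- lapply(pages, function(p) {
    p * meta$intensity_scale + meta$intensity_offset
  })
  names(channels) <- meta$channel_names
  soma <- tiff::readTIFF(paste0(path_prefix, "_soma.tif")) > 0
  nucleus <- tiff::readTIFF(paste0(path_prefix, "_nucleus.tif")) > 0
  annotated_image(channels, meta$pixel_size_um, soma, nucleus,
                  z_plane_id = meta$z_plane_id, cell_id = meta$cell_id)
}

#' Write / read a long measurement table (group, hemisphere, variable, value)
#'
#' @param table data.frame with the four canonical columns.
#' @param path CSV path.
#' @return `read_measurement_table` returns the validated data.frame.
#' @export
write_measurement_table <- function(table, path) {
  need <- c("group", "hemisphere", "variable", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns group, hemisphere, variable, value")
  }
  utils::write.csv(table[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "hemisphere", "variable", "value")
  if (!all(need %in% names(tab))) {
    stop(sprintf("%s lacks the columns group, hemisphere, variable, value", path))
  }
  tab
}

#' Write / read a ground-truth catalogue as JSON
#'
#' @param truth Ground-truth list from a generator.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
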