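#' Per-cell puncta metrics by compartment
#'
#' Assigns each detected punctum to a compartment by the membership of its
#' centre of mass (a punctum straddling the band belongs to the compartment
#' containing its centroid) and summarises counts, mean puncta area and
#' total stained area per cell. The whole-cell count always equals the sum
#' of the perinuclear and cytosolic counts; mean areas of empty compartments
#' are reported as missing (NA), never as zero.
#'
#' @param records Puncta records data frame from [detect_puncta()].
#' @param compartments A [partition_compartments()] result.
#' @param cell_id,channel Identifiers carried into the output row.
#' @param qc Optional [qc_ratio_filter()] result to carry into the row.
#' @return One-row data.frame: cell_id, channel, qc_ratio, qc_pass, n_whole,
#'   n_peri, n_cyto, mean_area_whole, mean_area_peri, mean_area_cyto,
#'   total_area (areas in um^2). The punctum-level compartment assignment is
#'   attached as attribute `"compartment"`.
#' @export
puncta_metrics <- function(records, compartments, cell_id = "cell",
                           channel = "puncta", qc = NULL) {
  stopifnot(inherits(compartments, "compartment_masks"))
  px <- compartments$pixel_size_um
  n <- nrow(records)
  comp <- character(n)
  if (n > 0L) {
    r_idx <- um_to_px(records$centroid_row_um, px)
    c_idx <- um_to_px(records$centroid_col_um, px)
    dims <- dim(compartments$whole_cell)
    if (any(r_idx < 1L | r_idx > dims[1L] | c_idx < 1L | c_idx > dims[2L])) {
      stop("punctum centroid outside the image: masking bug upstream")
    }
    lin <- cbind(r_idx, c_idx)
    inside <- compartments$whole_cell[lin]
    if (!all(inside)) stop("punctum centroid outside the whole-cell mask: masking bug upstream")
    # a centroid overlying the nucleus has distance 0 to it, hence perinuclear;
    # this keeps whole-cell = perinuclear + cytosolic an exact identity
    comp <- ifelse(compartments$cytosolic[lin], "cytosolic", "perinuclear")
  }
  peri <- comp == "perinuclear"; cyto <- comp == "cytosolic"
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  out <- data.frame(
    cell_id = cell_id, channel = channel,
    qc_ratio = if (is.null(qc)) NA_real_ else qc$qc_ratio,
    qc_pass = if (is.null(qc)) NA else qc$qc_pass,
    n_whole = n, n_peri = sum(peri), n_cyto = sum(cyto),
    mean_area_whole = mean_or_na(records$area_um2),
    mean_area_peri = mean_or_na(records$area_um2[peri]),
    mean_area_cyto = mean_or_na(records$area_um2[cyto]),
    total_area = sum(records$area_um2),
    stringsAsFactors = FALSE)
  attr(out, "compartment") <- comp
  out
}

#' Run the full per-cell puncta pipeline over a set of annotated images
#'
#' For each cell: the QC area-ratio filter is applied first (excluded cells
#' are logged with a reason, not silently dropped); the soma mask is applied
#' to the requested channel; puncta are detected, compartments partitioned,
#' per-cell metrics computed, and per-punctum distances to the nucleus
#' centre/border derived from the moment-fitted nuclear ellipse. Images with
#' missing masks produce a logged per-image error and the pipeline continues.
#'
#' @param images List of [annotated_image] objects.
#' @param channel Channel to quantify.
#' @param threshold_method,threshold_value,min_area_px,smooth_sigma_px
#'   Passed to [detect_puncta()].
#' @param perinuclear_band_um Band width for [partition_compartments()].
#' @param min_ratio QC minimum cytoplasm:nucleus area ratio.
#' @param metadata Optional data.frame(cell_id, group, hemisphere); when
#'   given, a per-hemisphere summary (mean over passing cells) is returned.
#' @return List of class `puncta_pipeline_result`: `metrics` (one row per
#'   passing cell), `puncta` (per-punctum table with compartments and
#'   distances), `exclusions` (cell_id, reason), and `summary` (per
#'   hemisphere, when metadata given).
#' @export
run_puncta_pipeline <- function(images, channel = "puncta",
                                threshold_method = "otsu",
                                threshold_value = NULL,
                                min_area_px = 2L, smooth_sigma_px = 1,
                                perinuclear_band_um = 2,
                                min_ratio = 2.0, metadata = NULL) {
  metrics <- list(); puncta <- list(); excl <- list()
  for (img in images) {
    cid <- if (inherits(img, "annotated_image")) img$cell_id else "<invalid>"
    if (!inherits(img, "annotated_image") ||
        is.null(img$soma_mask) || is.null(img$nucleus_mask)) {
      excl[[length(excl) + 1L]] <- data.frame(cell_id = cid,
                                              reason = "missing masks")
      next
    }
    res <- tryCatch({
      qc <- qc_ratio_filter(img$soma_mask, img$nucleus_mask, min_ratio)
      if (!qc$qc_pass) {
        excl[[length(excl) + 1L]] <- data.frame(
          cell_id = cid,
          reason = sprintf("QC fail: cytoplasm:nucleus ratio %.3f < %.2f",
                           qc$qc_ratio, min_ratio))
        NULL
      } else {
        g <- apply_cell_mask(img, channel)
        det <- detect_puncta(g, img$pixel_size_um,
                             threshold_method = threshold_method,
                             threshold_value = threshold_value,
                             min_area_px = min_area_px,
                             mask = img$soma_mask,
                             smooth_sigma_px = smooth_sigma_px)
        cmp <- partition_compartments(img$soma_mask, img$nucleus_mask,
                                      img$pixel_size_um, perinuclear_band_um)
        row <- puncta_metrics(det$records, cmp, cell_id = cid,
                              channel = channel, qc = qc)
        per <- det$records
        if (nrow(per) > 0L) {
          ell <- fit_nucleus_ellipse(img$nucleus_mask, img$pixel_size_um)
          dd <- t(vapply(seq_len(nrow(per)), function(i) {
            d <- distance_to_nucleus(c(per$centroid_row_um[i],
                                       per$centroid_col_um[i]), ell)
            c(d$dist_centre_um, d$dist_border_um)
          }, numeric(2)))
          per$compartment <- attr(row, "compartment")
          per$dist_to_nucleus_centre_um <- dd[, 1L]
          per$dist_to_nucleus_border_um <- dd[, 2L]
        } else {
          per$compartment <- character(0)
          per$dist_to_nucleus_centre_um <- numeric(0)
          per$dist_to_nucleus_border_um <- numeric(0)
        }
        per <- cbind(cell_id = rep(cid, nrow(per)), per)
        list(row = row, per = per)
      }
    }, error = function(e) {
      excl[[length(excl) + 1L]] <<- data.frame(
        cell_id = cid, reason = paste("error:", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      metrics[[length(metrics) + 1L]] <- res$row
      puncta[[length(puncta) + 1L]] <- res$per
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  puncta <- if (length(puncta)) do.call(rbind, puncta) else NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(cell_id = character(0), reason = character(0))

  summary <- NULL
  if (!is.null(metadata) && !is.null(metrics)) {
    m <- merge(metrics, metadata, by = "cell_id")
    num <- c("n_whole", "n_peri", "n_cyto", "mean_area_whole",
             "mean_area_peri", "mean_area_cyto", "total_area")
    summary <- stats::aggregate(m[num],
                                by = list(group = m$group,
                                          hemisphere = m$hemisphere),
                                FUN = mean, na.rm = TRUE)
  }
  structure(list(metrics = metrics, puncta = puncta,
                 exclusions = exclusions, summary = summary),
            class = "puncta_pipeline_result")
}

#' @export
print.puncta_pipeline_result <- function(x, ...) {
  cat(sprintf("<puncta_pipeline_result> %d cells quantified, %d excluded\n",
              if (is.null(x$metrics)) 0L else nrow(x$metrics),
              nrow(x$exclusions)))
  invisible(x)
}
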