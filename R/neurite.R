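# Neurite disintegration index: fragmented/swollen neurite segments occupy
# the highest beta-III-Tubulin intensities, so the index is the fraction of
# segmented neurite area whose intensity exceeds a DMSO-calibrated
# mean + k*SD threshold (k = 3 by default), calibrated per cell line.

#' Segment the total neurite area from a beta-III-Tubulin image
#'
#' Line structures are enhanced (tubeness, feature size 10), the response is
#' binarized with a global two-class Otsu threshold (no pre-smoothing,
#' correction factor 1.3, no hole filling) and all foreground is merged into
#' a single neurite-area object. The Otsu threshold of the response is
#' additionally bounded below by a robust background floor
#' (median + `floor_k` * MAD of the response) so that fields of view without
#' neurites yield empty masks instead of thresholding camera noise.
#'
#' @param tubulin tubulin-channel `ChannelImage` or matrix.
#' @param feature_size expected neurite width in pixels.
#' @param correction_factor Otsu correction factor.
#' @param floor_k robust background floor multiplier (MAD units); 0 disables
#'   the floor.
#' @return a `BinaryMask` of the merged neurite area.
#' @export
segment_neurite_area <- function(tubulin, feature_size = 10L,
                                 correction_factor = 1.3, floor_k = 5) {
  enh <- as_pixels(enhance_line_structures(tubulin, feature_size))
  nr <- nrow(enh); nc <- ncol(enh)
  if (max(enh) <= min(enh)) {
    warning("no line structure in image: returning empty neurite mask")
    return(binary_mask(matrix(FALSE, nr, nc)))
  }
  thr <- otsu_threshold(enh) * correction_factor
  if (floor_k > 0) {
    floor_thr <- stats::median(enh) + floor_k * stats::mad(enh)
    thr <- max(thr, floor_thr)
  }
  binary_mask(enh > thr)
}

#' DMSO-calibrated intensity threshold for disintegrated neurite area
#'
#' For each DMSO (vehicle) image the mean and SD of tubulin intensity inside
#' the segmented neurite area are measured; the per-image means and SDs are
#' then averaged across images and the cell-line threshold is
#' `mean + k * SD` (k = 3 by default).
#'
#' @param dmso_images list of `list(image =, mask =)` pairs (tubulin image
#'   and its neurite mask) for the DMSO condition of one cell line.
#' @param cell_line cell-line identifier.
#' @param k SD multiplier.
#' @return a `NeuriteCalibration` list with fields `cell_line`,
#'   `mean_intensity`, `sd_intensity`, `k`, `threshold`, `n_images`.
#' @export
calibrate_threshold <- function(dmso_images, cell_line, k = 3) {
  if (!length(dmso_images)) stop("calibration error: no DMSO images supplied")
  means <- numeric(0); sds <- numeric(0)
  for (im in dmso_images) {
    px <- as_pixels(im$image)[as_mask_matrix(im$mask)]
    if (!length(px)) next
    means <- c(means, mean(px))
    sds <- c(sds, if (length(px) > 1L) stats::sd(px) else 0)
  }
  if (!length(means))
    stop("calibration error: no DMSO image with a non-empty neurite mask")
  m <- mean(means); s <- mean(sds)
  structure(list(cell_line = cell_line, mean_intensity = m, sd_intensity = s,
                 k = k, threshold = m + k * s, n_images = length(means)),
            class = "NeuriteCalibration")
}

#' @export
print.NeuriteCalibration <- function(x, ...) {
  cat(sprintf(
    "NeuriteCalibration [%s]: mean %.4g, SD %.4g, k=%g -> threshold %.4g (%d image(s))\n",
    x$cell_line, x$mean_intensity, x$sd_intensity, x$k, x$threshold, x$n_images))
  invisible(x)
}

#' Neurite disintegration index of one image
#'
#' The disintegrated area is the number of neurite-mask pixels whose tubulin
#' intensity is strictly above the calibration threshold; the index is
#' disintegrated area / total neurite area. An empty mask yields a
#' flagged-undefined result rather than an index of 0, since total neurite
#' loss must not be scored as healthy.
#'
#' @param tubulin tubulin image.
#' @param neurite_mask `BinaryMask` from [segment_neurite_area()].
#' @param calibration `NeuriteCalibration` for the same cell line.
#' @param image_id,condition identifiers carried into the result.
#' @return a `DisintegrationResult` list: `image_id`, `cell_line`,
#'   `condition`, `total_neurite_area`, `disintegrated_area`, `index`,
#'   `defined`.
#' @export
disintegration_index <- function(tubulin, neurite_mask, calibration,
                                 image_id = NA_character_,
                                 condition = NA_character_) {
  stopifnot(inherits(calibration, "NeuriteCalibration"))
  msk <- as_mask_matrix(neurite_mask)
  px <- as_pixels(tubulin)
  if (!identical(dim(msk), dim(px)))
    stop("mask and image geometry differ")
  total <- sum(msk)
  if (total == 0L) {
    return(structure(list(image_id = image_id, cell_line = calibration$cell_line,
                          condition = condition, total_neurite_area = 0L,
                          disintegrated_area = 0L, index = NA_real_,
                          defined = FALSE),
                     class = "DisintegrationResult"))
  }
  dis <- sum(px[msk] > calibration$threshold)
  structure(list(image_id = image_id, cell_line = calibration$cell_line,
                 condition = condition, total_neurite_area = total,
                 disintegrated_area = dis, index = dis / total,
                 defined = TRUE),
            class = "DisintegrationResult")
}

#' Summarize disintegration indices per cell line and condition
#'
#' Arithmetic mean of defined per-image indices within each
#' (cell line, condition) group; undefined (empty-mask) results are excluded
#' and counted.
#'
#' @param results list of `DisintegrationResult`s.
#' @return data.frame with `cell_line`, `condition`, `mean_index`,
#'   `n_images`, `n_undefined`.
#' @export
summarize_disintegration <- function(results) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(cell_line = r$cell_line, condition = r$condition,
               index = r$index, defined = r$defined,
               stringsAsFactors = FALSE)
  }))
  groups <- unique(df[, c("cell_line", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- df$cell_line == groups$cell_line[i] &
      df$condition == groups$condition[i]
    dfi <- df[sel, ]
    n_undef <- sum(!dfi$defined)
    if (all(!dfi$defined)) {
      warning(sprintf("group %s/%s: all indices undefined, group omitted",
                      groups$cell_line[i], groups$condition[i]))
      return(NULL)
    }
    data.frame(cell_line = groups$cell_line[i],
               condition = groups$condition[i],
               mean_index = mean(dfi$index[dfi$defined]),
               n_images = sum(dfi$defined), n_undefined = n_undef,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full disintegration pipeline over a set of images
#'
#' Segments every image, calibrates one threshold per cell line from its
#' DMSO images, scores every image and returns per-image and per-group
#' tables.
#'
#' @param images named list of tubulin images.
#' @param manifest data.frame with `image_id`, `cell_line`, `condition`
#'   (the DMSO condition identified by `dmso_label`).
#' @param k SD multiplier for calibration.
#' @param dmso_label condition label identifying vehicle images.
#' @param ... passed to [segment_neurite_area()].
#' @return list with `per_image` (data.frame), `per_group` (data.frame),
#'   `calibrations`.
#' @export
run_disintegration_pipeline <- function(images, manifest, k = 3,
                                        dmso_label = "DMSO", ...) {
  stopifnot(all(c("image_id", "cell_line", "condition") %in% names(manifest)),
            all(manifest$image_id %in% names(images)))
  masks <- lapply(manifest$image_id, function(id)
    segment_neurite_area(images[[id]], ...))
  names(masks) <- manifest$image_id
  calibrations <- list()
  for (cl in unique(manifest$cell_line)) {
    sel <- manifest$cell_line == cl & manifest$condition == dmso_label
    if (!any(sel)) stop(sprintf("cell line %s has no %s images", cl, dmso_label))
    pairs <- lapply(manifest$image_id[sel], function(id)
      list(image = images[[id]], mask = masks[[id]]))
    calibrations[[cl]] <- calibrate_threshold(pairs, cl, k = k)
  }
  results <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$image_id[i]
    disintegration_index(images[[id]], masks[[id]],
                         calibrations[[manifest$cell_line[i]]],
                         image_id = id, condition = manifest$condition[i])
  })
  per_image <- do.call(rbind, lapply(results, function(r)
    data.frame(image_id = r$image_id, cell_line = r$cell_line,
               condition = r$condition, total_area = r$total_neurite_area,
               disintegrated_area = r$disintegrated_area, index = r$index,
               stringsAsFactors = FALSE)))
  list(per_image = per_image,
       per_group = summarize_disintegration(results),
       calibrations = calibrations)
}
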