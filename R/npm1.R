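# NPM1 nucleolar-stress readout: nucleophosmin concentrates in nucleoli and
# disperses into the nucleoplasm under nucleolar stress. Per neuronal
# nucleus, the ratio of mean NPM1 intensity in the non-nucleolar nucleoplasm
# to the mean in the nucleolar area rises with translocation; per-line
# medians summarize it.

#' Segment nuclei from the DAPI channel
#'
#' Global two-class Otsu (smoothing scale 0.5, correction factor 2),
#' 8-connected labelling.
#'
#' @param dapi DAPI-channel image.
#' @param smoothing_scale,correction_factor thresholding parameters.
#' @return a `LabelMap` of nuclei.
#' @export
segment_nuclei <- function(dapi, smoothing_scale = 0.5, correction_factor = 2) {
  mask <- threshold_mask(dapi, threshold_spec("global",
                                              smoothing_scale = smoothing_scale,
                                              correction_factor = correction_factor))
  label_objects(mask)
}

#' Segment the neuron area from the beta-III-Tubulin channel
#'
#' Adaptive two-class Otsu (smoothing scale 1.3488, correction factor 1.3).
#'
#' @param tubulin tubulin-channel image.
#' @param smoothing_scale,correction_factor,window thresholding parameters.
#' @return a `BinaryMask`.
#' @export
segment_neuron_area <- function(tubulin, smoothing_scale = 1.3488,
                                correction_factor = 1.3, window = 50L) {
  threshold_mask(tubulin, threshold_spec("adaptive",
                                         smoothing_scale = smoothing_scale,
                                         correction_factor = correction_factor,
                                         window = window))
}

#' Keep nuclei that belong to neurons
#'
#' A nucleus is neuronal when at least `min_overlap` of its area lies inside
#' the neuron mask (ties at exactly the boundary fraction are retained).
#' Surviving nuclei are relabelled contiguously.
#'
#' @param nuclei nucleus `LabelMap`.
#' @param neuron_mask neuron-area `BinaryMask`.
#' @param min_overlap minimum overlap fraction (default 0.5).
#' @return filtered `LabelMap`.
#' @export
filter_neuronal_nuclei <- function(nuclei, neuron_mask, min_overlap = 0.5) {
  msk <- as_mask_matrix(neuron_mask)
  if (!identical(dim(msk), dim(nuclei)))
    stop("nuclei and neuron mask geometry differ")
  n <- object_count(nuclei)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  keep <- 0L
  for (k in seq_len(n)) {
    sel <- nuclei == k
    if (sum(msk[sel]) / sum(sel) >= min_overlap) {
      keep <- keep + 1L
      out[sel] <- keep
    }
  }
  label_map(out)
}

# per-nucleus detection of nucleolar pixels on the prepared detection image;
# the two-class Otsu runs on the within-nucleus intensity distribution so the
# masked-out background cannot pull the threshold down
detect_nucleolar_mask <- function(det, nucleus_sel, correction_factor = 1) {
  vals <- det[nucleus_sel]
  if (max(vals) <= min(vals)) return(NULL)
  thr <- otsu_threshold(matrix(vals, nrow = 1L)) * correction_factor
  m <- nucleus_sel & det > thr
  if (!any(m)) return(NULL)
  m
}

#' Segment one nucleolar object per neuronal nucleus from the NPM1 channel
#'
#' Two detection routes are available. `"intensity"` (the default) thresholds
#' the NPM1 intensity image inside each nucleus with a two-class Otsu,
#' exploiting that nucleoli are the bright NPM1 compartment. `"edge"` mirrors
#' the published CellProfiler chain: the NPM1 image is masked to neuronal
#' nuclei, Sobel edge-enhanced, Gaussian filtered (sigma 2.5) and binarized
#' with an adaptive two-class Otsu (smoothing scale 1, correction factor 1);
#' at typical nucleolar sizes this detects the nucleolar rim as a band around
#' the true boundary (see the methods vignette), so it is not the default.
#' Either way, per nucleus all detected pixels are merged into a single
#' nucleolar object (label = nucleus label) and enclosed holes up to
#' `fill_hole_max` pixels are filled. Detection runs on a derived image;
#' intensity measurements elsewhere always use the original NPM1 image. The
#' outermost `rim_margin` pixels of each nucleus are excluded from detection
#' to avoid the masking-edge artifact.
#'
#' @param npm1 NPM1-channel image.
#' @param neuronal_nuclei `LabelMap` from [filter_neuronal_nuclei()].
#' @param method `"intensity"` or `"edge"`.
#' @param fill_hole_max maximum enclosed-hole area filled, in pixels.
#' @param edge_sigma Gaussian sigma applied after Sobel in the edge route.
#' @param rim_margin nucleus-boundary margin excluded from detection, px.
#' @return list: `nucleoli` (`LabelMap`, labels matching nucleus labels) and
#'   `flagged` (integer labels of nuclei with no detectable nucleolus).
#' @export
segment_nucleoli <- function(npm1, neuronal_nuclei,
                             method = c("intensity", "edge"),
                             fill_hole_max = 50L, edge_sigma = 2.5,
                             rim_margin = 3L) {
  method <- match.arg(method)
  px <- as_pixels(npm1)
  if (!identical(dim(px), dim(neuronal_nuclei)))
    stop("NPM1 image and nucleus label map geometry differ")
  n <- object_count(neuronal_nuclei)
  if (n < 1L) stop("no neuronal nuclei to segment nucleoli in")
  masked <- px
  masked[neuronal_nuclei == 0L] <- 0
  det <- if (method == "edge") {
    as_pixels(smooth_image(sobel_magnitude(masked), edge_sigma))
  } else {
    masked
  }
  interior <- erode_mask(unclass(neuronal_nuclei) > 0L, rim_margin)
  out <- matrix(0L, nrow(px), ncol(px))
  flagged <- integer(0)
  for (k in seq_len(n)) {
    nucleus_sel <- unclass(neuronal_nuclei) == k & interior
    if (!any(nucleus_sel)) { flagged <- c(flagged, k); next }
    m <- detect_nucleolar_mask(det, nucleus_sel)
    if (is.null(m)) { flagged <- c(flagged, k); next }
    if (fill_hole_max > 0L) {
      filled <- label_objects(m, merge_all = TRUE, fill_hole_max = fill_hole_max)
      m <- unclass(filled) > 0L
    }
    out[m] <- k
  }
  labs <- structure(out, object_count = n, class = c("LabelMap", "matrix", "array"))
  list(nucleoli = labs, flagged = flagged)
}

# binary erosion by a square structuring element of radius r
erode_mask <- function(mask, r) {
  r <- as.integer(r)
  if (r <= 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  mp <- pad_replicate(mask * 1L, r)
  out <- matrix(TRUE, nr, nc)
  for (dr in -r:r) for (dc in -r:r)
    out <- out & (shift_core(mp, r, nr, nc, dr, dc) > 0L)
  out
}

#' Per-cell NPM1 nucleoplasm/nucleolus intensity ratio
#'
#' The nucleoplasm is the nucleus minus its nucleolar object (tertiary
#' region); the ratio is mean NPM1 intensity over the nucleoplasm divided by
#' mean NPM1 intensity over the nucleolus, both measured on the original
#' NPM1 image. Empty compartments flag the measurement invalid.
#'
#' @param npm1 NPM1 image.
#' @param nucleus_sel logical matrix selecting the nucleus pixels.
#' @param nucleolus_sel logical matrix selecting the nucleolar pixels
#'   (must lie inside the nucleus).
#' @param image_id,nucleus_label identifiers carried into the result.
#' @return a `NucleusMeasurement` list.
#' @export
npm1_ratio <- function(npm1, nucleus_sel, nucleolus_sel,
                       image_id = NA_character_, nucleus_label = NA_integer_) {
  px <- as_pixels(npm1)
  if (any(nucleolus_sel & !nucleus_sel))
    stop("nucleolus must lie inside the nucleus")
  nucleoplasm_sel <- nucleus_sel & !nucleolus_sel
  valid <- any(nucleolus_sel) && any(nucleoplasm_sel)
  nucleolar_mean <- if (any(nucleolus_sel)) mean(px[nucleolus_sel]) else NA_real_
  nucleoplasm_mean <- if (any(nucleoplasm_sel)) mean(px[nucleoplasm_sel]) else NA_real_
  ratio <- if (valid && nucleolar_mean > 0) nucleoplasm_mean / nucleolar_mean else NA_real_
  structure(list(image_id = image_id, nucleus_label = nucleus_label,
                 nucleolar_area = sum(nucleolus_sel),
                 nucleoplasm_area = sum(nucleoplasm_sel),
                 nucleolar_mean_intensity = nucleolar_mean,
                 nucleoplasm_mean_intensity = nucleoplasm_mean,
                 ratio = ratio, valid = valid && !is.na(ratio)),
            class = "NucleusMeasurement")
}

#' Summarize NPM1 ratios per group (median)
#'
#' @param measurements list of `NucleusMeasurement`s.
#' @param cell_line,condition vectors parallel to `measurements`.
#' @return data.frame: `cell_line`, `condition`, `median_ratio`, `n_cells`,
#'   `n_invalid`.
#' @export
summarize_npm1 <- function(measurements, cell_line, condition) {
  df <- data.frame(cell_line = cell_line, condition = condition,
                   ratio = vapply(measurements, function(m) m$ratio, 0),
                   valid = vapply(measurements, function(m) m$valid, TRUE),
                   stringsAsFactors = FALSE)
  groups <- unique(df[, c("cell_line", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- df$cell_line == groups$cell_line[i] &
      df$condition == groups$condition[i]
    dfi <- df[sel, ]
    if (!any(dfi$valid)) {
      warning(sprintf("group %s/%s: no valid measurement, group omitted",
                      groups$cell_line[i], groups$condition[i]))
      return(NULL)
    }
    data.frame(cell_line = groups$cell_line[i],
               condition = groups$condition[i],
               median_ratio = stats::median(dfi$ratio[dfi$valid]),
               n_cells = sum(dfi$valid), n_invalid = sum(!dfi$valid),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full NPM1 translocation pipeline for one field of view
#'
#' Segments nuclei (DAPI) and the neuron area (tubulin), keeps neuronal
#' nuclei, segments nucleoli from the NPM1 channel and measures the per-cell
#' nucleoplasm/nucleolus ratio.
#'
#' @param dapi,tubulin,npm1 the three channel images.
#' @param image_id identifier carried into the measurements.
#' @param method nucleolus detection route, see [segment_nucleoli()].
#' @return list: `measurements` (list of `NucleusMeasurement`),
#'   `n_nuclei`, `n_neuronal`, `n_flagged`.
#' @export
run_npm1_pipeline <- function(dapi, tubulin, npm1, image_id = NA_character_,
                              method = "intensity") {
  nuclei <- segment_nuclei(dapi)
  neuron <- segment_neuron_area(tubulin)
  neuronal <- filter_neuronal_nuclei(nuclei, neuron)
  if (object_count(neuronal) == 0L)
    return(list(measurements = list(), n_nuclei = object_count(nuclei),
                n_neuronal = 0L, n_flagged = 0L))
  seg <- segment_nucleoli(npm1, neuronal, method = method)
  meas <- list()
  for (k in seq_len(object_count(neuronal))) {
    if (k %in% seg$flagged) next
    meas[[length(meas) + 1L]] <- npm1_ratio(
      npm1, unclass(neuronal) == k, unclass(seg$nucleoli) == k,
      image_id = image_id, nucleus_label = k)
  }
  list(measurements = meas, n_nuclei = object_count(nuclei),
       n_neuronal = object_count(neuronal), n_flagged = length(seg$flagged))
}
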