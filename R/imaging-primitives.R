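# Reusable segmentation operators shared by the neurite-disintegration and
# NPM1-translocation pipelines. All operators are deterministic and preserve
# the source image geometry.

# -- low-level helpers ---------------------------------------------------

# replicate-pad a matrix by r rows/cols on each side
pad_replicate <- function(m, r) {
  if (r <= 0L) return(m)
  m <- rbind(m[rep(1L, r), , drop = FALSE], m,
             m[rep(nrow(m), r), , drop = FALSE])
  cbind(m[, rep(1L, r), drop = FALSE], m,
        m[, rep(ncol(m), r), drop = FALSE])
}

# shift a padded matrix so that out[i,j] = mp[i+r+dr, j+r+dc] on the core
shift_core <- function(mp, r, nr, nc, dr, dc) {
  mp[(r + dr) + seq_len(nr), (r + dc) + seq_len(nc), drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with a symmetric odd kernel, replicate boundary
convolve_separable <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nr, r), , drop = FALSE])
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * mp[(i - 1L) + seq_len(nr), , drop = FALSE]
  mp <- cbind(out[, rep(1L, r), drop = FALSE], out, out[, rep(nc, r), drop = FALSE])
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out2 <- out2 + k[i] * mp[, (i - 1L) + seq_len(nc), drop = FALSE]
  out2
}

# -- smoothing -----------------------------------------------------------

#' Gaussian smoothing
#'
#' Isotropic Gaussian blur with `sigma = smoothing_scale` pixels (truncated at
#' 4 sigma, replicate boundary). A scale of 0 returns the input unchanged.
#' This fixes the meaning of the "smoothing scale" parameter used throughout
#' the segmentation pipelines.
#'
#' @param image `ChannelImage` or numeric matrix.
#' @param smoothing_scale Gaussian sigma in pixels, `>= 0`.
#' @return smoothed image of the same class and geometry.
#' @export
smooth_image <- function(image, smoothing_scale) {
  if (!is.numeric(smoothing_scale) || length(smoothing_scale) != 1L ||
      is.na(smoothing_scale) || smoothing_scale < 0)
    stop("`smoothing_scale` must be a single non-negative number")
  m <- as_pixels(image)
  if (smoothing_scale == 0) return(image)
  rewrap(convolve_separable(m, gaussian_kernel_1d(smoothing_scale)), image)
}

# -- Otsu thresholding ---------------------------------------------------

#' Otsu two-class threshold
#'
#' Histogram of 256 uniform bins over the image's own `[min, max]`; returns
#' the bin edge maximizing the between-class variance. Pixels strictly above
#' the returned value belong to the bright class.
#'
#' @param image `ChannelImage` or numeric matrix with at least two distinct
#'   values.
#' @param nbins number of histogram bins (256 by default, the 8-bit
#'   convention applied to float data).
#' @return the threshold (a single number).
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  m <- as_pixels(image)
  lo <- min(m); hi <- max(m)
  if (hi <= lo) stop("degenerate input: constant image has no Otsu threshold")
  edges <- seq(lo, hi, length.out = nbins + 1L)
  idx <- findInterval(m, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  s <- cumsum(counts * mids)
  tot <- w[nbins]; stot <- s[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]; w1 <- tot - w0
  mu0 <- ifelse(w0 > 0, s[k] / w0, 0)
  mu1 <- ifelse(w1 > 0, (stot - s[k]) / w1, 0)
  bcv <- ifelse(w0 > 0 & w1 > 0, w0 * w1 * (mu0 - mu1)^2, -Inf)
  edges[which.max(bcv) + 1L]
}

# Otsu effectiveness: max between-class variance / total variance, in [0,1].
otsu_eta <- function(m) {
  thr <- otsu_threshold(m)
  fg <- m > thr
  v <- stats::var(as.vector(m))
  if (v == 0) return(0)
  w1 <- mean(fg); w0 <- 1 - w1
  if (w1 == 0 || w0 == 0) return(0)
  w0 * w1 * (mean(m[fg]) - mean(m[!fg]))^2 / v * length(m) / (length(m) - 1L)
}

# -- threshold specification and masking ---------------------------------

#' Thresholding parameters for [threshold_mask()]
#'
#' @param strategy `"global"` (one Otsu threshold for the whole image) or
#'   `"adaptive"` (per-tile Otsu thresholds, bilinearly interpolated between
#'   tile centers).
#' @param smoothing_scale Gaussian sigma applied before thresholding; 0
#'   disables smoothing.
#' @param correction_factor multiplier applied to the computed threshold(s);
#'   larger values shrink the foreground.
#' @param window adaptive tile side in pixels (`>= 8`); ignored for the
#'   global strategy.
#' @param fill_holes fill enclosed background holes in the resulting mask.
#' @param min_tile_range_frac adaptive tiles whose intensity range is below
#'   this fraction of the global range are treated as near-constant and
#'   inherit the global threshold.
#' @return a `ThresholdSpec` list.
#' @export
threshold_spec <- function(strategy = c("global", "adaptive"),
                           smoothing_scale = 0,
                           correction_factor = 1,
                           window = 50L,
                           fill_holes = FALSE,
                           min_tile_range_frac = 0.3) {
  strategy <- match.arg(strategy)
  if (correction_factor <= 0) stop("`correction_factor` must be positive")
  if (smoothing_scale < 0) stop("`smoothing_scale` must be non-negative")
  window <- as.integer(window)
  if (strategy == "adaptive" && window < 8L)
    stop("adaptive `window` must be at least 8 pixels")
  structure(list(strategy = strategy, smoothing_scale = smoothing_scale,
                 correction_factor = correction_factor, window = window,
                 fill_holes = isTRUE(fill_holes),
                 min_tile_range_frac = min_tile_range_frac),
            class = "ThresholdSpec")
}

# bilinear interpolation of a coarse grid of values up to an nr x nc raster,
# constant extrapolation beyond the outermost grid centers
interp_bilinear <- function(vals, centers_r, centers_c, nr, nc) {
  interp_axis <- function(centers, n, V) {
    if (length(centers) == 1L)
      return(matrix(rep(V[1L, ], each = n), n, ncol(V)))
    pos <- seq_len(n)
    i <- pmin(findInterval(pos, centers, all.inside = TRUE),
              length(centers) - 1L)
    w <- (pos - centers[i]) / (centers[i + 1L] - centers[i])
    w <- pmin(pmax(w, 0), 1)
    V[i, , drop = FALSE] * (1 - w) + V[i + 1L, , drop = FALSE] * w
  }
  tmp <- interp_axis(centers_r, nr, vals)
  t(interp_axis(centers_c, nc, t(tmp)))
}

#' Binarize an image by (optionally adaptive) Otsu thresholding
#'
#' Smooths the image, computes the Otsu threshold globally or per tile (with
#' bilinear interpolation of the threshold surface between tile centers),
#' multiplies by the correction factor and keeps pixels strictly above the
#' threshold. Near-constant adaptive tiles inherit the global threshold. A
#' constant image yields an empty mask with a warning so that pipelines can
#' proceed on blank fields of view.
#'
#' @param image `ChannelImage` or numeric matrix.
#' @param spec a [threshold_spec()].
#' @return a `BinaryMask` with the source geometry.
#' @export
threshold_mask <- function(image, spec = threshold_spec()) {
  stopifnot(inherits(spec, "ThresholdSpec"))
  m <- as_pixels(smooth_image(image, spec$smoothing_scale))
  nr <- nrow(m); nc <- ncol(m)
  if (max(m) <= min(m)) {
    warning("constant image: returning empty mask")
    return(binary_mask(matrix(FALSE, nr, nc)))
  }
  global_thr <- otsu_threshold(m)
  if (spec$strategy == "global") {
    mask <- m > global_thr * spec$correction_factor
  } else {
    w <- spec$window
    row_breaks <- unique(c(seq(0L, nr, by = w), nr))
    col_breaks <- unique(c(seq(0L, nc, by = w), nc))
    n_tr <- length(row_breaks) - 1L
    n_tc <- length(col_breaks) - 1L
    thr <- matrix(global_thr, n_tr, n_tc)
    centers_r <- numeric(n_tr); centers_c <- numeric(n_tc)
    grange <- max(m) - min(m)
    for (i in seq_len(n_tr)) {
      rows <- (row_breaks[i] + 1L):row_breaks[i + 1L]
      centers_r[i] <- mean(rows)
      for (j in seq_len(n_tc)) {
        cols <- (col_breaks[j] + 1L):col_breaks[j + 1L]
        if (i == 1L) centers_c[j] <- mean(cols)
        tile <- m[rows, cols]
        if (max(tile) - min(tile) >= spec$min_tile_range_frac * grange)
          thr[i, j] <- otsu_threshold(tile)
      }
    }
    surface <- interp_bilinear(thr, centers_r, centers_c, nr, nc)
    mask <- m > surface * spec$correction_factor
  }
  if (spec$fill_holes) mask <- fill_holes_mask(mask)
  binary_mask(mask)
}

# -- feature enhancement -------------------------------------------------

#' Enhance curvilinear (neurite-like) structures
#'
#' Hessian tubeness ridge filter: the image is smoothed at
#' `sigma = feature_size / 2`, the 2-D Hessian is estimated by central
#' differences, and the response is the magnitude of the most negative
#' eigenvalue, clipped at zero. Bright ridges of width up to `feature_size`
#' score higher than isotropic blobs of equal peak intensity.
#'
#' @param image `ChannelImage` or numeric matrix.
#' @param feature_size expected structure width in pixels (`>= 2`).
#' @return non-negative response image, same class and geometry.
#' @export
enhance_line_structures <- function(image, feature_size = 10L) {
  if (feature_size < 2) stop("`feature_size` must be at least 2")
  m <- as_pixels(image)
  g <- as_pixels(smooth_image(m, feature_size / 2))
  nr <- nrow(g); nc <- ncol(g)
  gp <- pad_replicate(g, 1L)
  up    <- shift_core(gp, 1L, nr, nc, -1L, 0L)
  down  <- shift_core(gp, 1L, nr, nc,  1L, 0L)
  left  <- shift_core(gp, 1L, nr, nc, 0L, -1L)
  right <- shift_core(gp, 1L, nr, nc, 0L,  1L)
  ul <- shift_core(gp, 1L, nr, nc, -1L, -1L)
  ur <- shift_core(gp, 1L, nr, nc, -1L,  1L)
  dl <- shift_core(gp, 1L, nr, nc,  1L, -1L)
  dr <- shift_core(gp, 1L, nr, nc,  1L,  1L)
  ixx <- up + down - 2 * g
  iyy <- left + right - 2 * g
  ixy <- (dr + ul - ur - dl) / 4
  lam_min <- (ixx + iyy) / 2 - sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  rewrap(pmax(-lam_min, 0), image)
}

#' Sobel gradient magnitude
#'
#' Standard 3x3 Sobel kernels (weights 1-2-1, unnormalized), replicate
#' boundary; returns `sqrt(gx^2 + gy^2)`. An interior vertical step of height
#' `h` responds with 4`h` in the two columns adjacent to the step.
#'
#' @param image `ChannelImage` or numeric matrix.
#' @return gradient-magnitude image, same class and geometry.
#' @export
sobel_magnitude <- function(image) {
  m <- as_pixels(image)
  nr <- nrow(m); nc <- ncol(m)
  mp <- pad_replicate(m, 1L)
  s <- function(dr, dc) shift_core(mp, 1L, nr, nc, dr, dc)
  gx <- (s(-1L, 1L) + 2 * s(0L, 1L) + s(1L, 1L)) -
        (s(-1L, -1L) + 2 * s(0L, -1L) + s(1L, -1L))
  gy <- (s(1L, -1L) + 2 * s(1L, 0L) + s(1L, 1L)) -
        (s(-1L, -1L) + 2 * s(-1L, 0L) + s(-1L, 1L))
  rewrap(sqrt(gx^2 + gy^2), image)
}

# -- connected components, merging, hole filling -------------------------

# connected-component labelling via the pixel adjacency graph;
# connectivity 8 for foreground objects, 4 for background holes
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(out)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ea <- integer(0); eb <- integer(0)
  for (o in offs) {
    r2 <- rr + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[nb] > 0L
    ea <- c(ea, vid[idx[ok]][hit])
    eb <- c(eb, vid[nb][hit])
  }
  if (length(ea)) {
    g <- igraph::make_graph(rbind(ea, eb), n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  # contiguous labels in column-major first-pixel order
  memb <- match(memb, unique(memb))
  out[idx] <- memb
  out
}

# fill every enclosed background hole (background components not touching
# the image border) of a logical mask
fill_holes_mask <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border_labels <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  mask | (bg > 0L & !(bg %in% border_labels))
}

#' Label connected foreground objects
#'
#' 8-connected component labelling of a binary mask, with optional merging of
#' all foreground into a single object and filling of enclosed background
#' holes up to a maximum area, attributed to the unique enclosing object.
#'
#' @param mask logical matrix / `BinaryMask`.
#' @param merge_all merge all foreground pixels into one object (label 1).
#' @param fill_hole_max fill enclosed holes of area `<=` this many pixels
#'   when they are bordered by exactly one object; 0 disables filling.
#' @return a `LabelMap`.
#' @export
label_objects <- function(mask, merge_all = FALSE, fill_hole_max = 0L) {
  m <- as_mask_matrix(mask)
  lab <- label_components(m, connectivity = 8L)
  if (merge_all) lab[lab > 0L] <- 1L
  if (fill_hole_max > 0L && any(lab > 0L)) {
    nr <- nrow(lab); nc <- ncol(lab)
    bg <- label_components(lab == 0L, connectivity = 4L)
    border_labels <- unique(c(bg[1L, ], bg[nr, ], bg[, 1L], bg[, nc]))
    holes <- setdiff(unique(bg[bg > 0L]), border_labels)
    labp <- pad_replicate(lab, 1L)
    for (h in holes) {
      hidx <- which(bg == h)
      if (length(hidx) > fill_hole_max) next
      rr <- ((hidx - 1L) %% nr) + 1L
      cc <- ((hidx - 1L) %/% nr) + 1L
      nb_labels <- unique(c(labp[cbind(rr, cc + 1L)], labp[cbind(rr + 2L, cc + 1L)],
                            labp[cbind(rr + 1L, cc)], labp[cbind(rr + 1L, cc + 2L)]))
      nb_labels <- nb_labels[nb_labels > 0L]
      if (length(nb_labels) == 1L) lab[hidx] <- nb_labels
    }
  }
  label_map(lab)
}
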