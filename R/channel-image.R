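#' Single-channel fluorescence image
#'
#' Lightweight container for one 2-D channel of a fluorescence field of view:
#' a non-negative intensity matrix plus a channel tag and optional pixel size.
#' All segmentation operators in the package accept either a `ChannelImage`
#' or a bare numeric matrix.
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (arbitrary fluorescence units), at least 2 x 2.
#' @param channel channel tag, one of `"tubulin"`, `"dapi"`, `"npm1"`,
#'   `"other"`.
#' @param scale optional microns-per-pixel, informational only.
#' @return an object of class `ChannelImage`.
#' @export
channel_image <- function(pixels, channel = c("other", "tubulin", "dapi", "npm1"),
                          scale = NULL) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2 pixels")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("intensities must be finite")
  if (any(pixels < 0))
    stop("intensities must be non-negative")
  structure(list(pixels = pixels, channel = channel, scale = scale),
            class = "ChannelImage")
}

#' @export
print.ChannelImage <- function(x, ...) {
  cat(sprintf("ChannelImage [%s]: %d x %d px, range [%.4g, %.4g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ChannelImage <- function(x) dim(x$pixels)

# Accept ChannelImage or plain matrix; returns the intensity matrix.
as_pixels <- function(image) {
  if (inherits(image, "ChannelImage")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected a ChannelImage or numeric matrix")
}

# Rewrap a matrix with the metadata of a template image (if any).
rewrap <- function(pixels, template) {
  if (inherits(template, "ChannelImage"))
    structure(list(pixels = pixels, channel = template$channel,
                   scale = template$scale), class = "ChannelImage")
  else pixels
}

#' Binary mask sharing an image's geometry
#'
#' @param pixels logical matrix.
#' @return object of class `BinaryMask` (a logical matrix).
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  structure(pixels, class = c("BinaryMask", class(pixels)))
}

as_mask_matrix <- function(mask) {
  if (is.matrix(mask) && is.logical(mask)) return(unclass(mask))
  stop("expected a logical matrix mask")
}

#' Integer label map of segmented objects
#'
#' Background is 0; objects carry contiguous labels `1..object_count`.
#'
#' @param pixels integer matrix of labels.
#' @return object of class `LabelMap` with attribute `object_count`.
#' @export
label_map <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  n <- if (length(pixels)) max(pixels) else 0L
  labs <- sort(unique(pixels[pixels > 0L]))
  if (length(labs) && !identical(labs, seq_len(n)))
    stop("labels must be contiguous 1..object_count")
  structure(pixels, object_count = as.integer(n),
            class = c("LabelMap", class(pixels)))
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap: %d x %d px, %d object(s)\n",
              nrow(x), ncol(x), attr(x, "object_count")))
  invisible(x)
}

#' Number of labelled objects in a LabelMap
#' @param labels a `LabelMap`.
#' @return integer object count.
#' @export
object_count <- function(labels) {
  n <- attr(labels, "object_count")
  if (is.null(n)) n <- max(0L, as.integer(max(labels)))
  n
}

#' Read a single-channel TIFF as a ChannelImage
#'
#' Multi-sample TIFFs are reduced to the requested sample (plane).
#'
#' @param path TIFF file path.
#' @param channel channel tag for the result.
#' @param plane which sample/plane to take if the file holds several.
#' @return `ChannelImage`.
#' @export
read_channel_tiff <- function(path, channel = "other", plane = 1L) {
  arr <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(arr)) arr <- arr[[plane]]
  if (length(dim(arr)) == 3L) arr <- arr[, , plane]
  channel_image(matrix(as.numeric(arr), nrow(arr), ncol(arr)), channel = channel)
}

#' Write an image, mask or label map to 16-bit TIFF for inspection
#'
#' Intensities are rescaled to `[0, 1]` over the data range; masks map to
#' \{0, 1\} and label maps to label/65535.
#'
#' @param x `ChannelImage`, `BinaryMask`, `LabelMap` or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(x, path) {
  m <- if (inherits(x, "ChannelImage")) x$pixels else unclass(x)
  if (is.logical(m)) m <- m * 1
  m <- m * 1.0
  if (inherits(x, "LabelMap")) m <- m / 65535 else {
    rng <- range(m)
    m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  }
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
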