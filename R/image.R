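#' Coerce to a grayscale image matrix
#'
#' A gray image is a plain numeric matrix (rows = image rows) with finite
#' values, nominally in \[0, 1\]. File readers rescale by dtype range
#' (8/16-bit) or min-max (float); in-memory matrices are taken as-is so that
#' affine transforms of an image (used e.g. to study contrast equivariance
#' of the filters) are not silently renormalized.
#'
#' @param x A numeric matrix, or an array with a single channel.
#' @param normalize If `TRUE`, min-max rescale to \[0, 1\] (constant images
#'   are clamped instead).
#' @return A numeric matrix of class `gray_image`.
#' @export
as_gray_image <- function(x, normalize = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L)
      stop("multi-channel input: select a channel first")
    x <- x[, , 1L]
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (!all(is.finite(x))) stop("image contains non-finite values")
  if (normalize) {
    rng <- range(x)
    x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else
      pmin(pmax(x, 0), 1)
  }
  class(x) <- c("gray_image", class(matrix()))
  x
}

#' Read a single-channel image file
#'
#' Reads 8-bit, 16-bit or float TIFF and PNG images as a gray image matrix
#' scaled to \[0, 1\]. Integer samples are scaled by their dtype range (the
#' underlying readers already do this); float samples outside \[0, 1\] are
#' min-max rescaled. Multi-channel images are an error unless `channel`
#' names the channel to extract.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel Optional 1-based channel index for multi-channel files.
#' @return A `gray_image` matrix.
#' @export
read_gray_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("input image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              tif = ,
              tiff = tiff::readTIFF(path),
              png = png::readPNG(path),
              stop("unsupported image format '.", ext, "': ", path))
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(channel)) {
      if (dim(x)[3] == 1L) channel <- 1L
      else stop("multi-channel image (", dim(x)[3],
                " channels); pass `channel`: ", path)
    }
    if (channel < 1L || channel > dim(x)[3])
      stop("channel ", channel, " out of range for ", path)
    x <- x[, , channel]
  }
  rng <- range(x)
  needs_rescale <- rng[1] < 0 || rng[2] > 1
  as_gray_image(x, normalize = needs_rescale)
}

#' Write a response map as 32-bit float TIFF
#'
#' Values already inside \[0, 1\] (e.g. any TSBF map of a normalized
#' image with `omega = 1`) are stored as-is. Maps with values outside
#' \[0, 1\] (SBF/CI maps are signed) are affinely rescaled into \[0, 1\]
#' for storage -- the TIFF writer only defines float samples on that range
#' -- and the transform is recorded in a `<path>.json` sidecar with fields
#' `offset` and `scale` (`original = offset + scale * stored`).
#'
#' @param response A `response_map` (from [filter_image()]) or numeric
#'   matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_tiff <- function(response, path) {
  v <- if (inherits(response, "response_map")) response$values else response
  storage.mode(v) <- "double"
  lo <- min(v); hi <- max(v)
  if (lo < 0 || hi > 1) {
    scale <- if (hi > lo) hi - lo else 1
    jsonlite::write_json(list(offset = lo, scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    v <- (v - lo) / scale
  }
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a gray image as 16-bit TIFF
#'
#' Values are clamped to \[0, 1\] before quantization.
#'
#' @param image Gray image matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  v <- pmin(pmax(unclass(image), 0), 1)
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("Gray image: %d x %d, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, ..., main = "gray image") {
  m <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  graphics::image(m, col = gray(seq(0, 1, length.out = 256)),
                  asp = nrow(x) / ncol(x), axes = FALSE, main = main, ...)
  invisible(x)
}
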