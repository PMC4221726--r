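resolve_threshold <- function(values, params) {
  switch(params$threshold_mode,
         absolute = params$threshold_value,
         mean_plus_k_std = mean(values) + params$threshold_value * sd(values),
         fraction_of_max = params$threshold_value * max(values))
}

new_detection <- function(centers, scores, border_flags, threshold = NA_real_,
                          method = "TSBF") {
  ord <- order(-scores, centers[, 1], centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  colnames(centers) <- c("row", "col")
  structure(list(centers = centers, scores = scores[ord],
                 border_flags = border_flags[ord],
                 count = nrow(centers), threshold = threshold,
                 method = method),
            class = "cell_detection")
}

#' Non-maximum suppression on a response map
#'
#' Returns every pixel that strictly exceeds the resolved threshold and is
#' strictly greater than all other pixels in its
#' `(2 * window_half_width + 1)^2` window. Tied plateaus keep only the
#' lexicographically smallest `(row, col)` pixel, so output never contains
#' two centers within `window_half_width` Chebyshev distance. Centers are
#' reported 0-based and sorted by descending score.
#'
#' @param response A `response_map` from [filter_image()] or a numeric
#'   matrix (all values finite).
#' @param params An [nms_params()] object.
#' @return An object of class `cell_detection` with `centers` (0-based
#'   integer `(row, col)` matrix), `scores`, `border_flags`, `count` and
#'   the resolved `threshold`.
#' @export
non_max_suppression <- function(response, params = nms_params()) {
  is_map <- inherits(response, "response_map")
  v <- if (is_map) response$values else response
  if (!is.matrix(v) || !is.numeric(v)) stop("response must be a numeric matrix")
  if (!all(is.finite(v))) stop("response contains non-finite values")
  thr <- resolve_threshold(v, params)
  res <- nms_cpp(v, params$window_half_width, thr)
  centers <- cbind(res$row, res$col)
  border <- if (is_map && nrow(centers) > 0)
    response$border[centers + 1L] else rep(FALSE, nrow(centers))
  new_detection(centers, res$score, border, thr,
                method = if (is_map) response$kind else "map")
}

#' Detect cells with the TSBF pipeline
#'
#' Enhancement by [filter_image()] with the `"TSBF"` kind followed by
#' [non_max_suppression()]. Deterministic for fixed inputs.
#'
#' @param image Gray image matrix.
#' @param filter_params A [filter_params()] object.
#' @param nms_params An [nms_params()] object.
#' @param smoothing_sigma Gradient pre-smoothing sigma in pixels.
#' @return A `cell_detection` object.
#' @examples
#' sc <- generate_brightfield_scene(scene_spec(n_cells = 3, seed = 7))
#' det <- detect_cells(sc$image)
#' det$count
#' @export
detect_cells <- function(image, filter_params = tsbf::filter_params(),
                         nms_params = tsbf::nms_params(),
                         smoothing_sigma = 1) {
  rmap <- filter_image(image, filter_params, "TSBF", smoothing_sigma)
  non_max_suppression(rmap, nms_params)
}

#' Laplacian-of-Gaussian baseline detector
#'
#' Classical blob detection: the image is Gaussian-smoothed at scale
#' `sigma` and the negated discrete Laplacian is taken as the response, so
#' that bright-core blobs -- a dark-field cell, or the bright interior of a
#' bright-field ring seen at a matched scale -- are response maxima. The
#' same non-maximum suppression as the TSBF pipeline extracts centers.
#'
#' @param image Gray image matrix.
#' @param sigma LoG scale in pixels (> 0).
#' @param nms_params An [nms_params()] object.
#' @return A `cell_detection` object.
#' @export
detect_cells_log_baseline <- function(image, sigma = 8,
                                      nms_params = tsbf::nms_params()) {
  m <- unclass(image)
  if (!is.matrix(m)) stop("image must be a matrix")
  if (sigma <= 0) stop("sigma must be > 0")
  ms <- smooth_gaussian(m, sigma)
  H <- nrow(ms); W <- ncol(ms)
  up    <- ms[pmax(seq_len(H) - 1L, 1L), , drop = FALSE]
  down  <- ms[pmin(seq_len(H) + 1L, H), , drop = FALSE]
  left  <- ms[, pmax(seq_len(W) - 1L, 1L), drop = FALSE]
  right <- ms[, pmin(seq_len(W) + 1L, W), drop = FALSE]
  log_resp <- -(up + down + left + right - 4 * ms)
  det <- non_max_suppression(log_resp, nms_params)
  det$method <- "LoG"
  det
}

#' Intensity-threshold baseline detector
#'
#' Binarizes the image with the dark-object convention used for bright
#' field (pixels strictly darker than `threshold` are foreground), labels
#' connected components (8-connectivity) and reports component centroids
#' as centers with component pixel count as score. For ring-shaped cells
#' the foreground is the membrane annulus, so centroids need not lie on
#' any cell structure.
#'
#' @param image Gray image matrix.
#' @param threshold Intensity fraction in (0, 1).
#' @return A `cell_detection` object (centers are rounded centroids,
#'   0-based).
#' @export
detect_cells_threshold_baseline <- function(image, threshold = 0.5) {
  m <- unclass(image)
  if (!is.matrix(m)) stop("image must be a matrix")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mask <- m < threshold
  if (!any(mask))
    return(new_detection(matrix(integer(), 0, 2), numeric(), logical(),
                         method = "threshold"))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  labv <- as.integer(lab)
  keep <- labv > 0L
  rows <- row(m)[keep]; cols <- col(m)[keep]; labv <- labv[keep]
  cr <- tapply(rows, labv, mean)
  cc <- tapply(cols, labv, mean)
  size <- tapply(rows, labv, length)
  centers <- cbind(as.integer(round(cr)) - 1L, as.integer(round(cc)) - 1L)
  new_detection(centers, as.numeric(size), rep(FALSE, nrow(centers)),
                threshold, method = "threshold")
}

#' @export
print.cell_detection <- function(x, ...) {
  cat(sprintf("%s detection: %d centers%s\n", x$method, x$count,
              if (is.finite(x$threshold))
                sprintf(" (threshold %.4g)", x$threshold) else ""))
  if (x$count > 0) {
    n <- min(x$count, 6L)
    df <- data.frame(row = x$centers[seq_len(n), 1],
                     col = x$centers[seq_len(n), 2],
                     score = signif(x$scores[seq_len(n)], 4),
                     border = x$border_flags[seq_len(n)])
    print(df, row.names = FALSE)
    if (x$count > n) cat("... and", x$count - n, "more\n")
  }
  invisible(x)
}

#' @export
summary.cell_detection <- function(object, ...) {
  cat(sprintf("%s detection: %d centers (%d on border margin)\n",
              object$method, object$count, sum(object$border_flags)))
  if (object$count > 0)
    print(summary(object$scores))
  invisible(object)
}

#' @export
plot.cell_detection <- function(x, image = NULL, ...) {
  if (is.null(image)) stop("pass the source image: plot(det, image = img)")
  plot(as_gray_image(unclass(image)), main = paste(x$method, "detections"))
  if (x$count > 0) {
    # gray_image plot maps col -> x in [0,1], row -> y (flipped)
    W <- ncol(image); H <- nrow(image)
    graphics::points((x$centers[, 2] + 0.5) / W,
                     1 - (x$centers[, 1] + 0.5) / H,
                     col = "red", pch = 3)
  }
  invisible(x)
}

#' Write detections as CSV
#'
#' Columns `image, row, col, score, border_flag`, coordinates 0-based. A
#' sidecar `<path>.json` records the run parameters when supplied.
#'
#' @param det A `cell_detection`.
#' @param path Output CSV path.
#' @param image_id Identifier put in the `image` column.
#' @param params Optional named list serialized as the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(det, path, image_id = "image", params = NULL) {
  df <- data.frame(image = rep(image_id, det$count),
                   row = det$centers[, 1], col = det$centers[, 2],
                   score = det$scores, border_flag = det$border_flags)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
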