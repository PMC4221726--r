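kind_code <- function(kind) {
  switch(kind, CI = 0L, SBF = 1L, TSBF = 2L,
         stop("unknown filter kind: ", kind))
}

#' Radial ray-sample offset tables
#'
#' Integer pixel offsets of every (support line, radius) sample used by the
#' band filters, plus the unit vector from each rounded sample back toward
#' the center. Line `i` (1-based) points along `phi = 2*pi*(i-1)/n_lines`;
#' the sample at radius `rad` sits at the rounded offset
#' `(round(rad*sin(phi)), round(rad*cos(phi)))` (R rounding, no
#' interpolation). Radii run from `r_min - floor(band_width/2)` to
#' `r_max + ceiling(band_width/2) - 1`, the union of all sliding-band
#' positions; nominal radii below 1 are flagged invalid and dropped from
#' band means.
#'
#' @param params A [filter_params()] object.
#' @return List with integer matrices `dr`, `dc` (`n_lines` x n_radii),
#'   unit-vector matrices `uy`, `ux`, the radius vector `rad`, validity
#'   flags `rad_ok` and the first nominal radius `rad_lo`.
#' @export
ray_offsets <- function(params) {
  stopifnot(inherits(params, "filter_params"))
  bw <- params$band_width
  rad_lo <- params$r_min - bw %/% 2L
  rad_hi <- params$r_max + as.integer(ceiling(bw / 2)) - 1L
  rad <- seq.int(rad_lo, rad_hi)
  phi <- 2 * pi * (seq_len(params$n_lines) - 1L) / params$n_lines
  dr <- round(outer(sin(phi), rad))
  dc <- round(outer(cos(phi), rad))
  len <- sqrt(dr^2 + dc^2)
  uy <- ifelse(len > 0, -dr / len, 0)
  ux <- ifelse(len > 0, -dc / len, 0)
  storage.mode(dr) <- "integer"
  storage.mode(dc) <- "integer"
  list(dr = dr, dc = dc, uy = uy, ux = ux, rad = rad,
       rad_ok = rad >= 1L, rad_lo = rad_lo)
}

as_center <- function(center) {
  center <- as.integer(round(center))
  if (length(center) != 2L || any(is.na(center)))
    stop("center must be a (row, col) pair")
  center
}

#' Convergence index over an arbitrary support
#'
#' Mean, over a set of support pixels, of the cosine of the angle between
#' the gradient vector at each support pixel and the direction from that
#' pixel toward the candidate center. Pixels with zero gradient magnitude
#' (and a support pixel coinciding with the center, whose direction is
#' undefined) contribute 0 but count in the denominator. Ranges over
#' \[-1, 1\]: +1 when every gradient points exactly at the center.
#'
#' @param grad A [compute_gradient()] result.
#' @param center `(row, col)` pixel, 1-based.
#' @param support Two-column matrix of `(row, col)` support pixels,
#'   1-based, all inside the image.
#' @return A scalar in \[-1, 1\].
#' @export
convergence_index <- function(grad, center, support) {
  stopifnot(inherits(grad, "gradient_field"))
  center <- as_center(center)
  support <- as.matrix(support)
  if (nrow(support) == 0L) stop("support must be non-empty")
  H <- nrow(grad$gx); W <- ncol(grad$gx)
  if (any(support[, 1] < 1 | support[, 1] > H |
          support[, 2] < 1 | support[, 2] > W))
    stop("support pixels must lie inside the image")
  dy <- center[1] - support[, 1]
  dx <- center[2] - support[, 2]
  len <- sqrt(dy^2 + dx^2)
  idx <- cbind(support[, 1], support[, 2])
  gy <- grad$gy[idx]; gx <- grad$gx[idx]
  mag <- sqrt(gy^2 + gx^2)
  ok <- mag > 0 & len > 0
  cosv <- numeric(nrow(support))
  cosv[ok] <- (gy[ok] * dy[ok] + gx[ok] * dx[ok]) / (mag[ok] * len[ok])
  mean(cosv)
}

point_band_response <- function(grad, center, params, kind) {
  stopifnot(inherits(grad, "gradient_field"))
  center <- as_center(center)
  H <- nrow(grad$gx); W <- ncol(grad$gx)
  if (any(center < 1L) || center[1] > H || center[2] > W)
    stop("center must lie inside the image")
  off <- ray_offsets(params)
  point_response_cpp(grad$gx, grad$gy, off$dr, off$dc, off$uy, off$ux,
                     off$rad_ok, off$rad_lo, params$r_min, params$r_max,
                     params$band_width, params$omega, kind_code(kind),
                     center[1] - 1L, center[2] - 1L)
}

#' Sliding band filter response at one pixel
#'
#' On each of `n_lines` radial support lines, a band of `band_width`
#' consecutive radial samples slides with its center between `r_min` and
#' `r_max`; the band score is the mean convergence cosine over its samples
#' (samples off the image are dropped and the mean renormalized), each line
#' contributes its maximum band score, and the response is the mean over
#' lines. Lies in \[-1, 1\]; large positive values mark centers of rounded
#' convex (dark-field) objects.
#'
#' @inheritParams convergence_index
#' @param params A [filter_params()] object.
#' @return A scalar in \[-1, 1\].
#' @export
sbf_response <- function(grad, center, params = filter_params())
  point_band_response(grad, center, params, "SBF")

#' Transformed sliding band filter response at one pixel
#'
#' Identical band geometry to [sbf_response()], but each sample scores
#' `omega * |cos(angle)| * |gradient|`: taking the absolute convergence
#' removes the sign flip between the inner (convergent) and outer
#' (divergent) edge of a bright-field cell membrane, and the gradient
#' magnitude weight concentrates the response on the membrane.
#' Non-negative by construction; scales linearly with image contrast.
#'
#' @inheritParams sbf_response
#' @return A non-negative scalar.
#' @export
tsbf_response <- function(grad, center, params = filter_params())
  point_band_response(grad, center, params, "TSBF")

#' Filter an image with a convergence-index family filter
#'
#' Applies the chosen per-pixel response at every pixel of the image:
#' `"TSBF"` (the bright-field cell detector), `"SBF"` (signed convergence,
#' sliding band), or `"CI"` (signed convergence over the fixed annulus
#' `r_min..r_max` on all lines). Ray offsets are precomputed once per
#' parameter set. Pixels closer than `r_max + ceiling(band_width/2)` to an
#' image edge are computed on the clipped support region and flagged as
#' border in the result.
#'
#' @param image Gray image matrix; both sides must be at least
#'   `2 * (r_max + band_width)` pixels.
#' @param params A [filter_params()] object.
#' @param kind `"TSBF"`, `"SBF"` or `"CI"`.
#' @param smoothing_sigma Gaussian pre-smoothing for the gradient
#'   (pixels).
#' @param grad Optional precomputed [compute_gradient()] result (overrides
#'   `smoothing_sigma`).
#' @return An object of class `response_map`: list with the response
#'   matrix `values`, `kind`, `params`, `smoothing_sigma`, the border
#'   margin `border_margin` and a logical `border` matrix.
#' @examples
#' sc <- generate_brightfield_scene(scene_spec(n_cells = 2, seed = 1))
#' rm <- filter_image(sc$image, filter_params(), "TSBF")
#' which(rm$values == max(rm$values), arr.ind = TRUE)
#' @export
filter_image <- function(image, params = filter_params(),
                         kind = c("TSBF", "SBF", "CI"),
                         smoothing_sigma = 1, grad = NULL) {
  kind <- match.arg(kind)
  m <- unclass(image)
  if (!is.matrix(m)) stop("image must be a matrix")
  min_side <- 2L * (params$r_max + params$band_width)
  if (nrow(m) < min_side || ncol(m) < min_side)
    stop(sprintf("image (%d x %d) too small for the filter support: both sides must be >= %d",
                 nrow(m), ncol(m), min_side))
  if (is.null(grad)) grad <- compute_gradient(m, smoothing_sigma)
  off <- ray_offsets(params)
  values <- response_map_cpp(grad$gx, grad$gy, off$dr, off$dc, off$uy,
                             off$ux, off$rad_ok, off$rad_lo, params$r_min,
                             params$r_max, params$band_width, params$omega,
                             kind_code(kind))
  margin <- params$r_max + as.integer(ceiling(params$band_width / 2))
  border <- matrix(FALSE, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)); ci <- seq_len(ncol(m))
  border[ri <= margin | ri > nrow(m) - margin, ] <- TRUE
  border[, ci <= margin | ci > ncol(m) - margin] <- TRUE
  structure(list(values = values, kind = kind, params = params,
                 smoothing_sigma = smoothing_sigma,
                 border_margin = margin, border = border),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("%s response map: %d x %d, values in [%.4g, %.4g], border margin %d px\n",
              x$kind, nrow(x$values), ncol(x$values), min(x$values),
              max(x$values), x$border_margin))
  invisible(x)
}

#' @export
plot.response_map <- function(x, ...) {
  plot(as_gray_image(x$values, normalize = TRUE),
       main = paste(x$kind, "response"), ...)
  invisible(x)
}
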