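#' Separable Gaussian smoothing with replicate edges
#'
#' Direct (non-FFT) separable convolution with a normalized Gaussian kernel
#' truncated at 3 sigma, replicating edge pixels. The direct form keeps a
#' constant image exactly constant, so flat fields yield exactly zero
#' gradients downstream.
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns `m`
#'   unchanged.
#' @return Smoothed matrix.
#' @keywords internal
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  w <- dnorm(seq.int(-r, r), sd = sigma)
  w <- w / sum(w)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (k in seq.int(-r, r)) {
    idx <- pmin(pmax(seq_len(H) + k, 1L), H)
    out <- out + w[k + r + 1L] * m[idx, , drop = FALSE]
  }
  m2 <- out
  out <- matrix(0, H, W)
  for (k in seq.int(-r, r)) {
    idx <- pmin(pmax(seq_len(W) + k, 1L), W)
    out <- out + w[k + r + 1L] * m2[, idx, drop = FALSE]
  }
  out
}

#' Image gradient field
#'
#' Central-difference gradients of the (optionally Gaussian-smoothed) image.
#' `gx` is the gradient along columns, `gy` along rows, both in intensity
#' per pixel; border gradients use one-sided differences on replicated
#' edges. `angle` is `atan2(gy, gx)` in (-pi, pi\], flagged `NA` where the
#' magnitude is zero (such pixels contribute 0 to every convergence score).
#'
#' @param image Gray image matrix (at least 3x3).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels (>= 0);
#'   default 1.
#' @return An object of class `gradient_field` with elements `gx`, `gy`,
#'   `magnitude`, `angle`.
#' @examples
#' g <- compute_gradient(as_gray_image(matrix(runif(64^2), 64)), 1)
#' range(g$magnitude)
#' @export
compute_gradient <- function(image, smoothing_sigma = 1) {
  m <- unclass(image)
  if (!is.matrix(m) || nrow(m) < 3L || ncol(m) < 3L)
    stop("image must be a matrix of at least 3 x 3 pixels")
  if (!all(is.finite(m))) stop("image contains non-finite values")
  if (!is.numeric(smoothing_sigma) || smoothing_sigma < 0)
    stop("smoothing_sigma must be >= 0")
  ms <- smooth_gaussian(m, smoothing_sigma)
  H <- nrow(ms); W <- ncol(ms)
  up    <- ms[pmax(seq_len(H) - 1L, 1L), , drop = FALSE]
  down  <- ms[pmin(seq_len(H) + 1L, H), , drop = FALSE]
  left  <- ms[, pmax(seq_len(W) - 1L, 1L), drop = FALSE]
  right <- ms[, pmin(seq_len(W) + 1L, W), drop = FALSE]
  gy <- (down - up) / 2
  gx <- (right - left) / 2
  magnitude <- sqrt(gx^2 + gy^2)
  angle <- atan2(gy, gx)
  angle[magnitude == 0] <- NA_real_
  structure(list(gx = gx, gy = gy, magnitude = magnitude, angle = angle,
                 smoothing_sigma = smoothing_sigma),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("Gradient field: %d x %d, |g| in [%.4g, %.4g] (sigma = %g)\n",
              nrow(x$gx), ncol(x$gx), min(x$magnitude), max(x$magnitude),
              x$smoothing_sigma))
  invisible(x)
}
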