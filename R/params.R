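#' Band-filter parameters
#'
#' The five knobs shared by the sliding band filter (SBF) and its transformed
#' variant (TSBF). Radial support lines are cast from each candidate center;
#' on each line a band of `band_width` consecutive integer radii slides with
#' its center between `r_min` and `r_max`.
#'
#' Defaults follow the reference insect-cell setting: minimum and maximum
#' cell radius 8 and 30 pixels, 32 support lines, band width 6 pixels
#' (matching the apparent membrane width), and unit gradient weight
#' `omega = 1`.
#'
#' @param r_min Integer >= 1. Smallest band-center radius, in pixels.
#' @param r_max Integer > `r_min`. Largest band-center radius, in pixels.
#' @param n_lines Integer >= 4. Number of radial support lines.
#' @param band_width Integer >= 1 and <= `r_max - r_min + 1`. Number of
#'   consecutive radial samples in the sliding band.
#' @param omega Non-negative scalar weight applied to every TSBF sample
#'   score; intended as a global gain for dim or unevenly lit acquisitions.
#' @return An object of class `filter_params`.
#' @examples
#' filter_params()
#' filter_params(r_min = 4, r_max = 12, band_width = 3)
#' @export
filter_params <- function(r_min = 8L, r_max = 30L, n_lines = 32L,
                          band_width = 6L, omega = 1) {
  r_min <- as.integer(r_min); r_max <- as.integer(r_max)
  n_lines <- as.integer(n_lines); band_width <- as.integer(band_width)
  if (is.na(r_min) || r_min < 1L) stop("r_min must be an integer >= 1")
  if (is.na(r_max) || r_max <= r_min) stop("r_max must be an integer > r_min")
  if (is.na(n_lines) || n_lines < 4L) stop("n_lines must be an integer >= 4")
  if (is.na(band_width) || band_width < 1L || band_width > r_max - r_min + 1L)
    stop("band_width must be an integer in [1, r_max - r_min + 1]")
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega < 0)
    stop("omega must be a single finite value >= 0")
  structure(list(r_min = r_min, r_max = r_max, n_lines = n_lines,
                 band_width = band_width, omega = as.numeric(omega)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "Band filter parameters: r_min=%d r_max=%d n_lines=%d band_width=%d omega=%g\n",
    x$r_min, x$r_max, x$n_lines, x$band_width, x$omega))
  invisible(x)
}

#' Non-maximum suppression parameters
#'
#' Detected centers are pixels that strictly dominate their
#' `(2 * window_half_width + 1)^2` neighbourhood and exceed a response
#' threshold. The default window half-width equals the minimum cell radius
#' of [filter_params()] (window side 17 for `r_min = 8`): two true centers
#' closer than one minimum radius cannot be distinct cells. The default
#' threshold is `mean + 2 * sd` of the response map, which suppresses
#' background maxima due to noise.
#'
#' @param window_half_width Integer >= 1; half-width of the square NMS
#'   window (window side is `2 * window_half_width + 1`).
#' @param threshold_mode One of `"mean_plus_k_std"`, `"absolute"`,
#'   `"fraction_of_max"`.
#' @param threshold_value Meaning depends on the mode: the `k` in
#'   mean + k*sd (default 2), an absolute response value, or a fraction of
#'   the map maximum in (0, 1].
#' @return An object of class `nms_params`.
#' @examples
#' nms_params()
#' nms_params(threshold_mode = "absolute", threshold_value = 0.05)
#' @export
nms_params <- function(window_half_width = 8L,
                       threshold_mode = c("mean_plus_k_std", "absolute",
                                          "fraction_of_max"),
                       threshold_value = NULL) {
  window_half_width <- as.integer(window_half_width)
  if (is.na(window_half_width) || window_half_width < 1L)
    stop("window_half_width must be an integer >= 1")
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(threshold_value))
    threshold_value <- switch(threshold_mode,
                              mean_plus_k_std = 2,
                              absolute = 0,
                              fraction_of_max = 0.5)
  if (!is.numeric(threshold_value) || length(threshold_value) != 1L ||
      !is.finite(threshold_value))
    stop("threshold_value must be a single finite number")
  structure(list(window_half_width = window_half_width,
                 threshold_mode = threshold_mode,
                 threshold_value = as.numeric(threshold_value)),
            class = "nms_params")
}

#' @export
print.nms_params <- function(x, ...) {
  cat(sprintf("NMS parameters: window side %d, threshold %s (%g)\n",
              2L * x$window_half_width + 1L, x$threshold_mode,
              x$threshold_value))
  invisible(x)
}
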