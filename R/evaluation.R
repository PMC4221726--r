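#' Hemocytometer chamber density
#'
#' Converts a mean per-square cell count into a suspension density in
#' cells/mL. A counting-chamber square of `region_area` mm^2 at
#' `chamber_depth` mm holds `region_area * chamber_depth` mm^3 = that
#' volume / 1000 mL, so
#' `density = count * dilution_factor * 1000 / (region_area * chamber_depth)`.
#' With the standard chamber (1 mm^2 squares, 0.1 mm depth) this is the
#' familiar count x 10^4 per mL before dilution.
#'
#' @param mean_count_per_region Mean cell count per chamber square (>= 0).
#' @param region_area Square area in mm^2 (default 1).
#' @param chamber_depth Chamber depth in mm (default 0.1).
#' @param dilution_factor Dilution applied before loading (>= 1 typically).
#' @return Density in cells/mL.
#' @examples
#' cells_per_ml(200) # 2e6 cells/mL
#' @export
cells_per_ml <- function(mean_count_per_region, region_area = 1,
                         chamber_depth = 0.1, dilution_factor = 1) {
  if (any(mean_count_per_region < 0)) stop("counts must be >= 0")
  if (region_area <= 0 || chamber_depth <= 0 || dilution_factor <= 0)
    stop("region_area, chamber_depth and dilution_factor must be > 0")
  mean_count_per_region * dilution_factor * 1000 /
    (region_area * chamber_depth)
}

#' Relative count error at one density
#'
#' `|method - ground truth| / ground truth`, the per-density error rate of
#' an automated count against the reference count.
#'
#' @param gt_density Ground-truth density (> 0).
#' @param method_density Method-estimated density (>= 0).
#' @return Non-negative fraction.
#' @export
error_rate <- function(gt_density, method_density) {
  if (any(gt_density <= 0))
    stop("error rate undefined for ground-truth density <= 0")
  abs(method_density - gt_density) / gt_density
}

#' Total error rate over a density series
#'
#' Unweighted mean of [error_rate()] over all `(ground truth, method)`
#' rows, the single-number summary of counting accuracy across the
#' sampled densities.
#'
#' @param report_rows Two-column matrix or data frame: ground-truth
#'   density, method density. At least one row.
#' @return Non-negative fraction.
#' @export
total_error_rate <- function(report_rows) {
  report_rows <- as.matrix(report_rows)
  if (nrow(report_rows) == 0L) stop("report_rows must have at least one row")
  mean(error_rate(report_rows[, 1], report_rows[, 2]))
}

#' A hemocytometer counting record
#'
#' One sample at one timepoint: per-square counts over the counted chamber
#' regions (classically squares A1..A5), with the density derived by
#' [cells_per_ml()] from their mean.
#'
#' @param sample_id Sample label.
#' @param timepoint Hours since seeding.
#' @param region_counts Integer vector of per-square counts.
#' @param dilution_factor,chamber_depth,region_area See [cells_per_ml()].
#' @return An object of class `count_record` (includes `$density`).
#' @export
count_record <- function(sample_id, timepoint, region_counts,
                         dilution_factor = 1, chamber_depth = 0.1,
                         region_area = 1) {
  region_counts <- as.numeric(region_counts)
  if (length(region_counts) == 0L || any(region_counts < 0) ||
      any(region_counts != round(region_counts)))
    stop("region_counts must be non-negative integers")
  density <- cells_per_ml(mean(region_counts), region_area, chamber_depth,
                          dilution_factor)
  structure(list(sample_id = as.character(sample_id),
                 timepoint = as.numeric(timepoint),
                 region_counts = region_counts,
                 dilution_factor = dilution_factor,
                 chamber_depth = chamber_depth, region_area = region_area,
                 density = density),
            class = "count_record")
}

#' Read a counting table
#'
#' Reads a CSV of manual or automated chamber counts with columns
#' `sample_id, timepoint_h, region, count` and optionally `dilution`
#' (default 1), one row per counted chamber square, and assembles one
#' [count_record()] per `(sample_id, timepoint_h)` pair.
#'
#' @param path CSV path.
#' @param chamber_depth,region_area Chamber geometry passed to
#'   [count_record()].
#' @return A list of `count_record` objects (input order of first
#'   appearance).
#' @export
read_count_records <- function(path, chamber_depth = 0.1, region_area = 1) {
  if (!file.exists(path)) stop("counting table not found: ", path)
  df <- read.csv(path)
  need <- c("sample_id", "timepoint_h", "region", "count")
  if (!all(need %in% names(df)))
    stop("counting table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$dilution)) df$dilution <- 1
  key <- paste(df$sample_id, df$timepoint_h, sep = "\r")
  lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    if (length(unique(rows$dilution)) != 1L)
      stop("inconsistent dilution within sample ", rows$sample_id[1],
           " at t = ", rows$timepoint_h[1])
    count_record(rows$sample_id[1], rows$timepoint_h[1], rows$count,
                 dilution_factor = rows$dilution[1],
                 chamber_depth = chamber_depth, region_area = region_area)
  })
}

#' Growth curve from counting records
#'
#' Averages densities across same-timepoint samples and orders by
#' timepoint. Duplicate `(sample_id, timepoint)` pairs are an error (a
#' sample is counted once per timepoint).
#'
#' @param records List of [count_record()] objects, at least two distinct
#'   timepoints.
#' @return Data frame with columns `timepoint`, `density`, `n_samples`.
#' @export
growth_curve <- function(records) {
  if (!is.list(records) || length(records) == 0L ||
      !all(vapply(records, inherits, TRUE, "count_record")))
    stop("records must be a list of count_record objects")
  ids <- vapply(records, `[[`, "", "sample_id")
  tps <- vapply(records, `[[`, 0, "timepoint")
  if (anyDuplicated(paste(ids, tps)))
    stop("duplicate (sample_id, timepoint) record")
  if (length(unique(tps)) < 2L)
    stop("need at least 2 distinct timepoints")
  dens <- vapply(records, `[[`, 0, "density")
  agg <- aggregate(dens, by = list(timepoint = tps),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(timepoint = agg$timepoint, density = agg$x[, 1],
                    n_samples = as.integer(agg$x[, 2]))
  out[order(out$timepoint), , drop = FALSE]
}

#' Match detected centers to planted truth
#'
#' Greedy nearest-first one-to-one matching: candidate pairs within
#' `tolerance` are sorted by distance (ties broken by detection index,
#' then truth index) and accepted while both endpoints are unmatched.
#' `tp + fn` equals the number of planted cells and `tp + fp` the number
#' of detections.
#'
#' @param detected A `cell_detection` or 0-based `(row, col)` matrix.
#' @param truth A `synthetic_scene` or 0-based `(row, col)` matrix.
#' @param tolerance Maximum matching distance in pixels (> 0).
#' @return List with `tp`, `fp`, `fn` and a `pairs` matrix
#'   (detection index, truth index, distance).
#' @export
match_centers <- function(detected, truth, tolerance = 3) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  det <- if (inherits(detected, "cell_detection")) detected$centers else
    as.matrix(detected)
  tru <- if (inherits(truth, "synthetic_scene")) truth$centers else
    as.matrix(truth)
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0L || nt == 0L)
    return(list(tp = 0L, fp = nd, fn = nt,
                pairs = matrix(numeric(), 0, 3,
                               dimnames = list(NULL, c("det", "truth", "dist")))))
  dmat <- sqrt(outer(det[, 1], tru[, 1], `-`)^2 +
               outer(det[, 2], tru[, 2], `-`)^2)
  cand <- which(dmat <= tolerance, arr.ind = TRUE)
  ord <- order(dmat[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  pairs <- matrix(numeric(), 0, 3,
                  dimnames = list(NULL, c("det", "truth", "dist")))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE
      pairs <- rbind(pairs, c(i, j, dmat[i, j]))
    }
  }
  tp <- sum(used_d)
  list(tp = tp, fp = nd - tp, fn = nt - tp, pairs = pairs)
}

#' Run the detector over a benchmark and score it
#'
#' Applies the TSBF pipeline ([detect_cells()]) to every scene of a
#' [generate_benchmark()] result and reports, per image, the planted and
#' detected counts, the relative count error, and center-matching
#' diagnostics, plus the total error rate (mean per-image relative error).
#'
#' @param bench A `scene_benchmark`.
#' @param filter_params,nms_params,smoothing_sigma Passed to
#'   [detect_cells()].
#' @param match_tolerance Pixel tolerance for [match_centers()]
#'   diagnostics.
#' @param detector Detection function `(image) -> cell_detection`;
#'   defaults to the TSBF pipeline with the given parameters. Supplying
#'   e.g. a baseline closure scores that detector instead.
#' @return An object of class `tsbf_error_report`: `per_image` data frame
#'   (image, n_true, n_detected, ert, tp, fp, fn), `tert`, `n_images`.
#' @export
run_benchmark <- function(bench, filter_params = tsbf::filter_params(),
                          nms_params = tsbf::nms_params(),
                          smoothing_sigma = 1, match_tolerance = 3,
                          detector = NULL) {
  stopifnot(inherits(bench, "scene_benchmark"))
  if (is.null(detector))
    detector <- function(img) detect_cells(img, filter_params, nms_params,
                                           smoothing_sigma)
  rows <- lapply(seq_along(bench$scenes), function(i) {
    sc <- bench$scenes[[i]]
    det <- detector(sc$image)
    m <- match_centers(det, sc, match_tolerance)
    data.frame(image = sprintf("scene_%03d", i),
               n_true = nrow(sc$centers), n_detected = det$count,
               ert = error_rate(nrow(sc$centers), det$count),
               tp = m$tp, fp = m$fp, fn = m$fn)
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 tert = mean(per_image$ert),
                 n_images = nrow(per_image)),
            class = "tsbf_error_report")
}

#' @export
print.tsbf_error_report <- function(x, ...) {
  cat(sprintf("Counting error report over %d images\n", x$n_images))
  print(x$per_image, row.names = FALSE)
  cat(sprintf("TERT (mean relative count error): %.4f (%.2f%%)\n",
              x$tert, 100 * x$tert))
  invisible(x)
}
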