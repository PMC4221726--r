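test_that("NMS finds unique peaks and applies the lexicographic plateau rule", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  det <- non_max_suppression(m, nms_params(1, "absolute", 0.5))
  expect_equal(det$count, 1L)
  expect_equal(det$centers[1, ], c(row = 2, col = 2))  # 0-based

  # constant map: mean + k*sd threshold excludes everything
  expect_equal(non_max_suppression(matrix(0.4, 9, 9), nms_params(2))$count, 0L)

  # two equal peaks inside one window: lexicographically first survives
  m <- matrix(0, 9, 9); m[3, 3] <- 1; m[3, 5] <- 1
  det <- non_max_suppression(m, nms_params(2, "absolute", 0.5))
  expect_equal(det$count, 1L)
  expect_equal(det$centers[1, ], c(row = 2, col = 2))

  expect_error(non_max_suppression(matrix(c(1, NA, 1, 1), 2)), "non-finite")
})

test_that("NMS equals a direct window scan on random maps", {
  set.seed(123)
  for (rep in 1:30) {
    # quantized values generate tied plateaus on purpose
    v <- round(matrix(runif(32 * 32), 32), digits = sample(1:2, 1))
    half <- sample(1:4, 1)
    thr <- runif(1, 0.2, 0.8)
    det <- non_max_suppression(v, nms_params(half, "absolute", thr))
    ref <- oracle_nms(v, half, thr)
    expect_equal(det$count, nrow(ref))
    if (det$count > 0) {
      got <- det$centers[order(det$centers[, 1], det$centers[, 2]), , drop = FALSE]
      ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(ref[, 1:2, drop = FALSE]))
    }
  }
})

test_that("NMS separation, threshold monotonicity and idempotence hold", {
  set.seed(5)
  for (rep in 1:10) {
    v <- matrix(runif(40 * 40), 40)
    half <- sample(2:5, 1)
    det <- non_max_suppression(v, nms_params(half, "absolute", 0.3))
    if (det$count > 1) {
      dch <- as.matrix(dist(det$centers, method = "maximum"))
      expect_gte(min(dch[upper.tri(dch)]), half + 1)
    }
    # raising the threshold never adds centers
    counts <- vapply(c(0.2, 0.5, 0.8), function(t)
      non_max_suppression(v, nms_params(half, "absolute", t))$count, 0L)
    expect_true(all(diff(counts) <= 0))
    # idempotence on the sparsified map
    if (det$count > 0) {
      v2 <- matrix(0, 40, 40)
      v2[det$centers + 1L] <- det$scores
      det2 <- non_max_suppression(v2, nms_params(half, "absolute", 0.3))
      expect_equal(sort(det2$centers[, 1] * 40 + det2$centers[, 2]),
                   sort(det$centers[, 1] * 40 + det$centers[, 2]))
    }
  }
})

test_that("the TSBF pipeline detects planted cells", {
  expect_equal(detect_cells(matrix(0.5, 80, 80))$count, 0L)

  sc1 <- generate_brightfield_scene(scene_spec(n_cells = 1, seed = 1))
  det1 <- detect_cells(sc1$image)
  expect_equal(det1$count, 1L)
  expect_lte(sqrt(sum((det1$centers[1, ] - sc1$centers[1, ])^2)), 3)

  sc15 <- generate_brightfield_scene(scene_spec(n_cells = 15, seed = 4))
  det15 <- detect_cells(sc15$image)
  expect_lte(abs(det15$count - 15L), 1L)
  m <- match_centers(det15, sc15, tolerance = 5)
  expect_gte(m$tp, 13L)
})

test_that("LoG baseline finds an isolated dark-field blob at its peak", {
  expect_equal(detect_cells_log_baseline(matrix(0.5, 64, 64), 5)$count, 0L)
  sp <- scene_spec(height = 128, width = 128, n_cells = 1,
                   radius_range = c(12, 12), background_level = 0.1,
                   seed = 6)
  sp$noise_sigma <- 0
  sc <- generate_darkfield_scene(sp)
  det <- detect_cells_log_baseline(sc$image, sigma = 6,
                                   nms_params(8, "fraction_of_max", 0.5))
  expect_equal(det$count, 1L)
  expect_lte(sqrt(sum((det$centers[1, ] - sc$centers[1, ])^2)), 2)
})

test_that("intensity-threshold baseline reports component centroids", {
  expect_equal(detect_cells_threshold_baseline(matrix(0.9, 30, 30), 0.5)$count, 0L)

  # solid dark disc: centroid is the disc center
  m <- matrix(1, 64, 64)
  d <- sqrt((row(m) - 30)^2 + (col(m) - 41)^2)
  m[d <= 10] <- 0.1
  det <- detect_cells_threshold_baseline(m, 0.5)
  expect_equal(det$count, 1L)
  expect_lte(max(abs(det$centers[1, ] - c(29, 40))), 1)  # 0-based
  expect_equal(det$scores[1], sum(d <= 10))

  # ring cell: the foreground component is the membrane annulus, not the body
  sp <- scene_spec(n_cells = 1, radius_range = c(15, 15), seed = 2)
  sp$noise_sigma <- 0
  sc <- generate_brightfield_scene(sp)
  detr <- detect_cells_threshold_baseline(sc$image, 0.5)
  expect_equal(detr$count, 1L)
  ctr <- sc$centers[1, ]
  dd <- sqrt((row(sc$image) - 1 - ctr[1])^2 + (col(sc$image) - 1 - ctr[2])^2)
  fg <- unclass(sc$image) < 0.5
  expect_true(all(abs(dd[fg] - sc$radii[1]) <= sp$membrane_thickness / 2 +
                    3 * sp$blur_sigma))
  expect_lt(detr$scores[1], sum(dd <= sc$radii[1]))  # annulus, not full disc
})

test_that("detections serialize to CSV with parameter sidecar", {
  sc <- generate_brightfield_scene(scene_spec(n_cells = 2, seed = 3))
  det <- detect_cells(sc$image)
  path <- tempfile(fileext = ".csv")
  write_detections_csv(det, path, image_id = "s1",
                       params = list(r_min = 8))
  df <- read.csv(path)
  expect_equal(nrow(df), det$count)
  expect_named(df, c("image", "row", "col", "score", "border_flag"))
  expect_true(file.exists(paste0(path, ".json")))
})
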