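# small parameter set keeps brute-force comparisons fast
small_params <- filter_params(r_min = 4, r_max = 12, n_lines = 16,
                              band_width = 3)

fake_grad <- function(gy, gx) {
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
                 angle = atan2(gy, gx), smoothing_sigma = 0),
            class = "gradient_field")
}

test_that("convergence index is +/-1 for perfectly convergent/divergent fields", {
  n <- 21
  ctr <- c(11, 11)
  dy <- ctr[1] - row(diag(n)); dx <- ctr[2] - col(diag(n))
  len <- sqrt(dy^2 + dx^2); len[ctr[1], ctr[2]] <- 1
  g_in <- fake_grad(dy / len, dx / len)   # gradients point at the center
  d <- sqrt(dy^2 + dx^2)
  support <- which(d >= 3 & d <= 8, arr.ind = TRUE)
  expect_equal(convergence_index(g_in, ctr, support), 1)
  g_out <- fake_grad(-dy / len, -dx / len)
  expect_equal(convergence_index(g_out, ctr, support), -1)

  # zero-gradient pixels contribute 0 but stay in the denominator
  g_half <- g_in
  g_half$gx[support[1, 1], support[1, 2]] <- 0
  g_half$gy[support[1, 1], support[1, 2]] <- 0
  g_half$magnitude <- sqrt(g_half$gx^2 + g_half$gy^2)
  expect_equal(convergence_index(g_half, ctr, support),
               (nrow(support) - 1) / nrow(support))

  expect_error(convergence_index(g_in, ctr, support[0, ]), "non-empty")
  expect_error(convergence_index(g_in, ctr, matrix(c(0, 5), 1)), "inside")
})

test_that("an ideal dark-field Gaussian blob has near-perfect convergence at its peak", {
  gb <- gaussian_bump(64, c(33, 33), sigma_b = 5)
  g <- compute_gradient(gb$img, smoothing_sigma = 0)
  d <- sqrt(gb$dr^2 + gb$dc^2)
  support <- which(d >= 3 & d <= 8, arr.ind = TRUE)
  expect_gte(convergence_index(g, c(33, 33), support), 0.99)
  # sliding band at the peak is also near its maximum
  expect_gte(sbf_response(g, c(33, 33), filter_params(3, 9, 16, 3)), 0.9)
})

test_that("band responses equal the brute-force triple-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    img <- matrix(runif(40 * 40), 40)
    g <- compute_gradient(img, smoothing_sigma = 1)
    for (k in 1:4) {
      ctr <- c(sample(5:36, 1), sample(5:36, 1))
      expect_lt(abs(sbf_response(g, ctr, small_params) -
                      oracle_band_response(g, ctr, small_params, "SBF")),
                1e-12)
      expect_lt(abs(tsbf_response(g, ctr, small_params) -
                      oracle_band_response(g, ctr, small_params, "TSBF")),
                1e-12)
    }
  }
  # default parameter set, support clipped at the frame
  img <- matrix(runif(80 * 80), 80)
  g <- compute_gradient(img, 1)
  for (ctr in list(c(40, 40), c(3, 78))) {
    expect_lt(abs(sbf_response(g, ctr) - oracle_band_response(g, ctr, filter_params(), "SBF")), 1e-12)
    expect_lt(abs(tsbf_response(g, ctr) - oracle_band_response(g, ctr, filter_params(), "TSBF")), 1e-12)
  }
})

test_that("flat images give exactly zero band responses everywhere", {
  flat <- matrix(0.5, 80, 80)
  g <- compute_gradient(flat, 1)
  expect_identical(sbf_response(g, c(40, 40)), 0)
  expect_identical(tsbf_response(g, c(40, 40)), 0)
  rmap <- filter_image(flat, filter_params(), "TSBF")
  expect_true(all(rmap$values == 0))
})

test_that("TSBF is contrast-equivariant and SBF contrast-invariant", {
  set.seed(7)
  img <- matrix(runif(48 * 48), 48)
  base_t <- filter_image(img, small_params, "TSBF")$values
  base_s <- filter_image(img, small_params, "SBF")$values
  for (a in c(0.5, 2, 10)) {
    for (b in c(0, 0.1)) {
      vt <- filter_image(a * img + b, small_params, "TSBF")$values
      expect_lt(max(abs(vt - a * base_t)) / max(a * base_t), 1e-9)
      vs <- filter_image(a * img + b, small_params, "SBF")$values
      expect_lt(max(abs(vs - base_s)), 1e-9)
    }
  }
})

test_that("filter responses respect their analytic ranges", {
  set.seed(11)
  for (rep in 1:3) {
    img <- matrix(runif(48 * 48), 48)
    ci <- filter_image(img, small_params, "CI")$values
    sb <- filter_image(img, small_params, "SBF")$values
    tb <- filter_image(img, small_params, "TSBF")$values
    expect_true(all(ci >= -1 & ci <= 1))
    expect_true(all(sb >= -1 & sb <= 1))
    expect_true(all(tb >= 0))
  }
})

test_that("TSBF response maps commute with 90-degree rotation", {
  set.seed(9)
  img <- matrix(runif(64 * 64), 64)
  rot90 <- function(m) t(m[nrow(m):1, ])
  a <- filter_image(img, small_params, "TSBF")$values
  b <- filter_image(rot90(img), small_params, "TSBF")$values
  expect_lt(max(abs(b - rot90(a))), 1e-9)
})

test_that("a planted ring cell's center dominates all pixels one cell-radius away", {
  sp <- scene_spec(n_cells = 1, radius_range = c(15, 15), seed = 2)
  sp$noise_sigma <- 0
  sc <- generate_brightfield_scene(sp)
  rmap <- filter_image(sc$image, filter_params(), "TSBF")
  ctr <- sc$centers[1, ]
  d <- sqrt((row(rmap$values) - 1 - ctr[1])^2 +
              (col(rmap$values) - 1 - ctr[2])^2)
  expect_gt(rmap$values[ctr[1] + 1, ctr[2] + 1], max(rmap$values[d >= 8]))
})

test_that("border handling: margin is flagged and undersized images error", {
  expect_error(filter_image(matrix(0.5, 40, 40), filter_params()),
               "too small")
  rmap <- filter_image(matrix(0.5, 80, 80), filter_params(), "TSBF")
  expect_identical(rmap$border_margin, 33L)
  expect_true(rmap$border[1, 1] && rmap$border[33, 50])
  expect_false(rmap$border[40, 40])
})
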