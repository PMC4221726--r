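#' Synthetic scene specification
#'
#' Parameters of the synthetic microscopy scene generator. The bright-field
#' model renders each cell as a dark membrane annulus of the given
#' thickness and contrast on a mid-gray background, with the interior
#' offset slightly from the background (the cytoplasm of an unstained cell
#' is nearly invisible); the dark-field model renders bright Gaussian
#' blobs. Optical blur, an optional linear illumination ramp and additive
#' Gaussian noise are applied on top. All randomness is governed by `seed`.
#'
#' @param height,width Image size in pixels.
#' @param n_cells Number of cells to plant.
#' @param radius_range `(min, max)` cell radius in pixels; must lie within
#'   `[1, min(height, width)/4]`.
#' @param membrane_thickness Membrane annulus thickness in pixels.
#' @param membrane_contrast Intensity drop of the membrane below the
#'   background, in (0, 1\]; must exceed `noise_sigma` so planted cells are
#'   distinguishable by construction.
#' @param interior_offset Signed intensity offset of the cell interior
#'   relative to the background.
#' @param background_level Background intensity in \[0, 1\].
#' @param blur_sigma Gaussian optical blur sigma in pixels.
#' @param noise_sigma Additive Gaussian noise sigma (intensity units).
#' @param illumination_gradient Maximum fractional shading across the
#'   frame (0 disables the ramp).
#' @param min_center_separation Floor on pairwise center distance in
#'   pixels; placement additionally enforces per-pair non-overlap
#'   (`r_i + r_j + 2 * membrane_thickness + 2`). Default `2 * min radius + 4`.
#' @param seed Integer RNG seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L, n_cells = 15L,
                       radius_range = c(10, 22), membrane_thickness = 3,
                       membrane_contrast = 0.3, interior_offset = 0.02,
                       background_level = 0.6, blur_sigma = 1.5,
                       noise_sigma = 0.02, illumination_gradient = 0,
                       min_center_separation = NULL, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  n_cells <- as.integer(n_cells)
  if (height < 8L || width < 8L) stop("scene too small")
  if (n_cells < 0L) stop("n_cells must be >= 0")
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2])
    stop("radius_range must be (min, max)")
  if (radius_range[1] < 1 || radius_range[2] > min(height, width) / 4)
    stop("radius_range must lie within [1, min(height, width)/4]")
  if (membrane_contrast <= noise_sigma)
    stop("membrane_contrast must exceed noise_sigma")
  if (background_level < 0 || background_level > 1)
    stop("background_level must be in [0, 1]")
  if (is.null(min_center_separation))
    min_center_separation <- 2 * radius_range[1] + 4
  structure(list(height = height, width = width, n_cells = n_cells,
                 radius_range = as.numeric(radius_range),
                 membrane_thickness = as.numeric(membrane_thickness),
                 membrane_contrast = as.numeric(membrane_contrast),
                 interior_offset = as.numeric(interior_offset),
                 background_level = as.numeric(background_level),
                 blur_sigma = as.numeric(blur_sigma),
                 noise_sigma = as.numeric(noise_sigma),
                 illumination_gradient = as.numeric(illumination_gradient),
                 min_center_separation = as.numeric(min_center_separation),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Scene spec: %d x %d, %d cells, radii [%g, %g] px, bg %.2f, contrast %.2f, blur %g, noise %g, seed %d\n",
    x$height, x$width, x$n_cells, x$radius_range[1], x$radius_range[2],
    x$background_level, x$membrane_contrast, x$blur_sigma, x$noise_sigma,
    x$seed))
  invisible(x)
}

# Largest-first rejection-sampling placement. Returns list(centers, radii)
# with centers 1-based continuous-free integer pixels.
place_cells <- function(spec) {
  n <- spec$n_cells
  if (n == 0L)
    return(list(centers = matrix(integer(), 0, 2), radii = numeric()))
  radii <- sort(runif(n, spec$radius_range[1], spec$radius_range[2]),
                decreasing = TRUE)
  centers <- matrix(NA_integer_, n, 2)
  th <- spec$membrane_thickness
  attempts <- 0L
  max_attempts <- 500L * n
  i <- 1L
  while (i <= n) {
    if (attempts >= max_attempts)
      stop(sprintf(
        "cell placement failed after %d attempts: cannot satisfy non-overlap/separation (n_cells = %d, separation floor = %g) in %d x %d",
        attempts, n, spec$min_center_separation, spec$height, spec$width))
    attempts <- attempts + 1L
    margin <- ceiling(radii[i] + th)
    if (spec$height - 2 * margin < 1 || spec$width - 2 * margin < 1)
      stop("cell placement failed: radius + membrane_thickness margin exceeds the frame")
    p <- c(round(runif(1, margin + 1, spec$height - margin)),
           round(runif(1, margin + 1, spec$width - margin)))
    ok <- TRUE
    if (i > 1L) {
      prev <- centers[seq_len(i - 1L), , drop = FALSE]
      d <- sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2)
      need <- pmax(radii[seq_len(i - 1L)] + radii[i] + 2 * th + 2,
                   spec$min_center_separation)
      ok <- all(d >= need)
    }
    if (ok) {
      centers[i, ] <- as.integer(p)
      i <- i + 1L
    }
  }
  list(centers = centers, radii = radii)
}

finish_scene <- function(img, spec, placed) {
  if (spec$illumination_gradient > 0) {
    ramp <- 1 + spec$illumination_gradient *
      ((seq_len(spec$width) - 1) / (spec$width - 1) - 0.5)
    img <- sweep(img, 2, ramp, `*`)
  }
  clean <- smooth_gaussian(img, spec$blur_sigma)
  noisy <- clean
  if (spec$noise_sigma > 0)
    noisy <- noisy + matrix(rnorm(length(noisy), sd = spec$noise_sigma),
                            nrow(noisy))
  noisy <- pmin(pmax(noisy, 0), 1)
  structure(list(image = as_gray_image(noisy), clean = clean,
                 centers = placed$centers - 1L,  # 0-based, like detections
                 radii = placed$radii, spec = spec),
            class = "synthetic_scene")
}

#' Generate a bright-field ring-cell scene
#'
#' Renders `n_cells` non-overlapping ring cells: a dark membrane annulus
#' (`|dist - radius| <= thickness/2`, intensity
#' `background - membrane_contrast`) around an interior at
#' `background + interior_offset`, then illumination ramp, Gaussian blur,
#' additive noise and clamping to \[0, 1\]. In the noise-free rendered
#' image the gradient converges toward each planted center just inside the
#' membrane and diverges just outside it -- the pattern the TSBF filter is
#' built for. Fully determined by `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `synthetic_scene`: `image` (noisy),
#'   `clean` (pre-noise), `centers` (0-based integer `(row, col)`),
#'   `radii`, `spec`.
#' @export
generate_brightfield_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    placed <- place_cells(spec)
    img <- matrix(spec$background_level, spec$height, spec$width)
    rowg <- row(img); colg <- col(img)
    for (i in seq_len(spec$n_cells)) {
      r <- placed$radii[i]; cy <- placed$centers[i, 1]; cx <- placed$centers[i, 2]
      half_th <- spec$membrane_thickness / 2
      ext <- ceiling(r + half_th + 1)
      rs <- max(1L, cy - ext):min(spec$height, cy + ext)
      cs <- max(1L, cx - ext):min(spec$width, cx + ext)
      d <- sqrt((rowg[rs, cs] - cy)^2 + (colg[rs, cs] - cx)^2)
      sub <- img[rs, cs]
      sub[d < r - half_th] <- spec$background_level + spec$interior_offset
      sub[abs(d - r) <= half_th] <- spec$background_level - spec$membrane_contrast
      img[rs, cs] <- sub
    }
    finish_scene(img, spec, placed)
  })
}

#' Generate a dark-field blob scene
#'
#' Renders cells as bright Gaussian blobs (peak height
#' `membrane_contrast`, spatial sigma `radius / 2`) added to a dark
#' background -- the classical rounded convex region whose gradients all
#' point at the center. Same illumination/blur/noise/determinism contracts
#' as [generate_brightfield_scene()].
#'
#' @param spec A [scene_spec()]; pass a low `background_level` (e.g. 0.1).
#' @return A `synthetic_scene`.
#' @export
generate_darkfield_scene <- function(spec = scene_spec(background_level = 0.1)) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    placed <- place_cells(spec)
    img <- matrix(spec$background_level, spec$height, spec$width)
    rowg <- row(img); colg <- col(img)
    for (i in seq_len(spec$n_cells)) {
      r <- placed$radii[i]; cy <- placed$centers[i, 1]; cx <- placed$centers[i, 2]
      d2 <- (rowg - cy)^2 + (colg - cx)^2
      img <- img + spec$membrane_contrast * exp(-d2 / (2 * (r / 2)^2))
    }
    img <- pmin(img, 1)
    finish_scene(img, spec, placed)
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d, %d planted cells (seed %d)\n",
              x$spec$height, x$spec$width, nrow(x$centers), x$spec$seed))
  invisible(x)
}

#' @export
plot.synthetic_scene <- function(x, truth = TRUE, ...) {
  plot(x$image, main = "synthetic scene")
  if (truth && nrow(x$centers) > 0)
    graphics::points((x$centers[, 2] + 0.5) / x$spec$width,
                     1 - (x$centers[, 1] + 0.5) / x$spec$height,
                     col = "green", pch = 1)
  invisible(x)
}

#' Generate a benchmark of synthetic scenes
#'
#' `n_images` scenes generated from `base_spec` with per-image seeds
#' `seed, seed + 1, ...` and per-image cell counts drawn uniformly from
#' `n_cells_range` (drawn up front under `seed`). A manifest data frame
#' records every planted cell. The default configuration (15 bright-field
#' images, 256 x 256, 10-20 cells of radius 10-22 px) is the package's
#' standing benchmark for the detector.
#'
#' @param n_images Number of scenes (>= 1).
#' @param base_spec A [scene_spec()] supplying everything but seed and
#'   cell count.
#' @param seed Integer master seed.
#' @param n_cells_range Integer `(min, max)` cells per image.
#' @param field `"bright"` or `"dark"`.
#' @return An object of class `scene_benchmark`: list with `scenes`,
#'   `manifest` (columns image, cell_id, row, col, radius), `seed`,
#'   `field`, `base_spec`.
#' @export
generate_benchmark <- function(n_images = 15L, base_spec = scene_spec(),
                               seed = 42L, n_cells_range = c(10L, 20L),
                               field = c("bright", "dark")) {
  field <- match.arg(field)
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("n_images must be >= 1")
  counts <- withr::with_seed(as.integer(seed),
    sample(seq.int(n_cells_range[1], n_cells_range[2]), n_images,
           replace = TRUE))
  gen <- if (field == "bright") generate_brightfield_scene else
    generate_darkfield_scene
  scenes <- vector("list", n_images)
  manifest <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- base_spec
    sp$n_cells <- counts[i]
    sp$seed <- as.integer(seed) + i - 1L
    scenes[[i]] <- gen(sp)
    manifest[[i]] <- data.frame(
      image = sprintf("scene_%03d", i),
      cell_id = seq_len(counts[i]),
      row = scenes[[i]]$centers[, 1],
      col = scenes[[i]]$centers[, 2],
      radius = scenes[[i]]$radii)
  }
  structure(list(scenes = scenes, manifest = do.call(rbind, manifest),
                 seed = as.integer(seed), field = field,
                 base_spec = base_spec),
            class = "scene_benchmark")
}

#' @export
print.scene_benchmark <- function(x, ...) {
  cat(sprintf("Scene benchmark: %d %s-field images, %d planted cells (seed %d)\n",
              length(x$scenes), x$field, nrow(x$manifest), x$seed))
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Scenes as 16-bit TIFF, the planted truth as `truth.csv`
#' (image, cell_id, row, col, radius; 0-based coordinates) and the base
#' spec as `spec.json`.
#'
#' @param bench A `scene_benchmark`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bench$scenes))
    write_image_tiff(bench$scenes[[i]]$image,
                     file.path(dir, sprintf("scene_%03d.tif", i)))
  manifest_path <- file.path(dir, "truth.csv")
  write.csv(bench$manifest, manifest_path, row.names = FALSE)
  sp <- bench$base_spec
  jsonlite::write_json(c(unclass(sp), list(master_seed = bench$seed,
                                           field = bench$field)),
                       file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest_path)
}
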