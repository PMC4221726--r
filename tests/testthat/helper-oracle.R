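# Independent brute-force oracles. These re-derive the band geometry from
# the documented conventions (rounded integer-radius ray samples, band of
# band_width consecutive radii centered at r in [r_min, r_max], clipped
# bands renormalized, toward-center cosine, zero-gradient terms = 0) as an
# explicit triple loop, deliberately sharing no code with the package
# internals.

oracle_band_response <- function(grad, center, params, kind = c("SBF", "TSBF")) {
  kind <- match.arg(kind)
  H <- nrow(grad$gx); W <- ncol(grad$gx)
  bw <- params$band_width
  line_scores <- numeric(params$n_lines)
  for (i in seq_len(params$n_lines)) {                    # lines
    phi <- 2 * pi * (i - 1) / params$n_lines
    best <- 0
    found <- FALSE
    for (r in params$r_min:params$r_max) {                # band positions
      ssum <- 0
      cnt <- 0L
      for (b in 0:(bw - 1L)) {                            # band samples
        rad <- r - floor(bw / 2) + b
        if (rad < 1) next
        dy <- round(rad * sin(phi)); dx <- round(rad * cos(phi))
        py <- center[1] + dy; px <- center[2] + dx
        if (py < 1 || py > H || px < 1 || px > W) next
        len <- sqrt(dy^2 + dx^2)
        gy <- grad$gy[py, px]; gx <- grad$gx[py, px]
        dot <- gy * (-dy / len) + gx * (-dx / len)
        s <- if (kind == "TSBF") {
          params$omega * abs(dot)
        } else {
          m <- sqrt(gy^2 + gx^2)
          if (m > 0) dot / m else 0
        }
        ssum <- ssum + s
        cnt <- cnt + 1L
      }
      if (cnt > 0L) {
        bscore <- ssum / cnt
        if (!found || bscore > best) { best <- bscore; found <- TRUE }
      }
    }
    line_scores[i] <- if (found) best else 0
  }
  mean(line_scores)
}

# Direct O(W*H*n^2) local-maximum scan with the same strict-greater +
# lexicographic plateau rule, written over the full window per pixel.
oracle_nms <- function(v, half, thr) {
  H <- nrow(v); W <- ncol(v)
  out <- NULL
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      x <- v[r, c]
      if (!(x > thr)) next
      keep <- TRUE
      for (rr in max(1, r - half):min(H, r + half)) {
        for (cc in max(1, c - half):min(W, c + half)) {
          if (rr == r && cc == c) next
          y <- v[rr, cc]
          if (y > x || (y == x && (rr < r || (rr == r && cc < c)))) {
            keep <- FALSE
            break
          }
        }
        if (!keep) break
      }
      if (keep) out <- rbind(out, c(r - 1L, c - 1L, x))
    }
  }
  if (is.null(out)) matrix(numeric(), 0, 3) else out
}

# Analytic isotropic Gaussian bump (peak 1) sampled on a grid, plus its
# exact discrete central-difference gradient in closed form.
gaussian_bump <- function(n, center, sigma_b) {
  d1 <- seq_len(n) - center[1]
  d2 <- seq_len(n) - center[2]
  a <- exp(-d1^2 / (2 * sigma_b^2))
  b <- exp(-d2^2 / (2 * sigma_b^2))
  img <- outer(a, b)
  s <- sigma_b^2
  k <- exp(-1 / (2 * s))
  list(img = img,
       gx = -img * k * rep(sinh(d2 / s), each = n),
       gy = -img * k * rep(sinh(d1 / s), times = n),
       dr = outer(d1, rep(1, n)), dc = outer(rep(1, n), d2))
}
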