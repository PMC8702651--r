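# Independent brute-force oracles and small synthetic fixtures.

# Naive quadruple-loop line-strength: for every pixel and orientation, walk
# the digital line explicitly and average in-bounds pixels; subtract the
# border-clipped square window mean.
brute_line_strength <- function(img, window_px, n_orientations = 12L,
                                angle_step_deg = 15) {
  h <- nrow(img)
  w <- ncol(img)
  half <- (window_px - 1L) / 2L
  out <- matrix(NA_real_, h, w)
  offs <- lapply(seq_len(n_orientations), function(k) {
    th <- (k - 1L) * angle_step_deg * pi / 180
    t <- -half:half
    if (abs(cos(th)) >= abs(sin(th))) {
      cbind(round(t * sin(th) / cos(th)), t)
    } else {
      cbind(t, round(t * cos(th) / sin(th)))
    }
  })
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      best <- -Inf
      for (off in offs) {
        rr <- r + off[, 1]
        cc <- c + off[, 2]
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        best <- max(best, mean(img[cbind(rr[ok], cc[ok])]))
      }
      rs <- max(1, r - half):min(h, r + half)
      cs <- max(1, c - half):min(w, c + half)
      out[r, c] <- best - mean(img[rs, cs, drop = FALSE])
    }
  }
  out
}

# Pixel-enumeration confusion counts.
brute_eval <- function(pred, gt) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1
    else if (pred[i] && !gt[i]) fp <- fp + 1
    else if (!pred[i] && gt[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Global optimum of 1-D 2-means: enumerate all contiguous splits of the
# sorted values (the 1-D optimum is a contiguous partition).
brute_kmeans2_split <- function(vals) {
  v <- sort(vals)
  n <- length(v)
  best_sse <- Inf
  best <- NULL
  for (i in seq_len(n - 1L)) {
    lo <- v[seq_len(i)]
    hi <- v[(i + 1L):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(lo = lo, hi = hi)
    }
  }
  best
}

# Sierpinski triangle raster on a 2^k grid.
sierpinski_mask <- function(n = 512L) {
  outer(0:(n - 1L), 0:(n - 1L), function(a, b) bitwAnd(a, b) == 0L)
}

# Solid disk / rotated ellipse masks (display convention: y up, angle CCW).
disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

ellipse_mask <- function(n, a, b, angle_deg = 0) {
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  th <- angle_deg * pi / 180
  x <- cc - ctr
  y <- -(rr - ctr)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Shared low-noise reference phantom (computed once per test file that
# needs it, via lazy promise).
reference_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_spec(seed = 42, speckle_shape = 50))
    }
    cache
  }
})
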