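#' Oriented line-strength map
#'
#' The basic line detector for vessel-like structures: at each pixel, digital
#' line segments of length \code{window_px} are laid through the pixel at
#' \code{n_orientations} angles spaced \code{angle_step_deg} degrees
#' (0, 15, ..., 165 by default). The line strength is the largest of the mean
#' gray levels along those lines, minus the mean gray of the
#' \code{window_px} x \code{window_px} square window centred on the pixel.
#' Elongated bright structures score high; flat regions score zero. Lines and
#' windows are clipped at the image border (means are taken over in-bounds
#' pixels only), so there are no padding artifacts at the field edge.
#'
#' @param image An \code{\link{angiogram}} or numeric gray matrix.
#' @param window_px Odd window size in pixels (>= 3).
#' @param n_orientations Number of orientations.
#' @param angle_step_deg Angular spacing; the product with
#'   \code{n_orientations} must be 180.
#' @return Object of class \code{strength_map}: list with \code{values}
#'   (numeric matrix, may be negative), \code{window_px},
#'   \code{n_orientations}, \code{angle_step_deg}.
#' @export
line_strength <- function(image, window_px, n_orientations = 12L,
                          angle_step_deg = 15) {
  img <- as_pixels(image)
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L) {
    stopf("window_px must be odd and >= 3 (got %d)", window_px)
  }
  if (n_orientations * angle_step_deg != 180) {
    stopf("n_orientations x angle_step_deg must equal 180")
  }
  h <- nrow(img)
  w <- ncol(img)
  if (h < window_px || w < window_px) {
    stopf("image (%d x %d) is smaller than the window (%d)", h, w, window_px)
  }

  ones <- matrix(1, h, w)
  best <- matrix(-Inf, h, w)
  for (k in seq_len(n_orientations)) {
    off <- line_offsets(window_px, (k - 1L) * angle_step_deg)
    lsum <- matrix(0, h, w)
    lcnt <- matrix(0, h, w)
    for (i in seq_len(nrow(off))) {
      # pixel p accumulates image[p + offset]; shifting by -offset aligns it
      lsum <- lsum + shift_mat(img, -off[i, 1L], -off[i, 2L])
      lcnt <- lcnt + shift_mat(ones, -off[i, 1L], -off[i, 2L])
    }
    best <- pmax(best, lsum / lcnt)
  }

  wm <- window_mean(img, window_px)
  structure(
    list(values = best - wm, window_px = window_px,
         n_orientations = as.integer(n_orientations),
         angle_step_deg = angle_step_deg),
    class = "strength_map"
  )
}

#' @export
print.strength_map <- function(x, ...) {
  cat(sprintf(
    "Line-strength map: %d x %d, window %d px, %d orientations (%g deg step)\n",
    nrow(x$values), ncol(x$values), x$window_px, x$n_orientations,
    x$angle_step_deg))
  cat(sprintf("  strength range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# Bresenham-style offsets of a digital line of length window_px through the
# origin at `theta_deg` (degrees from the column axis): unit steps along the
# dominant axis, rounded steps along the other.
line_offsets <- function(window_px, theta_deg) {
  half <- (window_px - 1L) / 2L
  th <- theta_deg * pi / 180
  dc <- cos(th)
  dr <- sin(th)
  t <- -half:half
  if (abs(dc) >= abs(dr)) {
    cbind(round(t * dr / dc), t)
  } else {
    cbind(t, round(t * dc / dr))
  }
}

# Border-clipped square window mean via summed-area tables.
window_mean <- function(img, window_px) {
  h <- nrow(img)
  w <- ncol(img)
  half <- (window_px - 1L) / 2L
  sat <- function(m) {
    cm <- apply(rbind(0, m), 2L, cumsum)
    t(apply(cbind(0, cm), 1L, cumsum))
  }
  S <- sat(img)
  N <- sat(matrix(1, h, w))
  r1 <- pmax(1L, seq_len(h) - half)
  r2 <- pmin(h, seq_len(h) + half)
  c1 <- pmax(1L, seq_len(w) - half)
  c2 <- pmin(w, seq_len(w) + half)
  num <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  den <- N[r2 + 1L, c2 + 1L] - N[r1, c2 + 1L] - N[r2 + 1L, c1] + N[r1, c1]
  num / den
}

#' Min-max normalization to [0, 1]
#'
#' Affine rescale of a matrix (or \code{strength_map}) to [0, 1]; a constant
#' input maps to all zeros.
#'
#' @param x Numeric matrix, \code{strength_map} or \code{angiogram}.
#' @return Numeric matrix in [0, 1].
#' @export
normalize01 <- function(x) {
  m <- if (inherits(x, "strength_map")) x$values else as_pixels(x)
  if (!all(is.finite(m))) stopf("values must be finite")
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}
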