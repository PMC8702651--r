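#' Detect the foveal avascular zone from a fused vessel mask
#'
#' The vessel mask is morphologically closed with a disk to seal
#' intercapillary gaps; the avascular (background) 4-connected components
#' are labeled; the FAZ is the component containing the image center (or,
#' if the center pixel is vascular, the component whose centroid lies
#' nearest the center, within 0.5 mm). Interior holes are filled before
#' morphometry. Reported shape descriptors: area, perimeter (4-direction
#' Crofton intercept estimate, nearly unbiased on round shapes),
#' circularity \eqn{4\pi A / P^2}, ellipse axes / orientation /
#' eccentricity from second-order central moments, and the horizontal and
#' vertical extents through the centroid.
#'
#' Orientation is measured in degrees counter-clockwise (as displayed) from
#' the horizontal axis, in (-90, 90].
#'
#' @param fused_mask Logical fused vessel mask.
#' @param geometry An \code{\link{angiogram}} or a list with
#'   \code{mm_per_px} (and matching shape).
#' @param faz_close_radius_px Disk radius used to close the vessel mask.
#' @return Object of class \code{faz_region}: \code{mask} plus
#'   \code{area_mm2}, \code{perimeter_mm}, \code{circularity},
#'   \code{major_axis_mm}, \code{minor_axis_mm}, \code{orientation_deg},
#'   \code{eccentricity}, \code{horizontal_diameter_mm},
#'   \code{vertical_diameter_mm}, \code{centroid} (row, col).
#' @export
detect_faz <- function(fused_mask, geometry, faz_close_radius_px = 10L) {
  mmpp <- if (inherits(geometry, "angiogram")) geometry$mm_per_px
          else geometry$mm_per_px
  h <- nrow(fused_mask)
  w <- ncol(fused_mask)
  comp <- avascular_components(fused_mask, faz_close_radius_px)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  ctr_px <- round(ctr)
  lab_at_ctr <- comp[ctr_px[1], ctr_px[2]]
  if (lab_at_ctr > 0L) {
    faz_lab <- lab_at_ctr
  } else {
    labs <- setdiff(unique(as.vector(comp)), 0L)
    if (length(labs) == 0L) stopf("FAZ not found: no avascular region")
    cent <- t(vapply(labs, function(l) {
      idx <- which(comp == l, arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2)))
    d_mm <- sqrt((cent[, 1] - ctr[1])^2 + (cent[, 2] - ctr[2])^2) * mmpp
    if (min(d_mm) > 0.5) {
      stopf("FAZ not found: no avascular region within 0.5 mm of center")
    }
    faz_lab <- labs[which.min(d_mm)]
  }
  mask <- comp == faz_lab
  mask <- matrix(as.logical(EBImage::fillHull(mask * 1L) > 0), h, w)

  area_px <- sum(mask)
  perim_px <- crofton_perimeter(mask)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  ell <- mask_ellipse(idx)
  list_out <- structure(
    list(
      mask = mask,
      area_mm2 = area_px * mmpp^2,
      perimeter_mm = perim_px * mmpp,
      circularity = 4 * pi * area_px / perim_px^2,
      major_axis_mm = ell$major_px * mmpp,
      minor_axis_mm = ell$minor_px * mmpp,
      orientation_deg = ell$orientation_deg,
      eccentricity = ell$eccentricity,
      horizontal_diameter_mm =
        extent_through_centroid(mask, centroid, "horizontal") * mmpp,
      vertical_diameter_mm =
        extent_through_centroid(mask, centroid, "vertical") * mmpp,
      centroid = centroid
    ),
    class = "faz_region"
  )
  list_out
}

#' @export
print.faz_region <- function(x, ...) {
  cat(sprintf(
    "FAZ: area %.4f mm2, perimeter %.3f mm, circularity %.3f\n",
    x$area_mm2, x$perimeter_mm, x$circularity))
  cat(sprintf(
    "  axes %.3f x %.3f mm at %.1f deg, eccentricity %.3f\n",
    x$major_axis_mm, x$minor_axis_mm, x$orientation_deg, x$eccentricity))
  invisible(x)
}

#' Detect non-perfusion regions
#'
#' Avascular 4-connected components of the closed vessel mask, excluding the
#' FAZ component, excluding components touching the outer border margin
#' (one closing-window width), and keeping only components of at least
#' \code{npa_min_area_mm2}.
#'
#' @param fused_mask Logical fused vessel mask.
#' @param faz A \code{faz_region} from \code{\link{detect_faz}}.
#' @param geometry An \code{\link{angiogram}} or list with \code{mm_per_px}.
#' @param npa_close_radius_px Disk radius for closing.
#' @param npa_min_area_mm2 Minimum region area in mm^2.
#' @return Object of class \code{nonperfusion_map}: \code{mask},
#'   \code{total_area_mm2}, \code{n_regions}.
#' @export
detect_nonperfusion <- function(fused_mask, faz, geometry,
                                npa_close_radius_px = 10L,
                                npa_min_area_mm2 = 0.015) {
  mmpp <- geometry$mm_per_px
  h <- nrow(fused_mask)
  w <- ncol(fused_mask)
  comp <- avascular_components(fused_mask, npa_close_radius_px)
  margin <- matrix(FALSE, h, w)
  m <- npa_close_radius_px
  margin[c(seq_len(m), (h - m + 1):h), ] <- TRUE
  margin[, c(seq_len(m), (w - m + 1):w)] <- TRUE
  labs <- setdiff(unique(as.vector(comp)), 0L)
  keep <- matrix(FALSE, h, w)
  n_regions <- 0L
  min_px <- npa_min_area_mm2 / mmpp^2
  for (l in labs) {
    cm <- comp == l
    if (any(cm & faz$mask)) next
    if (any(cm & margin)) next
    if (sum(cm) < min_px) next
    keep <- keep | cm
    n_regions <- n_regions + 1L
  }
  structure(
    list(mask = keep, total_area_mm2 = sum(keep) * mmpp^2,
         n_regions = n_regions),
    class = "nonperfusion_map"
  )
}

#' @export
print.nonperfusion_map <- function(x, ...) {
  cat(sprintf("Non-perfusion map: %d region(s), total %.4f mm2\n",
              x$n_regions, x$total_area_mm2))
  invisible(x)
}

# Crofton perimeter estimate from boundary intercepts in 4 directions
# (horizontal, vertical, both diagonals). Nearly unbiased on round shapes
# (< 1% error on digital disks), unlike raw boundary-pixel counts which
# inflate a circle's perimeter by ~25% and depress circularity accordingly.
crofton_perimeter <- function(mask) {
  storage.mode(mask) <- "integer"
  n_h <- sum(abs(mask[, -1L] - mask[, -ncol(mask)]))
  n_v <- sum(abs(mask[-1L, ] - mask[-nrow(mask), ]))
  d1 <- sum(abs(mask[-1L, -1L] - mask[-nrow(mask), -ncol(mask)]))
  d2 <- sum(abs(mask[-1L, -ncol(mask)] - mask[-nrow(mask), -1L]))
  pi / 4 * ((n_h + n_v) / 2 + (d1 + d2) / (2 * sqrt(2)))
}

# Close the vessel mask and label the avascular background (4-connected).
avascular_components <- function(fused_mask, close_radius_px) {
  closed <- EBImage::closing(fused_mask * 1L, disc_kernel(close_radius_px))
  bg <- matrix(as.vector(closed) == 0, nrow(fused_mask), ncol(fused_mask))
  label_components(bg)
}

# Ellipse descriptors from second-order central moments of the pixel set.
# y is flipped so the angle is counter-clockwise in display orientation.
mask_ellipse <- function(idx) {
  x <- idx[, 2]
  y <- -idx[, 1]
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  # +1/12: variance of the unit pixel footprint
  m20 <- sum((x - mx)^2) / n + 1 / 12
  m02 <- sum((y - my)^2) / n + 1 / 12
  m11 <- sum((x - mx) * (y - my)) / n
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  theta <- 0.5 * atan2(2 * m11, m20 - m02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(
    major_px = 4 * sqrt(l1),
    minor_px = 4 * sqrt(max(l2, 0)),
    orientation_deg = theta,
    eccentricity = sqrt(max(0, 1 - l2 / l1))
  )
}

extent_through_centroid <- function(mask, centroid, direction) {
  if (direction == "horizontal") {
    r <- round(centroid[1])
    cols <- which(mask[r, ])
    if (length(cols) == 0L) return(0)
    max(cols) - min(cols) + 1L
  } else {
    c <- round(centroid[2])
    rows <- which(mask[, c])
    if (length(rows) == 0L) return(0)
    max(rows) - min(rows) + 1L
  }
}
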