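#' Area density of a mask within a region of interest
#'
#' \code{|mask & roi| / |roi|}; with the full field as ROI this is the
#' global vessel (or skeleton) density.
#'
#' @param mask Logical matrix.
#' @param roi Logical ROI of the same shape; defaults to the full field.
#' @return Fraction in [0, 1].
#' @export
area_density <- function(mask, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(roi))) stopf("mask and roi shapes differ")
  if (!any(roi)) stopf("roi is empty")
  sum(mask & roi) / sum(roi)
}

#' Vessel perimeter index
#'
#' Fraction of ROI pixels lying on the vessel boundary (pixels 8-adjacent
#' to in-image background), from \code{\link{perimeter_map}}.
#'
#' @param perimeter_mask Logical perimeter mask.
#' @param roi Logical ROI; defaults to the full field.
#' @return Fraction in [0, 1].
#' @export
vessel_perimeter_index <- function(perimeter_mask, roi = NULL) {
  area_density(perimeter_mask, roi)
}

#' Vessel diameter index (mean caliber)
#'
#' Vessel foreground area divided by skeleton length (pixel counts): the
#' mean vessel caliber in pixels. Multiply by \code{mm_per_px * 1000} for
#' micrometres. Undefined (NaN) for an empty skeleton.
#'
#' @param vessel_mask Logical vessel mask.
#' @param skeleton_mask Logical skeleton mask.
#' @return Mean caliber in pixels, or NaN.
#' @export
vessel_diameter_index <- function(vessel_mask, skeleton_mask) {
  n_sk <- sum(skeleton_mask)
  if (n_sk == 0L) return(NaN)
  sum(vessel_mask) / n_sk
}

#' Vessel complexity index
#'
#' \eqn{P^2 / (4 \pi A)} with perimeter and area as pixel counts; 1 for a
#' continuum disk (isoperimetric minimum), larger for more convoluted
#' shapes. Undefined (NaN) for an empty mask.
#'
#' @param vessel_mask Logical vessel mask.
#' @param perimeter_mask Logical perimeter mask of the same vessels.
#' @return Dimensionless index, or NaN.
#' @export
vessel_complexity_index <- function(vessel_mask, perimeter_mask) {
  a <- sum(vessel_mask)
  if (a == 0L) return(NaN)
  sum(perimeter_mask)^2 / (4 * pi * a)
}

#' Box-counting fractal dimension of a skeleton
#'
#' Counts, for box sizes 2, 4, 8, 16, 32 and 64 px on a grid anchored at
#' the image origin, the number of boxes containing at least one foreground
#' pixel, and returns the negated least-squares slope of
#' \eqn{\log N(s)} versus \eqn{\log s}. About 1 for a line, 2 for a filled
#' field. Undefined (NaN) for an empty mask.
#'
#' @param skeleton_mask Logical matrix.
#' @param box_sizes Integer vector of box sizes in px.
#' @return Fractal dimension, or NaN.
#' @export
box_counting_dimension <- function(skeleton_mask,
                                   box_sizes = c(2L, 4L, 8L, 16L, 32L, 64L)) {
  idx <- which(skeleton_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NaN)
  counts <- vapply(box_sizes, function(s) {
    br <- (idx[, 1] - 1L) %/% s
    bc <- (idx[, 2] - 1L) %/% s
    length(unique(br * (max(bc) + 1L) + bc))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(box_sizes)), log(counts))
  -unname(fit$coefficients[2])
}

#' Circular region of interest
#'
#' Disk of the stated physical diameter, used for the 1-mm and 2-mm circle
#' densities. Centered on the FAZ centroid when available, else the image
#' center.
#'
#' @param geometry An \code{\link{angiogram}} or list with \code{mm_per_px}
#'   and \code{height}/\code{width}.
#' @param center Numeric (row, col) center in pixels.
#' @param diameter_mm Physical circle diameter; must not exceed the field.
#' @return Logical disk mask.
#' @export
circle_roi <- function(geometry, center, diameter_mm) {
  mmpp <- geometry$mm_per_px
  h <- geometry$height
  w <- geometry$width
  if (diameter_mm > geometry$field_size_mm + 1e-9) {
    stopf("circle diameter (%g mm) exceeds the field (%g mm)",
          diameter_mm, geometry$field_size_mm)
  }
  rad_px <- diameter_mm / 2 / mmpp
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= rad_px^2
}

metric_names <- c(
  "vessel_density", "vessel_skeleton_density", "vessel_perimeter_index",
  "vessel_diameter_index_px", "vessel_complexity_index",
  "vessel_skeleton_fractal_dimension", "big_vessel_density",
  "small_vessel_density", "big_vessel_skeleton_density",
  "small_vessel_skeleton_density", "non_perfusion_area_mm2",
  "faz_area_mm2", "faz_perimeter_mm", "faz_circularity",
  "faz_major_axis_mm", "faz_minor_axis_mm", "faz_orientation_deg",
  "faz_eccentricity", "faz_horizontal_diameter_mm",
  "faz_vertical_diameter_mm", "vd_circle_1mm", "vd_circle_2mm",
  "vsd_circle_1mm", "vsd_circle_2mm"
)

#' Quantify the 24 OCTA metrics from masks
#'
#' Computes the full metric record from an already-segmented image: global
#' and per-caliber densities, skeleton metrics, fractal dimension, FAZ
#' morphometry, non-perfusion area and the 1-mm / 2-mm circle densities.
#' FAZ-dependent metrics degrade to NaN sentinels (with circle ROIs centered
#' on the image center) when no FAZ is found.
#'
#' @param image An \code{\link{angiogram}} (for geometry).
#' @param large_mask,cap_mask,fused_mask Logical branch and fused masks.
#' @param config An \code{\link{mrvs_config}}.
#' @return One-row data.frame with the 24 metric columns.
#' @keywords internal
quantify_metrics <- function(image, large_mask, cap_mask, fused_mask,
                             config = mrvs_config()) {
  skel <- skeletonize(fused_mask)
  perim <- perimeter_map(fused_mask)
  skel_big <- skeletonize(large_mask)
  skel_small <- skeletonize(cap_mask)

  faz <- tryCatch(
    detect_faz(fused_mask, image, config$faz_close_radius_px),
    error = function(e) NULL
  )
  if (is.null(faz)) {
    message("FAZ not found; FAZ metrics set to NaN, circles centered on field")
    npa_total <- NaN
    center <- c((image$height + 1) / 2, (image$width + 1) / 2)
    faz_vals <- rep(NaN, 9)
  } else {
    npa <- detect_nonperfusion(fused_mask, faz, image,
                               config$npa_close_radius_px,
                               config$npa_min_area_mm2)
    npa_total <- npa$total_area_mm2
    center <- faz$centroid
    faz_vals <- c(faz$area_mm2, faz$perimeter_mm, faz$circularity,
                  faz$major_axis_mm, faz$minor_axis_mm, faz$orientation_deg,
                  faz$eccentricity, faz$horizontal_diameter_mm,
                  faz$vertical_diameter_mm)
  }
  roi1 <- circle_roi(image, center, 1.0)
  roi2 <- circle_roi(image, center, 2.0)

  rec <- data.frame(
    vessel_density = area_density(fused_mask),
    vessel_skeleton_density = area_density(skel),
    vessel_perimeter_index = vessel_perimeter_index(perim),
    vessel_diameter_index_px = vessel_diameter_index(fused_mask, skel),
    vessel_complexity_index = vessel_complexity_index(fused_mask, perim),
    vessel_skeleton_fractal_dimension = box_counting_dimension(skel),
    big_vessel_density = area_density(large_mask),
    small_vessel_density = area_density(cap_mask),
    big_vessel_skeleton_density = area_density(skel_big),
    small_vessel_skeleton_density = area_density(skel_small),
    non_perfusion_area_mm2 = npa_total,
    faz_area_mm2 = faz_vals[1],
    faz_perimeter_mm = faz_vals[2],
    faz_circularity = faz_vals[3],
    faz_major_axis_mm = faz_vals[4],
    faz_minor_axis_mm = faz_vals[5],
    faz_orientation_deg = faz_vals[6],
    faz_eccentricity = faz_vals[7],
    faz_horizontal_diameter_mm = faz_vals[8],
    faz_vertical_diameter_mm = faz_vals[9],
    vd_circle_1mm = area_density(fused_mask, roi1),
    vd_circle_2mm = area_density(fused_mask, roi2),
    vsd_circle_1mm = area_density(skel, roi1),
    vsd_circle_2mm = area_density(skel, roi2)
  )
  stopifnot(identical(names(rec), metric_names))
  rec
}

#' Segment an angiogram and quantify all 24 OCTA metrics
#'
#' Convenience wrapper: runs \code{\link{mrvsm}} and returns the one-row
#' metric record.
#'
#' @param image An \code{\link{angiogram}}.
#' @param config An \code{\link{mrvs_config}}.
#' @return One-row data.frame with 24 metric columns.
#' @export
quantify_all <- function(image, config = mrvs_config()) {
  mrvsm(image, config)$metrics
}
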