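#' Combine line-strength and intensity maps
#'
#' Convex combination of the min-max normalized line-strength map and the
#' min-max normalized intensity image,
#' \code{C = w_struct * normalize01(strength) + w_intensity * normalize01(image)}.
#' The default weights are 1/3 for structure and 2/3 for intensity.
#'
#' @param strength A \code{strength_map} or numeric matrix.
#' @param image An \code{angiogram} or numeric matrix, same shape.
#' @param w_struct,w_intensity Weights summing to 1.
#' @return Numeric matrix in [0, 1].
#' @export
combine_structure_intensity <- function(strength, image, w_struct = 1 / 3,
                                        w_intensity = 2 / 3) {
  s <- if (inherits(strength, "strength_map")) strength$values else strength
  img <- as_pixels(image)
  if (!identical(dim(s), dim(img))) {
    stopf("strength map and image shapes differ")
  }
  if (abs(w_struct + w_intensity - 1) > 1e-9) {
    stopf("w_struct + w_intensity must equal 1")
  }
  w_struct * normalize01(s) + w_intensity * normalize01(img)
}

#' Rough vessel/background binarization
#'
#' Otsu threshold on the combined structure/intensity map; foreground is the
#' above-threshold (vessel-candidate) class. A constant map has no threshold
#' and yields an all-background mask with a warning.
#'
#' @param combined Numeric matrix in [0, 1].
#' @return Logical matrix.
#' @export
rough_binarize <- function(combined) {
  rng <- range(combined)
  if (rng[1] == rng[2]) {
    warning("constant combined map: no Otsu threshold exists, returning ",
            "all-background mask")
    return(matrix(FALSE, nrow(combined), ncol(combined)))
  }
  th <- EBImage::otsu(EBImage::Image(combined), range = c(0, 1), levels = 256L)
  combined > th
}

#' Attenuate detected background
#'
#' Multiplies pixels outside the rough vessel mask by \code{background_atten}
#' (default 0.5: background intensity halved) and rounds half-up; vessel
#' pixels pass through unchanged. Improves vessel/background contrast before
#' gray-level clustering.
#'
#' @param image An \code{angiogram} or gray matrix.
#' @param rough_mask Logical matrix from \code{\link{rough_binarize}}.
#' @param background_atten Multiplicative factor in [0, 1].
#' @return Gray matrix.
#' @export
attenuate_background <- function(image, rough_mask, background_atten = 0.5) {
  img <- as_pixels(image)
  if (!identical(dim(img), dim(rough_mask))) {
    stopf("image and rough_mask shapes differ")
  }
  out <- img
  out[!rough_mask] <- round_half_up(img[!rough_mask] * background_atten)
  out
}

#' Separate vessel and background pixels by gray-level K-means
#'
#' One-dimensional 2-class K-means (Lloyd iterations) on the multiset of
#' pixel gray levels, initialized deterministically at the 25th and 75th
#' percentile gray values; iteration stops when both centroids move less
#' than 1e-6 or after 100 iterations. The vessel mask is the cluster with
#' the higher centroid. A constant image yields an empty mask.
#'
#' @param image Gray matrix (typically background-attenuated).
#' @param k Number of clusters; must be 2.
#' @return Logical vessel mask.
#' @export
kmeans_gray_separation <- function(image, k = 2L) {
  if (k != 2L) stopf("k must be 2")
  img <- as_pixels(image)
  vals <- as.vector(img)
  if (min(vals) == max(vals)) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  # Lloyd on the value histogram: exact and fast for gray-level data
  uv <- sort(unique(vals))
  cnt <- tabulate(match(vals, uv), nbins = length(uv))
  c_lo <- unname(stats::quantile(vals, 0.25, type = 7))
  c_hi <- unname(stats::quantile(vals, 0.75, type = 7))
  if (c_lo == c_hi) {
    c_lo <- min(vals)
    c_hi <- max(vals)
  }
  for (it in seq_len(100L)) {
    mid <- (c_lo + c_hi) / 2
    hi <- uv > mid
    w_lo <- sum(cnt[!hi])
    w_hi <- sum(cnt[hi])
    new_lo <- if (w_lo > 0) sum(uv[!hi] * cnt[!hi]) / w_lo else c_lo
    new_hi <- if (w_hi > 0) sum(uv[hi] * cnt[hi]) / w_hi else c_hi
    if (abs(new_lo - c_lo) < 1e-6 && abs(new_hi - c_hi) < 1e-6) {
      c_lo <- new_lo
      c_hi <- new_hi
      break
    }
    c_lo <- new_lo
    c_hi <- new_hi
  }
  img > (c_lo + c_hi) / 2
}

#' Top-bottom hat enhancement
#'
#' Adds the top-hat (small bright detail) and subtracts the bottom-hat
#' (small dark detail) of the image, clipping to [0, 255]:
#' \code{E = clip(I + (I - opening(I)) - (closing(I) - I))}, with a disk
#' structuring element. Highlights capillary-scale bright structures and
#' suppresses background undulation.
#'
#' @param image Gray matrix or \code{angiogram}.
#' @param se_radius Disk radius of the structuring element in px.
#' @return Enhanced gray matrix.
#' @export
top_bottom_hat <- function(image, se_radius = 8L) {
  img <- as_pixels(image)
  if (se_radius < 1L) stopf("se_radius must be >= 1")
  kern <- disc_kernel(se_radius)
  tophat <- img - gray_opening(img, kern)
  bottomhat <- gray_closing(img, kern) - img
  pmin(pmax(img + tophat - bottomhat, 0), 255)
}

branch_result <- function(strength, combined, rough_mask, final_mask, branch) {
  structure(
    list(strength = strength, combined = combined, rough_mask = rough_mask,
         final_mask = final_mask, branch = branch),
    class = "mrvs_branch"
  )
}

#' @export
print.mrvs_branch <- function(x, ...) {
  cat(sprintf("MRVS %s-vessel branch result: %d x %d, %d foreground px (%.3f)\n",
              x$branch, nrow(x$final_mask), ncol(x$final_mask),
              sum(x$final_mask), mean(x$final_mask)))
  invisible(x)
}

#' Large-vessel segmentation branch (LVSB)
#'
#' Line strength at the large-vessel window (25 x 25 px by default) is
#' combined with intensity (weights 1/3, 2/3), roughly binarized by Otsu,
#' the detected background is attenuated, and vessel pixels are separated
#' from background by gray-level K-means. Connected components smaller than
#' \code{win_cap_px^2} pixels are removed as speckle.
#'
#' @param image An \code{angiogram} or gray matrix.
#' @param config An \code{\link{mrvs_config}}.
#' @return An object of class \code{mrvs_branch} (fields \code{strength},
#'   \code{combined}, \code{rough_mask}, \code{final_mask}, \code{branch}).
#' @export
segment_large_vessels <- function(image, config = mrvs_config()) {
  img <- as_pixels(image)
  s <- line_strength(img, config$win_large_px, config$n_orientations,
                     config$angle_step_deg)
  comb <- combine_structure_intensity(s, img, config$w_struct,
                                      config$w_intensity)
  rough <- rough_binarize(comb)
  att <- attenuate_background(img, rough, config$background_atten)
  km <- kmeans_gray_separation(att, config$kmeans_k)
  final <- remove_small_components(km, config$win_cap_px^2)
  branch_result(s, comb, rough, final, "large")
}

#' Capillary segmentation branch
#'
#' Detected large-vessel pixels are first overwritten with a flat gray
#' (45 by default) to remove their interference, the image is enhanced by
#' the top-bottom hat transform, and the same stage chain as the
#' large-vessel branch is run at the capillary window (7 x 7 px by
#' default). Large-vessel pixels are excluded from the capillary mask so the
#' two branch masks are disjoint.
#'
#' @param image An \code{angiogram} or gray matrix.
#' @param large_mask Logical final mask from \code{\link{segment_large_vessels}}.
#' @param config An \code{\link{mrvs_config}}.
#' @return An \code{mrvs_branch}.
#' @export
segment_capillaries <- function(image, large_mask, config = mrvs_config()) {
  img <- as_pixels(image)
  if (!identical(dim(img), dim(large_mask))) {
    stopf("image and large_mask shapes differ")
  }
  filled <- img
  filled[large_mask] <- config$large_vessel_fill_gray
  enh <- top_bottom_hat(filled, config$tophat_se_radius_px)
  s <- line_strength(enh, config$win_cap_px, config$n_orientations,
                     config$angle_step_deg)
  comb <- combine_structure_intensity(s, enh, config$w_struct,
                                      config$w_intensity)
  rough <- rough_binarize(comb)
  att <- attenuate_background(enh, rough, config$background_atten)
  km <- kmeans_gray_separation(att, config$kmeans_k)
  # speckle suppression judges connectivity on the whole vasculature:
  # capillaries branch off larger vessels, so a capillary fragment touching
  # the large-vessel network is anatomy, not noise; only isolated specks
  # smaller than the capillary window area are removed
  final <- remove_small_components(km | large_mask, config$win_cap_px^2) &
    !large_mask
  branch_result(s, comb, rough, final, "capillary")
}

#' Fuse the two branch masks
#'
#' The segmentation result is the union (logical OR) of the large-vessel and
#' capillary foregrounds.
#'
#' @param large_result,cap_result \code{mrvs_branch} objects or logical masks.
#' @return Logical fused vessel mask.
#' @export
fuse_branches <- function(large_result, cap_result) {
  a <- if (inherits(large_result, "mrvs_branch")) large_result$final_mask
       else large_result
  b <- if (inherits(cap_result, "mrvs_branch")) cap_result$final_mask
       else cap_result
  if (!identical(dim(a), dim(b))) stopf("branch mask shapes differ")
  a | b
}

#' Morphological skeleton (medial axis) of a binary mask
#'
#' Zhang-Suen thinning to a 1-pixel-wide, topology-preserving skeleton.
#'
#' @param mask Logical matrix.
#' @return Logical skeleton mask.
#' @export
skeletonize <- function(mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- skeleton_neighbors(m)
      # neighbors in circular order P2..P9: N, NE, E, SE, S, SW, W, NW
      b <- Reduce(`+`, nb)
      ring <- c(nb, nb[1])
      a <- Reduce(`+`, lapply(seq_len(8L), function(i) {
        (!ring[[i]]) & ring[[i + 1L]]
      }))
      if (pass == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-neighborhood as shifted copies, order P2..P9 (N, NE, E, SE, S, SW, W, NW)
# in matrix convention: N = row above.
skeleton_neighbors <- function(m) {
  list(
    shift_mat(m, 1L, 0L, FALSE),    # N  (value from row above)
    shift_mat(m, 1L, -1L, FALSE),   # NE
    shift_mat(m, 0L, -1L, FALSE),   # E
    shift_mat(m, -1L, -1L, FALSE),  # SE
    shift_mat(m, -1L, 0L, FALSE),   # S
    shift_mat(m, -1L, 1L, FALSE),   # SW
    shift_mat(m, 0L, 1L, FALSE),    # W
    shift_mat(m, 1L, 1L, FALSE)     # NW
  )
}
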