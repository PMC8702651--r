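#' Multi-branch retinal vessel segmentation and quantification
#'
#' Runs the full pipeline on an en-face OCTA angiogram: the large-vessel
#' branch (25 x 25 px line detector, structure/intensity combination, rough
#' Otsu binarization, background attenuation, gray-level K-means), the
#' capillary branch (large vessels filled with gray 45, top-bottom hat
#' enhancement, the same stage chain at a 7 x 7 px window), fusion of the
#' two foregrounds by union, skeleton and perimeter extraction, FAZ and
#' non-perfusion detection, and the 24 vascular / FAZ metrics.
#'
#' The pipeline is fully deterministic: a fixed image and configuration
#' always produce identical masks and metrics.
#'
#' @param image An \code{\link{angiogram}} (or gray matrix, taken as a
#'   3-mm field).
#' @param config An \code{\link{mrvs_config}}.
#' @return Object of class \code{mrvsm} with elements \code{image},
#'   \code{config}, \code{large} and \code{capillary}
#'   (\code{mrvs_branch}es), \code{fused}, \code{skeleton},
#'   \code{perimeter} (logical masks), \code{faz} (\code{faz_region} or
#'   NULL), \code{npa} (\code{nonperfusion_map} or NULL) and \code{metrics}
#'   (one-row data.frame).
#' @export
#' @examples
#' bundle <- generate_phantom(phantom_spec(size_px = 128, seed = 1))
#' fit <- mrvsm(bundle$image)
#' fit$metrics$vessel_density
mrvsm <- function(image, config = mrvs_config()) {
  if (!inherits(image, "angiogram")) image <- angiogram(image)
  validate_config(config)
  large <- segment_large_vessels(image, config)
  capillary <- segment_capillaries(image, large$final_mask, config)
  fused <- fuse_branches(large, capillary)
  skeleton <- skeletonize(fused)
  perimeter <- perimeter_map(fused)
  faz <- tryCatch(
    detect_faz(fused, image, config$faz_close_radius_px),
    error = function(e) NULL
  )
  npa <- if (!is.null(faz)) {
    detect_nonperfusion(fused, faz, image, config$npa_close_radius_px,
                        config$npa_min_area_mm2)
  }
  metrics <- quantify_metrics(image, large$final_mask, capillary$final_mask,
                              fused, config)
  structure(
    list(image = image, config = config, large = large,
         capillary = capillary, fused = fused, skeleton = skeleton,
         perimeter = perimeter, faz = faz, npa = npa, metrics = metrics),
    class = "mrvsm"
  )
}

#' @export
print.mrvsm <- function(x, ...) {
  cat(sprintf("MRVS segmentation of a %d x %d angiogram (%.3g mm field)\n",
              x$image$height, x$image$width, x$image$field_size_mm))
  cat(sprintf("  vessel density %.4f (big %.4f, small %.4f)\n",
              x$metrics$vessel_density, x$metrics$big_vessel_density,
              x$metrics$small_vessel_density))
  if (!is.null(x$faz)) {
    cat(sprintf("  FAZ area %.4f mm2, circularity %.3f\n",
                x$metrics$faz_area_mm2, x$metrics$faz_circularity))
  } else {
    cat("  FAZ not found\n")
  }
  invisible(x)
}

#' @export
summary.mrvsm <- function(object, ...) {
  print(object)
  cat("\nAll 24 OCTA metrics:\n")
  m <- object$metrics
  for (nm in names(m)) cat(sprintf("  %-36s %s\n", nm, format(m[[nm]])))
  invisible(object$metrics)
}

#' @export
plot.mrvsm <- function(x, ...) {
  show <- function(m, main) {
    graphics::image(t(m)[, rev(seq_len(nrow(m)))], col = grDevices::gray(
      seq(0, 1, length.out = 256)), axes = FALSE, main = main, asp = 1)
  }
  old <- graphics::par(mfrow = c(2, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(old))
  show(x$image$pixels, "angiogram")
  show(x$fused * 1, "fused vessels")
  show(x$skeleton * 1, "skeleton")
  faz_overlay <- x$fused * 1
  if (!is.null(x$faz)) faz_overlay[x$faz$mask] <- 0.5
  show(faz_overlay, "FAZ over vessels")
  invisible(x)
}
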