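#' Segmentation pipeline configuration
#'
#' All tunable parameters of the two segmentation branches and the
#' downstream FAZ / non-perfusion detection. Defaults follow the published
#' operating point of the method: a 25 x 25 px line-detector window for the
#' large-vessel branch, 7 x 7 px for the capillary branch, 12 line
#' orientations spaced 15 degrees, structure/intensity combination weights
#' 1/3 and 2/3, background attenuation by one half, and large vessels
#' filled with gray 45 before capillary enhancement.
#'
#' @param n_orientations Number of line orientations (default 12).
#' @param angle_step_deg Angular spacing in degrees (default 15);
#'   \code{n_orientations * angle_step_deg} must equal 180.
#' @param win_large_px Odd line-detector window for the large-vessel branch.
#' @param win_cap_px Odd line-detector window for the capillary branch;
#'   must be smaller than \code{win_large_px}.
#' @param w_struct,w_intensity Combination weights for the line-strength and
#'   intensity maps; must sum to 1 and lie in (0, 1) (degenerate 0/1 weights
#'   are accepted for diagnostics).
#' @param background_atten Multiplicative attenuation applied to detected
#'   background (default 0.5, i.e. halved).
#' @param large_vessel_fill_gray Gray level written over detected large
#'   vessels before capillary enhancement (default 45, 0-255 scale).
#' @param tophat_se_radius_px Disk radius of the top/bottom-hat structuring
#'   element in px (default 8 at 320-px resolution).
#' @param faz_close_radius_px Disk radius for vessel-mask closing before FAZ
#'   detection (default 10).
#' @param npa_close_radius_px Same, for non-perfusion detection (default 10).
#' @param npa_min_area_mm2 Minimum area of a non-perfusion region in mm^2.
#' @param kmeans_k Number of K-means clusters; fixed at 2.
#' @param kmeans_seed Integer seed kept for provenance (the percentile
#'   initialization is deterministic, so it does not affect results).
#' @return An object of class \code{mrvs_config}.
#' @export
mrvs_config <- function(n_orientations = 12L,
                        angle_step_deg = 15,
                        win_large_px = 25L,
                        win_cap_px = 7L,
                        w_struct = 1 / 3,
                        w_intensity = 2 / 3,
                        background_atten = 0.5,
                        large_vessel_fill_gray = 45,
                        tophat_se_radius_px = 8L,
                        faz_close_radius_px = 10L,
                        npa_close_radius_px = 10L,
                        npa_min_area_mm2 = 0.015,
                        kmeans_k = 2L,
                        kmeans_seed = 1L) {
  cfg <- structure(
    list(
      n_orientations = as.integer(n_orientations),
      angle_step_deg = angle_step_deg,
      win_large_px = as.integer(win_large_px),
      win_cap_px = as.integer(win_cap_px),
      w_struct = w_struct,
      w_intensity = w_intensity,
      background_atten = background_atten,
      large_vessel_fill_gray = large_vessel_fill_gray,
      tophat_se_radius_px = as.integer(tophat_se_radius_px),
      faz_close_radius_px = as.integer(faz_close_radius_px),
      npa_close_radius_px = as.integer(npa_close_radius_px),
      npa_min_area_mm2 = npa_min_area_mm2,
      kmeans_k = as.integer(kmeans_k),
      kmeans_seed = as.integer(kmeans_seed)
    ),
    class = "mrvs_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (abs(cfg$w_struct + cfg$w_intensity - 1) > 1e-9) {
    stopf("w_struct + w_intensity must equal 1 (got %g + %g)",
          cfg$w_struct, cfg$w_intensity)
  }
  if (cfg$w_struct < 0 || cfg$w_struct > 1) {
    stopf("w_struct must lie in [0, 1]")
  }
  for (f in c("win_large_px", "win_cap_px")) {
    v <- cfg[[f]]
    if (v < 3L || v %% 2L == 0L) stopf("%s must be odd and >= 3", f)
  }
  if (cfg$win_cap_px >= cfg$win_large_px) {
    stopf("win_cap_px must be smaller than win_large_px")
  }
  if (cfg$n_orientations * cfg$angle_step_deg != 180) {
    stopf("n_orientations x angle_step_deg must equal 180")
  }
  if (cfg$kmeans_k != 2L) stopf("kmeans_k is fixed at 2")
  if (cfg$background_atten < 0 || cfg$background_atten > 1) {
    stopf("background_atten must lie in [0, 1]")
  }
  for (f in c("tophat_se_radius_px", "faz_close_radius_px",
              "npa_close_radius_px")) {
    if (cfg[[f]] < 1L) stopf("%s must be >= 1", f)
  }
  if (cfg$npa_min_area_mm2 < 0) stopf("npa_min_area_mm2 must be >= 0")
  cfg
}

#' @export
print.mrvs_config <- function(x, ...) {
  cat("MRVS pipeline configuration:\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take their defaults; an empty file yields the
#' default configuration. Invalid settings raise a validation error naming
#' the offending field.
#'
#' @param path Path to a YAML mapping of \code{\link{mrvs_config}} fields.
#' @return An \code{mrvs_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("cannot read config: no such file '%s'", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(mrvs_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(mrvs_config, vals)
}

#' Save a pipeline configuration to YAML
#'
#' @param config An \code{mrvs_config}.
#' @param path Destination path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "mrvs_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
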