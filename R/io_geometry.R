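#' Construct an en-face OCTA angiogram
#'
#' Wraps a grayscale pixel matrix together with the physical geometry of the
#' scanned field. En-face OCTA angiograms are square scans of a known physical
#' side length (3 mm x 3 mm macular scans by default), so the pixel pitch is
#' \code{field_size_mm / width}.
#'
#' @param pixels Numeric matrix of gray levels in [0, 255] (rows = image rows).
#' @param field_size_mm Physical side length of the square field in mm.
#' @return An object of class \code{angiogram} with elements \code{pixels},
#'   \code{height}, \code{width}, \code{field_size_mm} and \code{mm_per_px}.
#' @export
#' @examples
#' img <- angiogram(matrix(0, 64, 64))
#' img$mm_per_px  # 3/64
angiogram <- function(pixels, field_size_mm = 3.0) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("pixels must be a numeric matrix")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stopf("pixel values must lie in [0, 255]")
  }
  if (!is.numeric(field_size_mm) || length(field_size_mm) != 1L ||
      field_size_mm <= 0) {
    stopf("field_size_mm must be a positive scalar")
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      field_size_mm = field_size_mm,
      mm_per_px = field_size_mm / ncol(pixels)
    ),
    class = "angiogram"
  )
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf(
    "En-face OCTA angiogram: %d x %d px, %.3g mm field (%.5g mm/px)\n",
    x$height, x$width, x$field_size_mm, x$mm_per_px
  ))
  cat(sprintf("  gray range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an en-face angiogram from a TIFF or PNG file
#'
#' Reads an 8- or 16-bit single-channel raster (or an RGB export whose
#' channels are identical) and returns an \code{\link{angiogram}} on the
#' 0-255 gray scale. 16-bit input is rescaled to 0-255. RGB input with equal
#' channels is collapsed to one channel; unequal channels are averaged to
#' luminance with a warning.
#'
#' @param path Path to a TIFF or PNG file.
#' @param field_size_mm Physical side length of the field in mm (default 3).
#' @return An \code{angiogram}.
#' @export
read_angiogram <- function(path, field_size_mm = 3.0) {
  if (!file.exists(path)) stopf("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(frames) > 1L) {
      stopf("multi-frame TIFF stacks are not supported: '%s'", path)
    }
    raw <- frames[[1]]
    # as.is = TRUE yields integer sample values (0-255 or 0-65535)
    if (max(raw) > 255) raw <- raw / 65535 * 255
  } else if (ext == "png") {
    raw <- png::readPNG(path) * 255
  } else {
    stopf("unsupported image format '%s' (TIFF or PNG expected)", ext)
  }
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3]
    ch <- lapply(seq_len(min(nch, 3L)), function(i) raw[, , i])
    same <- all(vapply(ch[-1], function(m) isTRUE(all.equal(m, ch[[1]])),
                       logical(1)))
    if (same) {
      raw <- ch[[1]]
    } else {
      warning("RGB channels differ; collapsing to luminance average")
      raw <- Reduce(`+`, ch) / length(ch)
    }
  }
  angiogram(pmin(pmax(raw, 0), 255), field_size_mm = field_size_mm)
}

#' Write a binary mask as a lossless 8-bit image
#'
#' Foreground pixels are written as 255 and background as 0; masks round-trip
#' bit-exactly through \code{\link{read_mask}}.
#'
#' @param path Destination path (\code{.png}, \code{.tif} or \code{.tiff}).
#' @param mask Logical matrix.
#' @export
write_mask <- function(path, mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stopf("mask must be a logical matrix")
  }
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    } else {
      png::writePNG(img, path)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!isTRUE(ok) || !file.exists(path)) {
    stopf("cannot write mask to '%s'", path)
  }
  invisible(path)
}

#' Read a binary mask written by \code{\link{write_mask}}
#'
#' @param path Path to an 8-bit mask image (foreground 255).
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_angiogram(path, field_size_mm = 1)
  img$pixels > 127
}

#' Mask of pixels on the foreground boundary
#'
#' A perimeter pixel is a foreground pixel 8-adjacent to an in-image
#' background pixel. The image border itself does not count as background,
#' so a full-field mask has an empty perimeter.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of boundary pixels.
#' @export
perimeter_map <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  bg <- !mask
  near_bg <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      near_bg <- near_bg | shift_mat(bg, dr, dc, fill = FALSE)
    }
  }
  mask & near_bg
}
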