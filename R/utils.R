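# Internal helpers shared across modules.

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) > 0L && length(cs) > 0L && rs[1] <= rs[length(rs)] &&
      cs[1] <= cs[length(cs)]) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

# Round half away from zero (for non-negative gray levels: half-up).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L), kind = "Mersenne-Twister")
  expr
}

# Deterministic derived seed (kept < 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807 + 11) %%
               2147483629)
}

# Pixel matrix extraction: accepts an angiogram or a bare numeric matrix.
as_pixels <- function(x) {
  if (inherits(x, "angiogram")) x$pixels else x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Grayscale morphology wrappers: EBImage clamps intensities to [0, 1],
# so 0-255 images are rescaled around the call.
gray_opening <- function(img, kern) {
  EBImage::opening(img / 255, kern) * 255
}

gray_closing <- function(img, kern) {
  EBImage::closing(img / 255, kern) * 255
}

disc_kernel <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

# 4-connected component labeling (EBImage::bwlabel is 4-connected).
label_components <- function(mask) {
  storage.mode(mask) <- "integer"
  m <- EBImage::bwlabel(mask)
  matrix(as.integer(m), nrow(mask), ncol(mask))
}

# Drop connected components smaller than min_area pixels.
remove_small_components <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
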