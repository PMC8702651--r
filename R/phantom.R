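#' Synthetic OCTA angiogram specification
#'
#' Parameters of the synthetic en-face angiogram generator. The phantom
#' emulates the geometry of a 3 mm x 3 mm macular superficial-plexus scan:
#' a handful of large trunk vessels growing inward from the field borders as
#' correlated random walks, capillary side branches spawned along them, a
#' perifoveal capillary arcade bounding a central avascular zone (FAZ) whose
#' boundary carries low-frequency jitter, optional extra capillary-dropout
#' pockets, and multiplicative gamma speckle (unit mean) over the stamped
#' intensities. Every downstream stage can then be tested against
#' pixel-exact ground-truth masks.
#'
#' Range-valued parameters (\code{n_large_trunks}, \code{large_width_px},
#' \code{cap_width_px}, \code{dropout_patches}, the gray ranges) are
#' length-2 \code{c(min, max)} vectors sampled per phantom/vessel.
#'
#' @param size_px Image side length in pixels.
#' @param field_size_mm Physical side length in mm.
#' @param n_large_trunks Range of the number of large trunks.
#' @param large_width_px Range of large-vessel calibers in px.
#' @param cap_width_px Range of capillary calibers in px.
#' @param branching_prob Per-step probability of spawning a capillary branch.
#' @param step_px Walk step length in px.
#' @param turn_sigma_deg SD of the per-step heading perturbation (degrees).
#' @param faz_semi_axes_mm FAZ ellipse semi-axes (mm), \code{c(a, b)}.
#' @param faz_jitter Relative amplitude of the FAZ boundary roughness.
#' @param dropout_patches Range of the number of extra avascular pockets.
#' @param vessel_gray_large,vessel_gray_cap Gray ranges for stamped vessels.
#' @param background_gray_mean Background gray level before speckle.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative speckle
#'   (larger = less noise).
#' @param seed Integer seed; identical spec + seed gives bit-exact output.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(size_px = 320L,
                         field_size_mm = 3.0,
                         n_large_trunks = c(2L, 4L),
                         large_width_px = c(5L, 9L),
                         cap_width_px = c(1L, 2L),
                         branching_prob = 0.08,
                         step_px = 3,
                         turn_sigma_deg = 12,
                         faz_semi_axes_mm = c(0.25, 0.20),
                         faz_jitter = 0.1,
                         dropout_patches = c(0L, 3L),
                         vessel_gray_large = c(180, 255),
                         vessel_gray_cap = c(90, 160),
                         background_gray_mean = 40,
                         speckle_shape = 4.0,
                         seed = 1L) {
  as_range <- function(x) if (length(x) == 1L) c(x, x) else x[1:2]
  spec <- structure(
    list(
      size_px = as.integer(size_px),
      field_size_mm = field_size_mm,
      n_large_trunks = as.integer(as_range(n_large_trunks)),
      large_width_px = as.integer(as_range(large_width_px)),
      cap_width_px = as.integer(as_range(cap_width_px)),
      branching_prob = branching_prob,
      step_px = step_px,
      turn_sigma_deg = turn_sigma_deg,
      faz_semi_axes_mm = faz_semi_axes_mm,
      faz_jitter = faz_jitter,
      dropout_patches = as.integer(as_range(dropout_patches)),
      vessel_gray_large = vessel_gray_large,
      vessel_gray_cap = vessel_gray_cap,
      background_gray_mean = background_gray_mean,
      speckle_shape = speckle_shape,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  if (spec$size_px < 64L) stopf("size_px must be >= 64")
  if (any(spec$large_width_px < 1L) || any(spec$cap_width_px < 1L)) {
    stopf("vessel widths must be >= 1 px")
  }
  if (any(spec$faz_semi_axes_mm >= spec$field_size_mm / 4)) {
    stopf("faz_semi_axes_mm must be < field_size_mm / 4")
  }
  if (spec$branching_prob < 0 || spec$branching_prob > 1) {
    stopf("branching_prob must lie in [0, 1]")
  }
  if (spec$speckle_shape <= 0) stopf("speckle_shape must be > 0")
  if (spec$step_px <= 0) stopf("step_px must be > 0")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "OCTA phantom spec: %d px / %.3g mm field, seed %d\n",
    x$size_px, x$field_size_mm, x$seed))
  cat(sprintf("  trunks %d-%d (width %d-%d px), capillary width %d-%d px, branching p=%.3g\n",
              x$n_large_trunks[1], x$n_large_trunks[2],
              x$large_width_px[1], x$large_width_px[2],
              x$cap_width_px[1], x$cap_width_px[2], x$branching_prob))
  cat(sprintf("  FAZ %.3g x %.3g mm (jitter %.3g), speckle shape %.3g\n",
              x$faz_semi_axes_mm[1], x$faz_semi_axes_mm[2], x$faz_jitter,
              x$speckle_shape))
  invisible(x)
}

#' Generate a synthetic angiogram with ground truth
#'
#' Deterministic under a fixed \code{spec} (bit-exact). Vessel pixels are
#' never stamped inside the FAZ or the dropout pockets, so the ground-truth
#' masks satisfy \code{gt_large} within \code{gt_vessel} and avascular FAZ /
#' dropout regions by construction. Raising \code{branching_prob} with the
#' same seed only adds capillaries (spawn decisions use pre-drawn per-site
#' uniforms), so the vessel mask grows monotonically.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return Object of class \code{phantom_bundle}: \code{image}
#'   (\code{\link{angiogram}}), logical masks \code{gt_vessel},
#'   \code{gt_large}, \code{gt_cap}, \code{gt_faz}, \code{gt_dropout}, and
#'   \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  phantom_render(geom, spec, derive_seed(spec$seed, 1L))
}

#' Repeated acquisitions of one phantom eye
#'
#' Emulates repeated OCTA imaging of the same eye within one session: the
#' vascular geometry (and hence every ground-truth mask) is identical across
#' repeats while the speckle realization is independent, with per-repeat
#' seeds derived deterministically from \code{spec$seed}.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param n_repeats Number of repeated acquisitions (>= 2).
#' @return List of \code{phantom_bundle}s sharing all ground-truth masks.
#' @export
phantom_repeat_series <- function(spec, n_repeats) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_repeats < 2L) stopf("n_repeats must be >= 2")
  geom <- phantom_geometry(spec)
  lapply(seq_len(n_repeats), function(i) {
    phantom_render(geom, spec, derive_seed(spec$seed, i))
  })
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("OCTA phantom (seed %d): %d x %d px\n", x$spec$seed,
              nrow(x$image$pixels), ncol(x$image$pixels)))
  cat(sprintf("  vessel density %.3f (large %.3f), FAZ %d px, dropout %d px\n",
              mean(x$gt_vessel), mean(x$gt_large), sum(x$gt_faz),
              sum(x$gt_dropout)))
  invisible(x)
}

# ---- internal geometry construction -------------------------------------

phantom_geometry <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$size_px
    mmpp <- spec$field_size_mm / n
    ctr <- (n + 1) / 2

    faz <- faz_mask(n, ctr, spec$faz_semi_axes_mm / mmpp, spec$faz_jitter)
    dropout <- dropout_mask(n, ctr, spec, mmpp, faz)
    forbidden <- faz$mask | dropout

    # phase 1: large trunks
    n_tr <- sample_range(spec$n_large_trunks)
    large <- matrix(FALSE, n, n)
    sites <- list()
    for (i in seq_len(n_tr)) {
      w <- sample_range(spec$large_width_px)
      walk <- trunk_walk(n, ctr, spec, faz, w)
      large <- stamp_disks(large, walk$pts, w / 2, forbidden)
      sites[[i]] <- cbind(walk$pts, heading = walk$headings)
    }
    sites <- do.call(rbind, sites)

    # phase 2: pre-draw spawn uniforms and child seeds for every site so
    # branching_prob only gates which branches exist
    caps <- matrix(FALSE, n, n)
    if (!is.null(sites) && nrow(sites) > 0L) {
      u <- stats::runif(nrow(sites))
      child_seeds <- sample.int(2147483600L, nrow(sites), replace = TRUE)
      for (i in which(u < spec$branching_prob)) {
        caps <- cap_branch(caps, sites[i, 1L], sites[i, 2L], sites[i, 3L],
                           depth = 1L, seed = child_seeds[i], spec = spec,
                           faz = faz, forbidden = forbidden, n = n)
      }
    }

    # perifoveal arcade and space-filling capillary mesh (only when
    # capillaries exist at all); both drawn under derived seeds so the main
    # stream -- and hence trunk/branch geometry -- is independent of them
    if (spec$branching_prob > 0) {
      caps <- with_seed(derive_seed(spec$seed, 7919L), {
        arcade_ring(caps, n, ctr, faz, spec, forbidden)
      })
      caps <- with_seed(derive_seed(spec$seed, 104729L), {
        mesh_capillaries(caps, n, spec, forbidden)
      })
    }

    vessel <- large | caps
    # anatomy gray levels (shared across repeated acquisitions)
    base <- matrix(spec$background_gray_mean, n, n)
    cap_only <- caps & !large
    base[cap_only] <- stats::runif(sum(cap_only), spec$vessel_gray_cap[1],
                                   spec$vessel_gray_cap[2])
    base[large] <- stats::runif(sum(large), spec$vessel_gray_large[1],
                                spec$vessel_gray_large[2])

    list(gt_large = large, gt_cap = cap_only, gt_vessel = vessel,
         gt_faz = faz$mask, gt_dropout = dropout, base = base)
  })
}

phantom_render <- function(geom, spec, noise_seed) {
  img <- with_seed(noise_seed, {
    speckle <- matrix(
      stats::rgamma(spec$size_px^2, shape = spec$speckle_shape,
                    rate = spec$speckle_shape),
      spec$size_px, spec$size_px)
    round_half_up(pmin(pmax(geom$base * speckle, 0), 255))
  })
  structure(
    list(image = angiogram(img, spec$field_size_mm),
         gt_vessel = geom$gt_vessel, gt_large = geom$gt_large,
         gt_cap = geom$gt_cap, gt_faz = geom$gt_faz,
         gt_dropout = geom$gt_dropout, spec = spec),
    class = "phantom_bundle"
  )
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

# FAZ: ellipse with low-frequency sinusoidal radial jitter; keeps the area
# close to pi*a*b while breaking perfect symmetry.
faz_mask <- function(n, ctr, semi_axes_px, jitter) {
  a <- semi_axes_px[1]
  b <- semi_axes_px[2]
  p1 <- stats::runif(1, 0, 2 * pi)
  p2 <- stats::runif(1, 0, 2 * pi)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- rr - ctr
  dx <- cc - ctr
  phi <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  radius <- ellipse_radius(phi, a, b) *
    (1 + jitter * (0.6 * sin(3 * phi + p1) + 0.4 * sin(5 * phi + p2)))
  list(mask = rho <= radius, a = a, b = b, p1 = p1, p2 = p2,
       jitter = jitter, ctr = ctr)
}

ellipse_radius <- function(phi, a, b) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

faz_boundary_radius <- function(faz, phi) {
  ellipse_radius(phi, faz$a, faz$b) *
    (1 + faz$jitter * (0.6 * sin(3 * phi + faz$p1) +
                         0.4 * sin(5 * phi + faz$p2)))
}

inside_faz <- function(faz, r, c, margin = 0) {
  dy <- r - faz$ctr
  dx <- c - faz$ctr
  sqrt(dx^2 + dy^2) <= faz_boundary_radius(faz, atan2(dy, dx)) + margin
}

dropout_mask <- function(n, ctr, spec, mmpp, faz) {
  k <- sample_range(spec$dropout_patches)
  m <- matrix(FALSE, n, n)
  if (k == 0L) return(m)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (i in seq_len(k)) {
    ang <- stats::runif(1, 0, 2 * pi)
    dist_px <- stats::runif(1, 0.8, 1.15) / mmpp
    cy <- ctr + dist_px * sin(ang)
    cx <- ctr + dist_px * cos(ang)
    ax <- stats::runif(1, 0.12, 0.20) / mmpp
    bx <- stats::runif(1, 0.12, 0.20) / mmpp
    th <- stats::runif(1, 0, pi)
    u <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
    v <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
    m <- m | ((u / ax)^2 + (v / bx)^2 <= 1)
  }
  m & !faz$mask
}

trunk_walk <- function(n, ctr, spec, faz, width) {
  side <- sample(1:4, 1L)
  t <- stats::runif(1, 0.15, 0.85) * n
  start <- switch(side,
                  c(1, t), c(n, t), c(t, 1), c(t, n))
  target <- c(ctr + stats::rnorm(1, 0, n / 6), ctr + stats::rnorm(1, 0, n / 6))
  base <- atan2(target[1] - start[1], target[2] - start[2])
  heading <- base
  max_steps <- ceiling(2.5 * n / spec$step_px)
  pts <- matrix(NA_real_, max_steps, 2L)
  headings <- numeric(max_steps)
  r <- start[1]
  c <- start[2]
  k <- 0L
  for (s in seq_len(max_steps)) {
    if (r < 1 || r > n || c < 1 || c > n) break
    # steer away from the FAZ so trunks skirt the avascular zone
    if (inside_faz(faz, r + spec$step_px * sin(heading) * 3,
                   c + spec$step_px * cos(heading) * 3,
                   margin = width / 2 + 2)) {
      heading <- heading + pi / 2
      base <- base + pi / 2
    }
    k <- k + 1L
    pts[k, ] <- c(r, c)
    headings[k] <- heading
    # mean-reverting heading: trunks curve gently but keep crossing the field
    heading <- heading - 0.15 * (heading - base) +
      stats::rnorm(1, 0, spec$turn_sigma_deg * pi / 180)
    r <- r + spec$step_px * sin(heading)
    c <- c + spec$step_px * cos(heading)
  }
  list(pts = pts[seq_len(k), , drop = FALSE],
       headings = headings[seq_len(k)])
}

# Capillary branch: path and all child spawn draws come from `seed` alone,
# so existing branches are unchanged when branching_prob grows.
cap_branch <- function(caps, r0, c0, heading0, depth, seed, spec, faz,
                       forbidden, n) {
  res <- with_seed(seed, {
    width <- sample_range(spec$cap_width_px)
    side <- sample(c(-1, 1), 1L)
    base <- heading0 + side * pi / 2 + stats::rnorm(1, 0, 0.35)
    heading <- base
    max_steps <- sample(ceiling(n / spec$step_px / 5):
                          ceiling(n / spec$step_px / 1.5), 1L)
    pts <- matrix(NA_real_, max_steps, 2L)
    headings <- numeric(max_steps)
    r <- r0
    c <- c0
    k <- 0L
    for (s in seq_len(max_steps)) {
      if (r < 1 || r > n || c < 1 || c > n) break
      if (inside_faz(faz, r, c, margin = width / 2)) break
      k <- k + 1L
      pts[k, ] <- c(r, c)
      headings[k] <- heading
      # tortuous but loosely direction-keeping
      heading <- heading - 0.05 * (heading - base) +
        stats::rnorm(1, 0, 2 * spec$turn_sigma_deg * pi / 180)
      r <- r + spec$step_px * sin(heading)
      c <- c + spec$step_px * cos(heading)
    }
    pts <- pts[seq_len(k), , drop = FALSE]
    headings <- headings[seq_len(k)]
    u <- if (k > 0L) stats::runif(k) else numeric(0)
    child_seeds <- if (k > 0L) {
      sample.int(2147483600L, k, replace = TRUE)
    } else integer(0)
    list(pts = pts, headings = headings, width = width, u = u,
         child_seeds = child_seeds)
  })
  if (nrow(res$pts) == 0L) return(caps)
  caps <- stamp_disks(caps, res$pts, res$width / 2, forbidden)
  if (depth < 2L) {
    for (i in which(res$u < spec$branching_prob)) {
      caps <- cap_branch(caps, res$pts[i, 1L], res$pts[i, 2L],
                         res$headings[i], depth + 1L, res$child_seeds[i],
                         spec, faz, forbidden, n)
    }
  }
  caps
}

# Space-filling capillary mesh: a jittered quadrilateral lattice of thin
# wiggly segments, emulating the dense intercapillary meshwork of the
# superficial plexus. Keeps incidental intercapillary gaps well below the
# non-perfusion detection threshold, so avascular regions on the phantom
# are only the FAZ and the stamped dropout pockets.
mesh_capillaries <- function(caps, n, spec, forbidden) {
  mmpp <- spec$field_size_mm / n
  s <- max(6L, round(0.12 / mmpp))  # ~0.12 mm lattice pitch
  coords <- seq(s / 2, n, by = s)
  ni <- length(coords)
  pr <- matrix(coords, ni, ni) +
    matrix(stats::runif(ni * ni, -0.3 * s, 0.3 * s), ni, ni)
  pc <- matrix(coords, ni, ni, byrow = TRUE) +
    matrix(stats::runif(ni * ni, -0.3 * s, 0.3 * s), ni, ni)
  for (i in seq_len(ni)) {
    for (j in seq_len(ni)) {
      for (dir in 1:2) {
        i2 <- i + (dir == 1L)
        j2 <- j + (dir == 2L)
        if (i2 > ni || j2 > ni) next
        p0 <- c(pr[i, j], pc[i, j])
        p1 <- c(pr[i2, j2], pc[i2, j2])
        mid <- (p0 + p1) / 2
        d <- p1 - p0
        perp <- c(-d[2], d[1]) / max(sqrt(sum(d^2)), 1e-9)
        mid <- mid + perp * stats::runif(1, -0.25 * s, 0.25 * s)
        width <- sample_range(spec$cap_width_px)
        caps <- stamp_disks(caps, rbind(p0, mid, p1), width / 2, forbidden)
      }
    }
  }
  caps
}

# Capillary ring just outside the FAZ boundary (the perifoveal arcade).
arcade_ring <- function(caps, n, ctr, faz, spec, forbidden) {
  width <- spec$cap_width_px[2]
  phis <- seq(0, 2 * pi, length.out = 540L)
  keep <- stats::runif(length(phis)) > 0.05  # occasional small gaps
  rad <- faz_boundary_radius(faz, phis) + width / 2 + 0.5
  pts <- cbind(ctr + rad * sin(phis), ctr + rad * cos(phis))[keep, ,
                                                            drop = FALSE]
  stamp_disks(caps, pts, width / 2, forbidden, connect = FALSE)
}

# Densify an ordered walk path so consecutive stamps overlap regardless of
# the step length / caliber ratio.
interpolate_path <- function(pts, spacing = 0.6) {
  if (nrow(pts) < 2L) return(pts)
  out <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    d <- sqrt(sum((pts[i + 1L, ] - pts[i, ])^2))
    k <- max(1L, ceiling(d / spacing))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(pts[i, 1L] + t * (pts[i + 1L, 1L] - pts[i, 1L]),
                      pts[i, 2L] + t * (pts[i + 1L, 2L] - pts[i, 2L]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

stamp_disks <- function(mask, pts, radius, forbidden, connect = TRUE) {
  if (connect) pts <- interpolate_path(pts)
  n <- nrow(mask)
  w <- ncol(mask)
  rad <- max(radius, 0)
  ir <- floor(rad)
  offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    rr <- round(pts[i, 1L]) + offs$dr
    cc <- round(pts[i, 2L]) + offs$dc
    ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= w
    if (!any(ok)) next
    idx <- cbind(rr[ok], cc[ok])
    sel <- !forbidden[idx]
    if (any(sel)) mask[idx[sel, , drop = FALSE]] <- TRUE
  }
  mask
}
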