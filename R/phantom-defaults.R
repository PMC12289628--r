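## Stated-world defaults for the synthetic phantoms. The three soil shape
## populations map onto the three shape-factor classes: long tubes (elongated,
## the dominant porosity carriers), spheres of 40-80 um (near-spherical
## mesopores) and small rough blobs of 12-24 um near the resolution floor
## (irregular micropores, the scale where smoothed-surface estimates drop the
## shape factor below 0.5). Stem vessels concentrate in 10-50 um diameters.

## minimal segment-segment distance (numeric 3-vectors)
seg_seg_dist <- function(p0, p1, q0, q1) {
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  dd <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  if (D < 1e-12) { sc <- 0 } else sc <- (b * e - cc * dd) / D
  sc <- min(max(sc, 0), 1)
  tc <- if (cc > 1e-12) (b * sc + e) / cc else 0
  tc <- min(max(tc, 0), 1)
  # re-clamp sc for the clamped tc
  if (a > 1e-12) sc <- min(max((b * tc - dd) / a, 0), 1)
  sqrt(sum((p0 + sc * u - (q0 + tc * v))^2))
}

prim_clearance <- function(p, q) {
  seg_of <- function(x) {
    if (x$type == "tube") list(a = x$p0, b = x$p1, r = x$r_vox)
    else list(a = x$c, b = x$c, r = x$r_vox)
  }
  s1 <- seg_of(p); s2 <- seg_of(q)
  seg_seg_dist(s1$a, s1$b, s2$a, s2$b) - s1$r - s2$r
}

sample_separated <- function(make_candidate, n, gap, max_tries = 200L) {
  placed <- list()
  geo <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- make_candidate()
      if (all(vapply(geo, function(g) prim_clearance(cand$geo, g) > gap,
                     logical(1)))) {
        placed[[i]] <- cand$prim
        geo[[i]] <- cand$geo
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place primitive ", i,
                  " without overlap; reduce counts or sizes")
  }
  placed
}

#' Default soil-core phantom specification
#'
#' Samples a well-separated set of pore primitives emulating a scanned soil
#' core: near-vertical elongated tubes with lognormal radii (diameters
#' 10-80 um), near-spherical pores of 40-80 um, and small irregular blobs of
#' 12-24 um, plus optional coarse root tubes. Defaults give a CT-resolvable
#' porosity of about 1% in a 1.5 mm cube at 6 um voxels, the resolution of
#' the study design this generator emulates.
#'
#' @param grid_shape grid dimensions in voxels (axis 1 vertical).
#' @param voxel_size micrometers per voxel.
#' @param n_tubes,n_spheres,n_blobs number of primitives per shape family.
#' @param n_roots number of root tubes (material `"root"`).
#' @param saturation target water fraction of pore volume.
#' @param seed integer seed (primitive placement and everything downstream).
#' @param noise_sd grayscale noise standard deviation.
#' @return A [phantom_spec()].
#' @export
soil_phantom_spec <- function(grid_shape = c(256, 256, 256), voxel_size = 6,
                              n_tubes = 60, n_spheres = 120, n_blobs = 150,
                              n_roots = 0, saturation = 0.4, seed = 1L,
                              noise_sd = 10) {
  d <- as.integer(grid_shape)
  with_seed(seed, {
    prims <- list()
    # root tubes first (largest structures)
    if (n_roots > 0) {
      roots <- sample_separated(function() {
        r_um <- runif(1, 30, 60)
        r <- r_um / voxel_size
        x2 <- runif(1, 0.25 * d[2], 0.75 * d[2])
        x3 <- runif(1, 0.25 * d[3], 0.75 * d[3])
        tilt <- runif(1, 0, 0.15)
        az <- runif(1, 0, 2 * pi)
        p0 <- c(3 + r, x2, x3)
        p1 <- c(d[1] - 2 - r,
                x2 + tilt * d[1] * cos(az), x3 + tilt * d[1] * sin(az))
        list(prim = list(type = "tube", p0 = p0, p1 = p1, radius_um = r_um,
                         material = "root"),
             geo = list(type = "tube", p0 = p0, p1 = p1, r_vox = r))
      }, n_roots, gap = 3)
      prims <- c(prims, roots)
    }
    tubes <- sample_separated(function() {
      r_um <- min(max(rlnorm(1, log(12), 0.35), 5), 40)
      r <- r_um / voxel_size
      len <- runif(1, 0.35, 0.6) * min(d)   # tube spans 35-60% of the core
      polar <- runif(1, 0, 40) * pi / 180   # biopores: biased near-vertical
      az <- runif(1, 0, 2 * pi)
      u <- c(cos(polar), sin(polar) * cos(az), sin(polar) * sin(az))
      ctr <- c(runif(1, len / 2 + r + 2, d[1] - len / 2 - r - 2),
               runif(1, len / 2 + r + 2, d[2] - len / 2 - r - 2),
               runif(1, len / 2 + r + 2, d[3] - len / 2 - r - 2))
      p0 <- ctr - u * len / 2; p1 <- ctr + u * len / 2
      list(prim = list(type = "tube", p0 = p0, p1 = p1, radius_um = r_um),
           geo = list(type = "tube", p0 = p0, p1 = p1, r_vox = r))
    }, n_tubes, gap = 3)
    spheres <- sample_separated_extra(function() {
      r_um <- runif(1, 20, 40)
      r <- r_um / voxel_size
      ctr <- runif(3, r + 3, d - r - 2)
      list(prim = list(type = "sphere", center = ctr, radius_um = r_um),
           geo = list(type = "sphere", c = ctr, r_vox = r))
    }, n_spheres, gap = 3, fixed = prim_geo(c(prims, tubes), voxel_size))
    blobs <- sample_separated_extra(function() {
      d_um <- runif(1, 12, 24)
      vol <- pi / 6 * d_um^3
      r <- 2 * (3 * vol / (4 * pi))^(1 / 3) / voxel_size + 2
      ctr <- round(runif(3, r + 3, d - r - 2))
      list(prim = list(type = "blob", center = ctr, volume_um3 = vol,
                       irregularity = 0.7),
           geo = list(type = "sphere", c = ctr, r_vox = r))
    }, n_blobs, gap = 2,
      fixed = c(prim_geo(c(prims, tubes), voxel_size),
                prim_geo_list(spheres)))
    phantom_spec(grid_shape = d, voxel_size = voxel_size,
                 primitives = c(prims, tubes,
                                lapply(spheres, `[[`, "prim"),
                                lapply(blobs, `[[`, "prim")),
                 phase_levels = default_phase_levels(noise_sd),
                 saturation = saturation, rng_seed = seed)
  })
}

## variant that also respects a fixed set of already-placed geometries
sample_separated_extra <- function(make_candidate, n, gap, fixed,
                                   max_tries = 200L) {
  placed <- list()
  geo <- fixed
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- make_candidate()
      if (all(vapply(geo, function(g) prim_clearance(cand$geo, g) > gap,
                     logical(1)))) {
        placed[[i]] <- cand
        geo[[length(geo) + 1L]] <- cand$geo
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place primitive ", i,
                  " without overlap; reduce counts or sizes")
  }
  placed
}

prim_geo <- function(prims, voxel_size) {
  lapply(prims, function(p) {
    if (p$type == "tube")
      list(type = "tube", p0 = p$p0, p1 = p$p1,
           r_vox = p$radius_um / voxel_size)
    else if (p$type == "sphere")
      list(type = "sphere", c = p$center, r_vox = p$radius_um / voxel_size)
    else
      list(type = "sphere", c = p$center,
           r_vox = 2 * (3 * p$volume_um3 / (4 * pi))^(1 / 3) / voxel_size + 2)
  })
}

prim_geo_list <- function(placed) lapply(placed, `[[`, "geo")

#' Default stem-segment phantom specification
#'
#' Samples a bundle of near-vertical vessel tubes inside a circular stem
#' cross-section. Vessel diameters are lognormal, concentrated in 10-50 um
#' (the dominant class of the shrub stems this generator emulates), at the
#' 3 um voxel size of the stem scans.
#'
#' @param grid_shape grid dimensions in voxels (axis 1 vertical).
#' @param voxel_size micrometers per voxel.
#' @param n_vessels number of vessel tubes.
#' @param embolism_rate fraction of vessels flagged embolized.
#' @param seed integer seed.
#' @param noise_sd grayscale noise standard deviation.
#' @param stem_radius_frac stem disc radius as fraction of grid half-width.
#' @return A [phantom_spec()].
#' @export
stem_phantom_spec <- function(grid_shape = c(96, 200, 200), voxel_size = 3,
                              n_vessels = 60, embolism_rate = 0.25, seed = 1L,
                              noise_sd = 10, stem_radius_frac = 0.9) {
  d <- as.integer(grid_shape)
  with_seed(seed, {
    cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
    rstem <- stem_radius_frac * (min(d[2], d[3]) - 1) / 2
    tubes <- sample_separated(function() {
      d_um <- min(max(rlnorm(1, log(22), 0.35), 8), 60)
      r <- d_um / 2 / voxel_size
      rho <- sqrt(runif(1)) * (rstem - r - 3)
      az <- runif(1, 0, 2 * pi)
      x2 <- cy + rho * cos(az); x3 <- cz + rho * sin(az)
      jit <- rnorm(2, 0, 0.02) * d[1]   # near-vertical: slight tilt
      p0 <- c(1, x2, x3)
      p1 <- c(d[1], x2 + jit[1], x3 + jit[2])
      list(prim = list(type = "tube", p0 = p0, p1 = p1, radius_um = d_um / 2),
           geo = list(type = "tube", p0 = p0, p1 = p1, r_vox = r))
    }, n_vessels, gap = 2.5)
    phantom_spec(grid_shape = d, voxel_size = voxel_size,
                 primitives = tubes,
                 phase_levels = default_phase_levels(noise_sd),
                 embolism_rate = embolism_rate, rng_seed = seed)
  })
}
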