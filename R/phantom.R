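#' Specification of a synthetic CT phantom
#'
#' Describes a synthetic grayscale volume: grid shape, voxel size, the
#' geometric primitives that carve the pore (or vessel) space, the grayscale
#' mean and noise standard deviation of each material phase, the target water
#' saturation of the pore space and the embolized fraction of vessel tubes.
#' Phase means default to the X-ray attenuation ordering
#' air < water < root < solid.
#'
#' Primitives are lists with a `type` field:
#' \describe{
#'   \item{sphere}{`center` (voxel coordinates), `radius_um`}
#'   \item{tube}{`p0`, `p1` (axis endpoints, voxel coordinates), `radius_um`}
#'   \item{blob}{`center`, `volume_um3` (target), `irregularity` in `[0, 1]`}
#' }
#' An optional `material` field (`"pore"`, default, or `"root"`) controls the
#' grayscale a dry primitive receives.
#'
#' @param grid_shape three positive integers (voxels); first axis is vertical.
#' @param voxel_size micrometers per voxel edge.
#' @param primitives list of primitive specs (see Details).
#' @param phase_levels named list with entries `air`, `water`, `root`,
#'   `solid`, each `c(mean, sd)` in intensity units.
#' @param saturation target water volume fraction of total pore volume.
#' @param embolism_rate fraction of tubes flagged embolized (stem phantoms).
#' @param rng_seed integer seed governing noise, blob growth and random
#'   water/embolism assignment.
#' @param max_overlap_frac overlap fraction (overlapping voxels / primitive
#'   voxels) above which [make_soil_phantom()] warns.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size, primitives,
                         phase_levels = default_phase_levels(),
                         saturation = 0, embolism_rate = 0,
                         rng_seed = 1L, max_overlap_frac = 0.05) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("'grid_shape' must be three positive integers (>= 2)")
  if (voxel_size <= 0) stop("'voxel_size' must be > 0")
  if (saturation < 0 || saturation > 1) stop("'saturation' must be in [0, 1]")
  if (embolism_rate < 0 || embolism_rate > 1)
    stop("'embolism_rate' must be in [0, 1]")
  mu <- vapply(phase_levels, `[`, numeric(1), 1L)
  if (anyDuplicated(mu)) stop("phase mean grayscales must be pairwise distinct")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 primitives = primitives, phase_levels = phase_levels,
                 saturation = saturation, embolism_rate = embolism_rate,
                 rng_seed = as.integer(rng_seed),
                 max_overlap_frac = max_overlap_frac),
            class = "phantom_spec")
}

#' Default grayscale levels of the four material phases
#'
#' Means follow the attenuation ordering air < water < root < solid with a
#' common noise standard deviation of 10 intensity units, giving a multimodal
#' histogram with clean inter-mode valleys of the kind global histogram
#' thresholding assumes.
#'
#' @param noise_sd Gaussian noise standard deviation applied to every phase.
#' @return Named list of `c(mean, sd)` pairs.
#' @export
default_phase_levels <- function(noise_sd = 10) {
  list(air = c(30, noise_sd), water = c(90, noise_sd),
       root = c(120, noise_sd), solid = c(180, noise_sd))
}

## ---- seeded evaluation that does not disturb the caller's RNG --------------
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## ---- rasterizers: return linear voxel indices ------------------------------
rast_sphere <- function(center, r_vox, d) {
  lo <- pmax(1L, floor(center - r_vox))
  hi <- pmin(d, ceiling(center + r_vox))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dist2 <- outer(outer((ix - center[1])^2, (iy - center[2])^2, "+"),
                 (iz - center[3])^2, "+")
  sel <- which(dist2 <= r_vox^2, arr.ind = TRUE)
  if (!nrow(sel)) return(integer(0))
  as.integer(ix[sel[, 1]] + d[1] * (iy[sel[, 2]] - 1L) +
               d[1] * d[2] * (iz[sel[, 3]] - 1L))
}

rast_tube <- function(p0, p1, r_vox, d) {
  lo <- pmax(1L, floor(pmin(p0, p1) - r_vox))
  hi <- pmin(d, ceiling(pmax(p0, p1) + r_vox))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- array(ix, c(nx, ny, nz)) - p0[1]
  Y <- array(rep(iy, each = nx), c(nx, ny, nz)) - p0[2]
  Z <- array(rep(iz, each = nx * ny), c(nx, ny, nz)) - p0[3]
  u <- p1 - p0
  L2 <- sum(u^2)
  t <- (X * u[1] + Y * u[2] + Z * u[3]) / L2
  # finite cylinder with flat ends (not a capsule): axial distance within
  # [0, 1] and radial distance within r
  dist2 <- (X - t * u[1])^2 + (Y - t * u[2])^2 + (Z - t * u[3])^2
  sel <- which(dist2 <= r_vox^2 & t >= 0 & t <= 1, arr.ind = TRUE)
  if (!nrow(sel)) return(integer(0))
  as.integer(ix[sel[, 1]] + d[1] * (iy[sel[, 2]] - 1L) +
               d[1] * d[2] * (iz[sel[, 3]] - 1L))
}

# Conditioned random aggregation: grow a rough cluster from a seed voxel until
# the target count is reached. Low irregularity prefers high-contact (compact)
# candidates, high irregularity adds boundary voxels nearly uniformly.
rast_blob <- function(center, target_vox, irregularity, d) {
  target_vox <- max(1L, as.integer(round(target_vox)))
  half <- max(4L, ceiling(2.5 * target_vox^(1 / 3)))
  n <- 2L * half + 1L
  m <- array(FALSE, c(n, n, n))
  ctr <- c(half + 1L, half + 1L, half + 1L)
  m[ctr[1], ctr[2], ctr[3]] <- TRUE
  count <- 1L
  face <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (count < target_vox) {
    occ <- which(m, arr.ind = TRUE)
    cand <- unique(do.call(rbind, lapply(seq_len(6), function(f)
      sweep(occ, 2, face[f, ], "+"))))
    keep <- cand[, 1] >= 2 & cand[, 1] <= n - 1 & cand[, 2] >= 2 &
      cand[, 2] <= n - 1 & cand[, 3] >= 2 & cand[, 3] <= n - 1
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[!m[cand], , drop = FALSE]
    if (!nrow(cand)) break
    nb <- vapply(seq_len(nrow(cand)), function(q) {
      p <- cand[q, ]
      sum(m[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1),
            (p[3] - 1):(p[3] + 1)])
    }, numeric(1))
    w <- nb^(3 * (1 - irregularity)) * runif(nrow(cand))
    take <- order(w, decreasing = TRUE)[seq_len(min(nrow(cand),
                                                    max(1L, nrow(cand) %/% 4L),
                                                    target_vox - count))]
    m[cand[take, , drop = FALSE]] <- TRUE
    count <- count + length(take)
  }
  occ <- which(m, arr.ind = TRUE)
  occ <- sweep(occ, 2, ctr - round(center), "-")
  keep <- occ[, 1] >= 1 & occ[, 1] <= d[1] & occ[, 2] >= 1 &
    occ[, 2] <= d[2] & occ[, 3] >= 1 & occ[, 3] <= d[3]
  occ <- occ[keep, , drop = FALSE]
  as.integer(occ[, 1] + d[1] * (occ[, 2] - 1L) + d[1] * d[2] * (occ[, 3] - 1L))
}

rasterize_primitive <- function(pr, voxel_size, d) {
  switch(pr$type,
    sphere = rast_sphere(pr$center, pr$radius_um / voxel_size, d),
    tube   = rast_tube(pr$p0, pr$p1, pr$radius_um / voxel_size, d),
    blob   = rast_blob(pr$center, pr$volume_um3 / voxel_size^3,
                       pr$irregularity, d),
    stop("unknown primitive type: ", pr$type))
}

analytic_volume_um3 <- function(pr, voxel_size) {
  switch(pr$type,
    sphere = 4 / 3 * pi * pr$radius_um^3,
    tube   = pi * pr$radius_um^2 *
      (sqrt(sum((pr$p1 - pr$p0)^2)) * voxel_size),
    blob   = pr$volume_um3)
}

true_diameter_um <- function(pr, vol_um3) {
  switch(pr$type,
    sphere = 2 * pr$radius_um,
    tube   = 2 * pr$radius_um,     # conduit diameter
    blob   = (6 * vol_um3 / pi)^(1 / 3))
}

shape_family <- function(type) {
  switch(type, tube = "elongated", sphere = "near-spherical",
         blob = "irregular")
}

#' Generate a synthetic soil-core volume with ground truth
#'
#' Rasterizes the primitives of a [phantom_spec()] into a grayscale volume:
#' background voxels carry the solid-phase intensity, pore primitives carry
#' air or water intensity according to the greedy water assignment (see
#' [assign_water()]), root primitives carry the root intensity. Additive
#' Gaussian noise is drawn per phase at the stated standard deviations. The
#' whole construction is a deterministic function of the spec, including its
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [voxel_grid()]), `truth` (the ground-truth
#'   bundle: `$primitives` data frame and `$global` summary) and `labels`
#'   (integer array, voxel ownership by primitive id, 0 = background).
#' @export
make_soil_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!length(spec$primitives)) stop("primitive list is empty")
  d <- spec$grid_shape
  with_seed(spec$rng_seed, {
    lab <- array(0L, d)
    np <- length(spec$primitives)
    vox_count <- integer(np)
    overlap_count <- integer(np)
    for (q in seq_len(np)) {
      idx <- rasterize_primitive(spec$primitives[[q]], spec$voxel_size, d)
      free <- lab[idx] == 0L
      lab[idx[free]] <- q
      vox_count[q] <- sum(free)
      overlap_count[q] <- sum(!free)
    }
    ofrac <- sum(overlap_count) / max(1L, sum(vox_count) + sum(overlap_count))
    if (ofrac > spec$max_overlap_frac)
      warning(sprintf(paste0("primitive overlap fraction %.3f exceeds %.3f; ",
                             "overlapping voxels kept with their first owner"),
                      ofrac, spec$max_overlap_frac))
    vv <- spec$voxel_size^3
    prims <- data.frame(
      id = seq_len(np),
      family = vapply(spec$primitives, function(p) shape_family(p$type), ""),
      material = vapply(spec$primitives, function(p)
        if (is.null(p$material)) "pore" else p$material, ""),
      true_volume_um3 = vapply(spec$primitives, analytic_volume_um3,
                               numeric(1), voxel_size = spec$voxel_size),
      voxel_count = vox_count,
      volume_um3 = vox_count * vv,
      overlap_voxels = overlap_count,
      water = FALSE, embolized = FALSE,
      stringsAsFactors = FALSE)
    prims$true_diameter_um <- mapply(function(p, v) true_diameter_um(p, v),
                                     spec$primitives, prims$true_volume_um3)
    # blobs have no analytic volume beyond the target; report the voxelized one
    isblob <- prims$family == "irregular"
    prims$true_volume_um3[isblob] <- prims$volume_um3[isblob]
    prims$true_diameter_um[isblob] <-
      (6 * prims$volume_um3[isblob] / pi)^(1 / 3)

    truth <- list(primitives = prims, global = NULL)
    truth <- assign_water(truth, spec$saturation, rule = "smallest-first")
    prims <- truth$primitives

    lev <- spec$phase_levels
    vol <- array(rnorm(prod(d), lev$solid[1], lev$solid[2]), d)
    occ <- which(lab > 0L)
    by_prim <- split(occ, lab[occ])
    for (qc in names(by_prim)) {
      q <- as.integer(qc)
      sel <- by_prim[[qc]]
      ph <- if (prims$material[q] == "root") lev$root
            else if (prims$water[q]) lev$water else lev$air
      vol[sel] <- rnorm(length(sel), ph[1], ph[2])
    }

    pore <- prims$material == "pore"
    roi_vol <- prod(d) * vv
    truth$global <- list(
      roi_volume_um3 = roi_vol,
      porosity = sum(prims$volume_um3[pore]) / roi_vol,
      water_volume_um3 = sum(prims$volume_um3[pore & prims$water]),
      pore_volume_um3 = sum(prims$volume_um3[pore]),
      saturation_achieved = if (any(pore))
        sum(prims$volume_um3[pore & prims$water]) /
          sum(prims$volume_um3[pore]) else NA_real_,
      class_counts = table(prims$family[pore]))
    list(volume = voxel_grid(vol, spec$voxel_size), truth = truth,
         labels = lab)
  })
}

#' Assign the water phase to pore primitives
#'
#' Greedy per-primitive filling: primitives are wholly water or wholly air.
#' Under `"smallest-first"` (the capillary ordering: narrow pores hold water
#' by stronger capillary forces) primitives are sorted by true diameter
#' ascending and filled until adding the next would overshoot
#' `saturation * total pore volume`; under `"random"` the order is a seeded
#' permutation. `saturation = 1` fills everything.
#'
#' @param truth ground-truth bundle from a phantom constructor (or a list with
#'   a `$primitives` data frame).
#' @param saturation target water fraction of total pore volume, in `[0, 1]`.
#' @param rule `"smallest-first"` or `"random"`.
#' @return The bundle with `water` flags set.
#' @export
assign_water <- function(truth, saturation, rule = c("smallest-first", "random")) {
  rule <- match.arg(rule)
  if (saturation < 0 || saturation > 1) stop("'saturation' must be in [0, 1]")
  pr <- truth$primitives
  pr$water <- FALSE
  pore <- which(pr$material == "pore")
  if (length(pore) && saturation > 0) {
    if (saturation >= 1) {
      pr$water[pore] <- TRUE
    } else {
      ord <- if (rule == "smallest-first")
        pore[order(pr$true_diameter_um[pore], pr$id[pore])]
      else pore[sample.int(length(pore))]
      target <- saturation * sum(pr$volume_um3[pore])
      acc <- 0
      for (q in ord) {
        if (acc + pr$volume_um3[q] > target) break
        pr$water[q] <- TRUE
        acc <- acc + pr$volume_um3[q]
      }
    }
  }
  truth$primitives <- pr
  truth
}

#' Generate a synthetic stem segment with a vessel bundle
#'
#' Builds a near-vertical bundle of tube primitives (the vessel lumina) inside
#' a circular stem cross-section of wall material; voxels outside the stem are
#' air. `round(embolism_rate * n_tubes)` tubes (a seeded random subset) carry
#' air intensity (embolized), the rest water intensity. Tube radii below one
#' voxel are rejected: the lumen would be unresolvable at this voxel size.
#'
#' @param spec a [phantom_spec()] whose primitives are all tubes.
#' @param stem_radius_frac stem radius as a fraction of the half-width of the
#'   in-plane grid.
#' @return A list with `volume`, `truth`, `labels` as in
#'   [make_soil_phantom()], plus `stem_area_um2` (cross-section area of the
#'   stem disc).
#' @export
make_stem_phantom <- function(spec, stem_radius_frac = 0.9) {
  stopifnot(inherits(spec, "phantom_spec"))
  types <- vapply(spec$primitives, `[[`, "", "type")
  if (!length(types) || any(types != "tube"))
    stop("stem phantom primitives must all be tubes")
  rad_vox <- vapply(spec$primitives, function(p) p$radius_um, numeric(1)) /
    spec$voxel_size
  if (any(rad_vox < 1))
    stop(sprintf(paste0("tube radius below the resolution floor of 1 voxel ",
                        "(%.3g um at this voxel size)"), spec$voxel_size))
  d <- spec$grid_shape
  with_seed(spec$rng_seed, {
    lab <- array(0L, d)
    np <- length(spec$primitives)
    vox_count <- integer(np)
    for (q in seq_len(np)) {
      idx <- rasterize_primitive(spec$primitives[[q]], spec$voxel_size, d)
      free <- lab[idx] == 0L
      lab[idx[free]] <- q
      vox_count[q] <- sum(free)
    }
    vv <- spec$voxel_size^3
    prims <- data.frame(
      id = seq_len(np), family = "elongated", material = "vessel",
      true_volume_um3 = vapply(spec$primitives, analytic_volume_um3,
                               numeric(1), voxel_size = spec$voxel_size),
      voxel_count = vox_count, volume_um3 = vox_count * vv,
      overlap_voxels = 0L,
      true_diameter_um = vapply(spec$primitives, function(p)
        2 * p$radius_um, numeric(1)),
      water = TRUE, embolized = FALSE, stringsAsFactors = FALSE)
    n_emb <- round(spec$embolism_rate * np)
    if (n_emb > 0) {
      emb <- sample.int(np, n_emb)
      prims$embolized[emb] <- TRUE
      prims$water[emb] <- FALSE
    }

    # stem disc in-plane (axes 2,3), full height along axis 1
    cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
    rstem <- stem_radius_frac * (min(d[2], d[3]) - 1) / 2
    dy2 <- (seq_len(d[2]) - cy)^2
    dz2 <- (seq_len(d[3]) - cz)^2
    disc <- outer(dy2, dz2, "+") <= rstem^2
    lev <- spec$phase_levels
    vol <- array(rnorm(prod(d), lev$air[1], lev$air[2]), d)
    in_stem <- rep(as.vector(disc), each = d[1])
    vol[in_stem] <- rnorm(sum(in_stem), lev$solid[1], lev$solid[2])
    occ <- which(lab > 0L)
    by_prim <- split(occ, lab[occ])
    for (qc in names(by_prim)) {
      q <- as.integer(qc)
      sel <- by_prim[[qc]]
      ph <- if (prims$embolized[q]) lev$air else lev$water
      vol[sel] <- rnorm(length(sel), ph[1], ph[2])
    }
    truth <- list(primitives = prims, global = list(
      roi_volume_um3 = prod(d) * vv,
      n_tubes = np, n_embolized = n_emb,
      embolism_rate = 100 * n_emb / np,
      stem_area_um2 = pi * (rstem * spec$voxel_size)^2))
    list(volume = voxel_grid(vol, spec$voxel_size), truth = truth,
         labels = lab, stem_area_um2 = pi * (rstem * spec$voxel_size)^2)
  })
}
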