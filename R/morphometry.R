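#' Equivalent spherical diameter from a 3D volume
#'
#' Diameter of the sphere with the same volume: `(6 V / pi)^(1/3)`.
#'
#' @param volume volume(s) in cubic micrometers, positive.
#' @return Diameter(s) in micrometers.
#' @export
equivalent_diameter_3d <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (6 * volume / pi)^(1 / 3)
}

#' Pore shape factor
#'
#' `SF = Sp^3 / (36 pi Vp^2)`: 1 for an exact sphere, above 1 for elongated
#' shapes, and below 1 only where the (smoothed) surface estimate drops under
#' the sphere-equivalent surface — which is precisely how the irregular class
#' (SF < 0.5) of small rough pores arises.
#'
#' @param Sp surface area(s), square micrometers.
#' @param Vp volume(s), cubic micrometers.
#' @return Dimensionless shape factor(s).
#' @export
shape_factor <- function(Sp, Vp) {
  if (any(Sp <= 0) || any(Vp <= 0)) stop("Sp and Vp must be positive")
  Sp^3 / (36 * pi * Vp^2)
}

#' Size and shape classification of pores
#'
#' Size classes by equivalent diameter: micropores `[5, 30)` um, mesopores
#' `[30, 80]` um, macropores `(80, Inf)` um; diameters below 5 um are
#' sub-resolution and flagged for exclusion from summaries. Shape classes by
#' shape factor: irregular `SF < 0.5`, near-spherical `0.5 <= SF <= 1`,
#' elongated `SF > 1`.
#'
#' @param d equivalent diameter(s), micrometers.
#' @param SF shape factor(s).
#' @return Data frame with `size_class`, `shape_class`, `sub_resolution`.
#' @export
classify_pore <- function(d, SF) {
  size <- ifelse(d < 5, "sub-resolution",
          ifelse(d < 30, "micro",
          ifelse(d <= 80, "meso", "macro")))
  shape <- ifelse(SF < 0.5, "irregular",
           ifelse(SF <= 1, "near-spherical", "elongated"))
  data.frame(size_class = factor(size, c("micro", "meso", "macro",
                                         "sub-resolution")),
             shape_class = factor(shape, c("irregular", "near-spherical",
                                           "elongated")),
             sub_resolution = d < 5)
}

#' Label 26-connected components and tabulate per-pore morphometry
#'
#' Labels the mask, then computes per component: volume (voxel count times
#' voxel volume), smoothed surface area (coarea estimator, see
#' `vignette("ctmorph-methods")`), equivalent diameter, shape factor, the
#' size/shape classes, and — when a water mask is supplied — the water volume
#' inside the component and a water-filled flag (majority of the component's
#' voxels water).
#'
#' @param mask a [phase_mask()] of the pore (or root/vessel) phase.
#' @param water optional [phase_mask()] of the water phase, same shape.
#' @param sigma Gaussian smoothing length of the surface estimator, voxels.
#' @param drop_border drop components touching the volume border.
#' @return A `region_table`: data frame with one row per component plus
#'   attributes `voxel_size`, `labels` (the label array).
#' @export
label_components <- function(mask, water = NULL, sigma = 1, drop_border = FALSE) {
  d <- dim(mask$data)
  lab <- cpp_label26(as.logical(mask$data), as.integer(d))
  nlab <- attr(lab, "nlab")
  vs <- mask$voxel_size
  if (nlab == 0) {
    tb <- data.frame(label = integer(0), voxel_count = integer(0),
                     volume_um3 = numeric(0), surface_um2 = numeric(0),
                     equiv_diameter_um = numeric(0), shape_factor = numeric(0),
                     size_class = factor(character(0)),
                     shape_class = factor(character(0)),
                     sub_resolution = logical(0),
                     water_volume_um3 = numeric(0), water_filled = logical(0),
                     border = logical(0))
    attr(tb, "voxel_size") <- vs
    attr(tb, "labels") <- array(0L, d)
    class(tb) <- c("region_table", "data.frame")
    return(tb)
  }
  st <- cpp_label_stats(lab, as.integer(d), nlab)
  surf_vox <- cpp_surface_by_label(lab, as.integer(d), nlab, st$lo, st$hi,
                                   sigma)
  vol <- st$count * vs^3
  surf <- surf_vox * vs^2
  dia <- equivalent_diameter_3d(vol)
  sf <- shape_factor(surf, vol)
  cls <- classify_pore(dia, sf)
  border <- st$lo[, 1] == 1 | st$lo[, 2] == 1 | st$lo[, 3] == 1 |
    st$hi[, 1] == d[1] | st$hi[, 2] == d[2] | st$hi[, 3] == d[3]
  wvol <- rep(0, nlab); wfill <- rep(FALSE, nlab)
  if (!is.null(water)) {
    if (!identical(dim(water$data), d)) stop("water mask shape mismatch")
    wl <- lab[which(water$data)]
    wl <- wl[wl > 0]
    if (length(wl)) {
      tabw <- table(wl)
      wvol[as.integer(names(tabw))] <- as.integer(tabw) * vs^3
    }
    wfill <- wvol > 0.5 * vol
  }
  tb <- data.frame(label = seq_len(nlab), voxel_count = st$count,
                   volume_um3 = vol, surface_um2 = surf,
                   equiv_diameter_um = dia, shape_factor = sf,
                   size_class = cls$size_class, shape_class = cls$shape_class,
                   sub_resolution = cls$sub_resolution,
                   water_volume_um3 = wvol, water_filled = wfill,
                   border = border)
  if (drop_border) tb <- tb[!tb$border, , drop = FALSE]
  attr(tb, "voxel_size") <- vs
  attr(tb, "labels") <- array(lab, d)
  class(tb) <- c("region_table", "data.frame")
  tb
}

#' Proportion of water-filled pores
#'
#' Per group (size class or shape class): in `"volume"` mode the summed water
#' volume over the summed pore volume; in `"number"` mode the count of
#' water-filled pores over the pore count. Sub-resolution pores are excluded.
#'
#' @param regions a region table from [label_components()].
#' @param by `"volume"` or `"number"`.
#' @param group_by `"size_class"`, `"shape_class"` or `"none"` (single total).
#' @return Data frame with `group`, `pwp_percent` (NA for empty groups).
#' @export
pwp <- function(regions, by = c("volume", "number"),
                group_by = c("size_class", "shape_class", "none")) {
  by <- match.arg(by)
  group_by <- match.arg(group_by)
  r <- regions[!regions$sub_resolution, , drop = FALSE]
  g <- if (group_by == "none") factor(rep("all", nrow(r)))
       else droplevels_keep(r[[group_by]])
  levs <- levels(g)
  out <- data.frame(group = levs, pwp_percent = NA_real_)
  for (i in seq_along(levs)) {
    sel <- which(g == levs[i])
    if (!length(sel)) next
    out$pwp_percent[i] <- if (by == "volume")
      100 * sum(r$water_volume_um3[sel]) / sum(r$volume_um3[sel])
    else
      100 * sum(r$water_filled[sel]) / length(sel)
  }
  out
}

## keep all declared levels except the bookkeeping one
droplevels_keep <- function(f) {
  factor(f, levels = setdiff(levels(f), "sub-resolution"))
}
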