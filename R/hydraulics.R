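#' Viscosity of water at 20 degrees C, in MPa s
#'
#' Configuration constant of the Hagen-Poiseuille conductivity; diameters are
#' supplied in micrometers and converted to meters internally.
#' @export
eta_water_20C <- 1.002e-9

#' Hydraulic diameter of a vessel population
#'
#' Fourth root of the mean fourth power of the equivalent diameters: the
#' uniform diameter giving the same per-vessel Poiseuille conductance.
#'
#' @param D vessel equivalent diameters, micrometers (positive, non-empty).
#' @return Hydraulic diameter, micrometers.
#' @examples
#' hydraulic_diameter(c(10, 20))  # (85000/2)^(1/4)... = 17.07
#' @export
hydraulic_diameter <- function(D) {
  if (!length(D)) stop("empty diameter list")
  if (any(D <= 0)) stop("diameters must be positive")
  (mean(D^4))^(1 / 4)
}

#' Diameter contributing 95% of hydraulic conductance (D95)
#'
#' Sort diameters descending, accumulate fourth powers until the running sum
#' first reaches at least 95% of the total, and return the arithmetic mean of
#' the included diameters. Fourth-power weighting means few large vessels
#' carry most of the conductance.
#'
#' @param D vessel equivalent diameters, micrometers.
#' @param frac conductance fraction (default 0.95).
#' @return D95 in micrometers.
#' @examples
#' d95(c(30, 20, 10))  # 25: the 30 and 20 um vessels carry >= 95% of sum(D^4)
#' @export
d95 <- function(D, frac = 0.95) {
  if (!length(D)) stop("empty diameter list")
  if (any(D <= 0)) stop("diameters must be positive")
  ds <- sort(D, decreasing = TRUE)
  cum <- cumsum(ds^4)
  k <- which(cum >= frac * cum[length(cum)])[1]
  mean(ds[seq_len(k)])
}

#' Hagen-Poiseuille hydraulic conductivity
#'
#' `K = sum(pi * d_i^4 / (128 * eta))` over vessels, with diameters converted
#' from micrometers to meters; `eta` in MPa s gives K in
#' kg s^-1 m^-1 MPa^-1 (the printed equation omits the fluid density term of
#' the mass-flow form; it is followed verbatim). Additive over vessels by
#' construction; an empty population has K = 0.
#'
#' @param D vessel equivalent diameters, micrometers.
#' @param eta water viscosity in MPa s (default [eta_water_20C]).
#' @return Conductivity, kg s^-1 m^-1 MPa^-1.
#' @export
poiseuille_conductivity <- function(D, eta = eta_water_20C) {
  if (eta <= 0) stop("'eta' must be positive")
  if (!length(D)) return(0)
  if (any(D <= 0)) stop("diameters must be positive")
  sum(pi * (D * 1e-6)^4 / (128 * eta))
}

#' Maximum, embolized and natural conductivity partition
#'
#' `Km` is the Poiseuille conductivity over all vessels (the fully dried
#' stem), `Ks` over the embolized subset (the natural-state scan), and the
#' natural conductivity `Kn = Km - Ks`, identically the conductivity of the
#' water-filled subset. `Ks` and `Kn` are computed as subset sums and `Km` as
#' their total, so the partition identity is exact in floating point too.
#'
#' @param pop a `vessel_population` data frame (columns `diameter_um`,
#'   `status`) from [vessel_table_from_mask()] or built directly.
#' @param eta water viscosity, MPa s.
#' @return List with `Km`, `Ks`, `Kn`.
#' @export
conductivity_partition <- function(pop, eta = eta_water_20C) {
  if (!all(pop$status %in% c("water-filled", "embolized")))
    stop("every vessel needs status 'water-filled' or 'embolized'")
  Ks <- poiseuille_conductivity(pop$diameter_um[pop$status == "embolized"],
                                eta)
  Kn <- poiseuille_conductivity(pop$diameter_um[pop$status == "water-filled"],
                                eta)
  list(Km = Ks + Kn, Ks = Ks, Kn = Kn)
}

#' Per-vessel table from lumen and embolized masks
#'
#' Labels the lumen mask (26-connectivity), takes each vessel's cross-section
#' area on the mid-slice (falling back to its mean per-slice area when it
#' misses the mid-slice), derives the area-equivalent diameter
#' `D = sqrt(4 A / pi)`, and sets the status by majority voxel overlap with
#' the embolized mask. Components spanning fewer than 3 slices, or smaller
#' than `min_voxels` (default 10, about the 1-voxel-radius lumen disc over
#' the 3-slice minimum — anything smaller is segmentation speckle, not a
#' resolvable vessel), are dropped with a message.
#'
#' @param lumen [phase_mask()] of all vessel lumina.
#' @param embolized optional [phase_mask()] of embolized lumina (same shape);
#'   `NULL` marks every vessel water-filled.
#' @param stem_area_um2 stem cross-section area in square micrometers.
#' @param min_voxels minimum component size in voxels for a resolvable vessel.
#' @return A `vessel_population` data frame: `id`, `area_um2`, `diameter_um`,
#'   `status`, `n_slices`, with attributes `stem_area_um2`, `voxel_size`.
#' @export
vessel_table_from_mask <- function(lumen, embolized = NULL,
                                   stem_area_um2 = NA, min_voxels = 10) {
  d <- dim(lumen$data)
  vs <- lumen$voxel_size
  lab <- cpp_label26(as.logical(lumen$data), as.integer(d))
  nlab <- attr(lab, "nlab")
  lab <- array(lab, d)
  if (nlab == 0)
    return(structure(data.frame(id = integer(0), area_um2 = numeric(0),
                                diameter_um = numeric(0),
                                status = character(0), n_slices = integer(0)),
                     stem_area_um2 = stem_area_um2, voxel_size = vs,
                     class = c("vessel_population", "data.frame")))
  if (!is.null(embolized) && !identical(dim(embolized$data), d))
    stop("embolized mask shape mismatch")
  mid <- ceiling(d[1] / 2)
  occ <- which(lab > 0L)
  labs_occ <- lab[occ]
  slice_of <- ((occ - 1L) %% d[1]) + 1L
  n_slices <- vapply(split(slice_of, labs_occ), function(s)
    length(unique(s)), integer(1))
  n_slices <- n_slices[as.character(seq_len(nlab))]
  mid_area <- tabulate(lab[mid, , ], nbins = nlab) * vs^2
  mean_area <- vapply(split(slice_of, labs_occ), function(s)
    length(s) / length(unique(s)), numeric(1))[as.character(seq_len(nlab))] * vs^2
  A <- ifelse(mid_area > 0, mid_area, mean_area)
  status <- rep("water-filled", nlab)
  if (!is.null(embolized)) {
    ov <- lab[which(embolized$data)]
    ov <- ov[ov > 0]
    if (length(ov)) {
      tab <- table(ov)
      total <- tabulate(labs_occ, nbins = nlab)
      emb_frac <- rep(0, nlab)
      emb_frac[as.integer(names(tab))] <- as.integer(tab)
      emb_frac <- emb_frac / total
      status[emb_frac > 0.5] <- "embolized"
    }
  }
  total_vox <- tabulate(labs_occ, nbins = nlab)
  keep <- n_slices >= 3L & total_vox >= min_voxels
  if (any(!keep))
    message(sum(!keep),
            " component(s) dropped (< 3 slices or below the size floor)")
  out <- data.frame(id = seq_len(nlab), area_um2 = A,
                    diameter_um = sqrt(4 * A / pi), status = status,
                    n_slices = as.integer(n_slices),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  structure(out, stem_area_um2 = stem_area_um2, voxel_size = vs,
            class = c("vessel_population", "data.frame"))
}

#' Hydraulic summary of a vessel population
#'
#' Binned counts plus the stem-level statistics: hydraulic diameter, D95,
#' mean vessel area, vessel count, vessel density per square millimeter of
#' stem cross-section, vessel lumen fraction, the Km/Ks/Kn conductivity
#' partition and the number-based embolism rate (percent of vessels that are
#' gas-filled).
#'
#' @param pop a `vessel_population` data frame.
#' @param bins ascending diameter breakpoints in micrometers; defaults to
#'   `c(10, 20, 30, 50)` giving classes <10, 10-20, 20-30, 30-50, >50.
#' @param stem_area_um2 stem cross-section area; defaults to the table's
#'   attribute.
#' @param eta water viscosity, MPa s.
#' @return A `hydraulic_summary` list, including a `per_bin` data frame with
#'   total and water-filled counts per diameter class.
#' @export
vessel_summary <- function(pop, bins = c(10, 20, 30, 50),
                           stem_area_um2 = attr(pop, "stem_area_um2"),
                           eta = eta_water_20C) {
  if (is.unsorted(bins, strictly = TRUE)) stop("'bins' must be ascending")
  n <- nrow(pop)
  if (n == 0)
    return(structure(list(n = 0L, Dh_um = NA_real_, D95_um = NA_real_,
                          mean_area_um2 = NA_real_,
                          vessel_density_per_mm2 = NA_real_,
                          lumen_fraction = NA_real_, Km = NA_real_,
                          Ks = NA_real_, Kn = NA_real_,
                          embolism_rate_percent = NA_real_,
                          per_bin = NULL), class = "hydraulic_summary"))
  brks <- c(0, bins, Inf)
  labs <- c(paste0("<", bins[1]),
            paste0(bins[-length(bins)], "-", bins[-1]),
            paste0(">", bins[length(bins)]))
  bin <- cut(pop$diameter_um, brks, labels = labs, right = TRUE)
  per_bin <- data.frame(
    bin = labs,
    n = as.integer(table(bin)),
    n_water_filled = as.integer(table(bin[pop$status == "water-filled"])))
  ks <- conductivity_partition(pop, eta)
  stem_mm2 <- stem_area_um2 * 1e-6
  structure(list(
    n = n,
    Dh_um = hydraulic_diameter(pop$diameter_um),
    D95_um = d95(pop$diameter_um),
    mean_area_um2 = mean(pop$area_um2),
    vessel_density_per_mm2 = if (is.finite(stem_mm2)) n / stem_mm2 else NA_real_,
    lumen_fraction = if (is.finite(stem_area_um2))
      sum(pop$area_um2) / stem_area_um2 else NA_real_,
    Km = ks$Km, Ks = ks$Ks, Kn = ks$Kn,
    embolism_rate_percent = 100 * sum(pop$status == "embolized") / n,
    per_bin = per_bin), class = "hydraulic_summary")
}

#' @export
print.hydraulic_summary <- function(x, ...) {
  cat(sprintf(paste0("hydraulic_summary: n = %d vessels, Dh = %.4g um, ",
                     "D95 = %.4g um,\n  Km = %.4g, Ks = %.4g, Kn = %.4g ",
                     "kg s-1 m-1 MPa-1, embolism rate = %.4g%%\n"),
              x$n, x$Dh_um, x$D95_um, x$Km, x$Ks, x$Kn,
              x$embolism_rate_percent))
  invisible(x)
}
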