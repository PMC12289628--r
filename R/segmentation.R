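#' Cylindrical region of interest
#'
#' Returns the mask of the largest in-plane-centered cylinder (axes 2 and 3;
#' axis 1 is vertical) shrunk by `margin` micrometers, the standard crop that
#' excludes voids near the column wall and sampling disturbances.
#'
#' @param volume a [voxel_grid()] or [phase_mask()].
#' @param margin shrink margin in micrometers; must be smaller than half the
#'   smaller in-plane extent.
#' @return A [phase_mask()] (phase `"roi"`), true inside the cylinder.
#' @examples
#' v <- voxel_grid(array(0, c(10, 20, 20)), voxel_size = 10)
#' roi <- cylindrical_roi(v, margin = 0)
#' sum(roi$data) / 10  # disc voxel count per slice
#' @export
cylindrical_roi <- function(volume, margin = 0) {
  d <- dim(volume$data)
  vs <- volume$voxel_size
  half_um <- (min(d[2], d[3]) / 2) * vs
  if (margin >= half_um)
    stop(sprintf("margin (%.3g um) must be below the in-plane half-width (%.3g um)",
                 margin, half_um))
  r_vox <- min(d[2], d[3]) / 2 - margin / vs
  cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  disc <- outer((seq_len(d[2]) - cy)^2, (seq_len(d[3]) - cz)^2, "+") <= r_vox^2
  mask <- array(rep(as.vector(disc), each = d[1]), d)
  phase_mask(mask, phase = "roi", voxel_size = vs)
}

## Local maxima of a lightly smoothed histogram. The prominence floor is
## relative to the dominant peak and deliberately small: in a soil volume the
## solid phase dwarfs the pore modes (a 2% porosity leaves the air/water peaks
## two orders of magnitude below the solid peak).
find_modes <- function(mids, counts, smooth = 5L, min_frac = 0.001) {
  k <- rep(1 / smooth, smooth)
  sm <- stats::filter(counts, k, sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  if (n < 3 || max(sm) == min(sm)) return(integer(0))
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    sm[i] == max(sm[lo:hi]) && any(sm[lo:hi] < sm[i])
  }, logical(1))
  idx <- which(is_max & sm >= min_frac * max(sm))
  # collapse plateaus
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 2)]
  idx
}

#' Histogram-parabola global threshold
#'
#' Fits a least-squares quadratic to the histogram counts inside the
#' inter-mode valley and returns the parabola's vertex abscissa as the global
#' threshold, clipped to the search window. Voxels strictly below the
#' threshold belong to the darker phase; voxels equal to it go to the
#' brighter phase.
#'
#' When `search_window` is missing it is auto-detected as the interval between
#' the two dominant histogram modes. If the fitted parabola is concave (no
#' valley curvature) the minimum-count bin of the window is returned with a
#' warning.
#'
#' @param histogram an object from [graphics::hist()] (fields `mids`,
#'   `counts`) or a list with those fields.
#' @param search_window optional `c(lo, hi)` intensity range to fit within.
#' @return The threshold intensity (scalar).
#' @export
parabola_threshold <- function(histogram, search_window = NULL) {
  mids <- histogram$mids
  counts <- as.numeric(histogram$counts)
  if (length(mids) < 5) stop("histogram too coarse")
  if (max(counts) == min(counts))
    stop("degenerate flat histogram: no inter-mode valley")
  if (is.null(search_window)) {
    modes <- find_modes(mids, counts)
    if (length(modes) < 2)
      stop("unimodal histogram: no inter-mode valley")
    dom <- modes[order(counts[modes], decreasing = TRUE)][1:2]
    dom <- sort(dom)
    # fit strictly between the peaks, trimming the flanks of each mode
    span <- mids[dom[2]] - mids[dom[1]]
    search_window <- c(mids[dom[1]] + 0.15 * span, mids[dom[2]] - 0.15 * span)
  }
  inw <- which(mids >= search_window[1] & mids <= search_window[2])
  if (length(inw) < 3) stop("search window covers fewer than 3 bins")
  x <- mids[inw]; y <- counts[inw]
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  if (!is.finite(cf[3]) || cf[3] <= 0) {
    warning("parabola is not convex in the window; using minimum-count bin")
    thr <- x[which.min(y)]
  } else {
    thr <- -cf[2] / (2 * cf[3])
  }
  min(max(thr, search_window[1]), search_window[2])
}

#' Binarize a volume at a global threshold
#'
#' Voxels strictly below `threshold` form the darker phase. With
#' `darker = FALSE` the mask is the complementary brighter phase
#' (intensity >= threshold).
#'
#' @param volume a [voxel_grid()].
#' @param threshold intensity threshold.
#' @param phase label for the resulting mask.
#' @param darker keep the darker phase (default) or the brighter one.
#' @return A [phase_mask()].
#' @export
apply_threshold <- function(volume, threshold, phase = "pore", darker = TRUE) {
  m <- if (darker) volume$data < threshold else volume$data >= threshold
  phase_mask(m, phase = phase, voxel_size = volume$voxel_size)
}

#' Voxelwise a AND NOT b
#'
#' The "and not image" phase arithmetic: removes from `a` every voxel also in
#' `b`, e.g. to eliminate the pore/root intersection, or to subtract the
#' naturally embolized vessels from the fully dried vessel set.
#'
#' @param a,b [phase_mask()]s of identical shape.
#' @param phase label for the result (default: `a`'s label).
#' @return A [phase_mask()].
#' @export
and_not <- function(a, b, phase = a$phase) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("masks have different shapes")
  phase_mask(a$data & !b$data, phase = phase, voxel_size = a$voxel_size)
}

#' Seeded region growing
#'
#' Grows a region from seed voxels through 26-connected neighbours whose
#' intensity lies within `tolerance` of the running region mean, visiting
#' first-in-first-out; the result is deterministic. The growth method suits
#' structures that extend through the slices, such as roots and vessels.
#'
#' @param volume a [voxel_grid()].
#' @param seeds integer matrix or data frame of 1-based voxel coordinates,
#'   one row per seed (columns: axis 1, 2, 3).
#' @param tolerance nonnegative intensity tolerance. Zero keeps only voxels
#'   exactly equal to the running mean (on noisy data this is just the seeds).
#' @param phase label for the resulting mask.
#' @return A [phase_mask()].
#' @export
region_grow <- function(volume, seeds, tolerance, phase = "root") {
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  seeds <- as.matrix(seeds)
  storage.mode(seeds) <- "integer"
  d <- dim(volume$data)
  if (ncol(seeds) != 3L) stop("'seeds' needs three coordinate columns")
  bad <- seeds[, 1] < 1 | seeds[, 1] > d[1] | seeds[, 2] < 1 |
    seeds[, 2] > d[2] | seeds[, 3] < 1 | seeds[, 3] > d[3]
  if (any(bad)) stop("seed outside the grid: row ", which(bad)[1])
  m <- cpp_region_grow(as.numeric(volume$data), as.integer(d), seeds,
                       as.numeric(tolerance))
  phase_mask(array(m, d), phase = phase, voxel_size = volume$voxel_size)
}

#' Binary closing (dilation then erosion, 3x3x3 neighbourhood)
#'
#' @param mask a [phase_mask()].
#' @return A [phase_mask()].
#' @export
binary_closing <- function(mask) {
  d <- dim(mask$data)
  m <- cpp_dilate26(as.logical(mask$data), as.integer(d))
  m <- cpp_erode26(m, as.integer(d))
  phase_mask(array(m, d), phase = mask$phase, voxel_size = mask$voxel_size)
}

#' Segment roots (or vessels) by growth plus one closing
#'
#' Operationalizes the interactive magic-wand/expansion workflow as seeded
#' region growing followed by a single binary closing that restores valid
#' interior voxels.
#'
#' @inheritParams region_grow
#' @return A [phase_mask()].
#' @export
segment_by_growth <- function(volume, seeds, tolerance, phase = "root") {
  binary_closing(region_grow(volume, seeds, tolerance, phase = phase))
}

#' Water-filled vessels from the natural / fully-dried scan pair
#'
#' The fully dried stem exposes every vessel lumen; the natural scan exposes
#' only the embolized ones. Their and-not difference is the water-filled
#' lumen set. The natural set must be contained in the dried set up to a
#' tolerated mis-registration fraction.
#'
#' @param natural_embolized [phase_mask()] of embolized lumina in the natural
#'   state.
#' @param fully_dried [phase_mask()] of all lumina after full drying.
#' @param tol_frac maximum fraction of natural voxels allowed outside the
#'   dried set (default 2%) before an error is raised.
#' @return A [phase_mask()] (phase `"water-filled-vessel"`).
#' @export
extract_water_filled_vessels <- function(natural_embolized, fully_dried,
                                         tol_frac = 0.02) {
  if (!identical(dim(natural_embolized$data), dim(fully_dried$data)))
    stop("masks have different shapes")
  n_nat <- sum(natural_embolized$data)
  if (n_nat > 0) {
    outside <- sum(natural_embolized$data & !fully_dried$data) / n_nat
    if (outside > tol_frac)
      stop(sprintf(paste0("%.1f%% of the natural embolized mask lies outside ",
                          "the dried mask: probable mis-registration"),
                   100 * outside))
    if (outside > 0)
      message(sprintf("%.2f%% of natural voxels outside the dried set (tolerated)",
                      100 * outside))
  }
  and_not(fully_dried, natural_embolized, phase = "water-filled-vessel")
}

#' Automatic soil phase segmentation
#'
#' Convenience wrapper for the full soil chain: histogram the volume, detect
#' the intensity modes, place the parabola threshold between the solid mode
#' (brightest) and the nearest darker mode to extract the pore space
#' (air + water), and, when a water mode exists, a second threshold between
#' the air and water modes to isolate the water phase.
#'
#' @param volume a [voxel_grid()].
#' @param nbins number of histogram bins.
#' @return List with `pore` and `water` [phase_mask()]s (the latter `NULL`
#'   when no water mode is found), plus the thresholds used.
#' @export
segment_soil <- function(volume, nbins = 256) {
  h <- graphics::hist(volume$data, breaks = nbins, plot = FALSE)
  modes <- find_modes(h$mids, h$counts)
  if (length(modes) < 2) stop("unimodal histogram: no inter-mode valley")
  mm <- h$mids[modes]
  solid_mode <- max(mm)
  below <- sort(mm[mm < solid_mode])
  dark_mode <- below[length(below)]     # nearest mode darker than solid
  span <- solid_mode - dark_mode
  thr_pore <- parabola_threshold(h, c(dark_mode + 0.15 * span,
                                      solid_mode - 0.15 * span))
  pore <- apply_threshold(volume, thr_pore, phase = "pore")
  water <- NULL; thr_water <- NA_real_
  if (length(below) >= 2) {
    air_mode <- below[1]
    wspan <- dark_mode - air_mode
    thr_water <- parabola_threshold(h, c(air_mode + 0.15 * wspan,
                                         dark_mode - 0.15 * wspan))
    wm <- volume$data >= thr_water & volume$data < thr_pore
    water <- phase_mask(wm, phase = "water", voxel_size = volume$voxel_size)
  }
  list(pore = pore, water = water,
       thresholds = c(pore = thr_pore, water = thr_water))
}
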