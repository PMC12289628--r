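#' 3D grayscale volume with voxel size
#'
#' A `voxel_grid` wraps a 3D numeric array of X-ray attenuation intensities
#' together with its isotropic voxel edge length in micrometers. The first
#' array dimension is the vertical (gravity) axis, matching the slice order of
#' a CT stack scanned along the column axis.
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_size voxel edge length in micrometers (> 0).
#' @return An object of class `voxel_grid`.
#' @examples
#' v <- voxel_grid(array(0, c(4, 4, 4)), voxel_size = 6)
#' dim(v$data)
#' @export
voxel_grid <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 2L))
    stop("all three dimensions must be >= 2")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("'voxel_size' must be a single positive number (micrometers)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid")
}

#' Binary phase mask
#'
#' Marks the voxels belonging to one material phase (pore space, water, root
#' tissue, vessel lumen, ...) of a parent [voxel_grid()]. Stored as a logical
#' array of the same shape.
#'
#' @param data 3D logical array.
#' @param phase phase label, one of `"pore"`, `"water"`, `"root"`,
#'   `"vessel-lumen"`, `"embolized-vessel"` or any user label.
#' @param voxel_size voxel edge length in micrometers.
#' @return An object of class `phase_mask`.
#' @export
phase_mask <- function(data, phase = "pore", voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) stop("mask must be strictly binary")
    data <- array(as.logical(data), dim(data))
  }
  if (voxel_size <= 0) stop("'voxel_size' must be positive")
  structure(list(data = data, phase = as.character(phase),
                 voxel_size = as.numeric(voxel_size)),
            class = "phase_mask")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g um/voxel, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.phase_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("phase_mask '%s': %d x %d x %d voxels, %.3g um/voxel, %d set (%.2f%%)\n",
              x$phase, d[1], d[2], d[3], x$voxel_size,
              sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

voxel_volume_um3 <- function(x) x$voxel_size^3

as_mask_array <- function(x) {
  if (inherits(x, "phase_mask")) x$data else x
}
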