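test_that("cylindrical ROI matches the analytic disc", {
  v <- voxel_grid(array(0, c(50, 100, 100)), voxel_size = 1)
  roi <- cylindrical_roi(v, margin = 0)
  per_slice <- sum(roi$data) / 50
  expect_equal(per_slice, pi * 50^2, tolerance = 0.01)
  # shrunk cylinder: r = 40 voxels
  roi40 <- cylindrical_roi(v, margin = 10)
  expect_equal(sum(roi40$data), pi * 40^2 * 50, tolerance = 0.01)
  expect_error(cylindrical_roi(v, margin = 50), "half-width")
})

test_that("parabola threshold finds the inter-mode valley of a mixture", {
  h <- mixture_hist(c(60, 160), c(12, 12))
  thr <- parabola_threshold(h)
  # oracle: numeric minimization of the mixture density between the modes
  valley <- optimize(function(v) dnorm(v, 60, 12) + dnorm(v, 160, 12),
                     c(60, 160))$minimum
  expect_lt(abs(thr - valley), 5)
  # perfectly symmetric mixture: midpoint
  expect_lt(abs(thr - 110), 2)
})

test_that("parabola threshold refuses degenerate histograms", {
  flat <- list(mids = 0:255, counts = rep(7L, 256))
  expect_error(parabola_threshold(flat), "flat histogram")
  uni <- mixture_hist(130, 15)
  expect_error(parabola_threshold(uni), "unimodal")
  # a window centered on a peak has concave curvature: fallback + warning
  h <- mixture_hist(c(60, 160), c(12, 12))
  expect_warning(thr <- parabola_threshold(h, c(140, 180)), "not convex")
  expect_true(thr >= 140 && thr <= 180)
})

test_that("threshold rises monotonically with the darker phase's mean", {
  thrs <- vapply(c(40, 50, 60, 70), function(m)
    parabola_threshold(mixture_hist(c(m, 160), c(12, 12))), numeric(1))
  expect_true(all(diff(thrs) >= 0))
})

test_that("and_not implements the voxelwise truth table", {
  a <- phase_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(4, 2, 2)), "pore", 1)
  b <- phase_mask(array(c(FALSE, TRUE, FALSE, TRUE), c(4, 2, 2)), "root", 1)
  r <- and_not(a, b)
  expect_identical(r$data[, 1, 1], c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(r$data), sum(a$data) - sum(a$data & b$data))
  expect_false(any(and_not(a, a)$data))
  empty <- phase_mask(array(FALSE, c(4, 2, 2)), "root", 1)
  expect_identical(and_not(a, empty)$data, a$data)
  bad <- phase_mask(array(FALSE, c(2, 2, 2)), "root", 1)
  expect_error(and_not(a, bad), "shape")
})

test_that("region growing floods exactly a noiseless constant region", {
  cyl <- cylinder_mask(4, 30)
  vol <- voxel_grid(array(100, dim(cyl$data)) - 60 * cyl$data, 1)
  seed <- which(cyl$data, arr.ind = TRUE)[200, , drop = FALSE]
  grown <- region_grow(vol, seed, tolerance = 5)
  expect_identical(grown$data, cyl$data)
  # a background seed stays in the background component
  bg <- which(!cyl$data, arr.ind = TRUE)[1, , drop = FALSE]
  grown_bg <- region_grow(vol, bg, tolerance = 5)
  expect_false(any(grown_bg$data & cyl$data))
  expect_error(region_grow(vol, matrix(c(0, 1, 1), 1), 5), "outside")
})

test_that("root network recovery by growth stays under 5% voxel error", {
  spec <- soil_phantom_spec(grid_shape = c(96, 96, 96), n_tubes = 6,
                            n_spheres = 12, n_blobs = 15, n_roots = 2,
                            saturation = 0.3, seed = 5)
  ph <- make_soil_phantom(spec)
  gt <- ph$truth$primitives
  root_ids <- gt$id[gt$material == "root"]
  seeds <- do.call(rbind, lapply(root_ids, function(id)
    which(ph$labels == id, arr.ind = TRUE)[50, , drop = FALSE]))
  grown <- segment_by_growth(ph$volume, seeds, tolerance = 25)
  gtmask <- ph$labels %in% root_ids
  mis <- sum(xor(grown$data, gtmask)) / sum(gtmask)
  expect_lt(mis, 0.05)
})

test_that("pore/solid segmentation misclassifies < 2% of the ROI", {
  spec <- soil_phantom_spec(grid_shape = c(96, 96, 96), n_tubes = 8,
                            n_spheres = 16, n_blobs = 20, saturation = 0.4,
                            seed = 13)
  ph <- make_soil_phantom(spec)
  seg <- segment_soil(ph$volume)
  gt_pore <- ph$labels > 0L
  mis <- sum(xor(seg$pore$data, gt_pore)) / length(gt_pore)
  expect_lt(mis, 0.02)
})

test_that("pore mask after root subtraction is disjoint from the root mask", {
  spec <- soil_phantom_spec(grid_shape = c(80, 80, 80), n_tubes = 5,
                            n_spheres = 10, n_blobs = 10, n_roots = 1,
                            saturation = 0.3, seed = 17)
  ph <- make_soil_phantom(spec)
  seg <- segment_soil(ph$volume)
  root_ids <- ph$truth$primitives$id[ph$truth$primitives$material == "root"]
  seeds <- which(ph$labels == root_ids[1], arr.ind = TRUE)[10, , drop = FALSE]
  root <- segment_by_growth(ph$volume, seeds, tolerance = 25)
  pore_clean <- and_not(seg$pore, root)
  expect_identical(sum(pore_clean$data & root$data), 0L)
})

test_that("water-filled vessel extraction follows the and-not drying logic", {
  d <- c(12, 20, 20)
  dried <- phase_mask(array(runif(prod(d)) < 0.3, d), "vessel-lumen", 3)
  none <- phase_mask(array(FALSE, d), "embolized-vessel", 3)
  expect_identical(extract_water_filled_vessels(none, dried)$data,
                   dried$data)
  expect_false(any(extract_water_filled_vessels(dried, dried)$data))
  # containment violation beyond tolerance errors with a registration hint
  shifted <- phase_mask(array(c(dried$data[-1], FALSE), d),
                        "embolized-vessel", 3)
  expect_error(suppressMessages(
    extract_water_filled_vessels(shifted, dried, tol_frac = 0.001)),
    "mis-registration")
})
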