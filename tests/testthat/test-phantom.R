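test_that("a noiseless sphere primitive voxelizes to its analytic volume", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size = 1,
                       primitives = list(list(type = "sphere",
                                              center = c(16.5, 16.5, 16.5),
                                              radius_um = 10)),
                       phase_levels = default_phase_levels(noise_sd = 1e-9),
                       rng_seed = 1)
  ph <- make_soil_phantom(spec)
  expect_equal(ph$truth$primitives$volume_um3,
               4 / 3 * pi * 1000, tolerance = 0.02)
  expect_equal(ph$truth$primitives$true_volume_um3, 4 / 3 * pi * 1000)
})

test_that("identical spec and seed give bit-identical volumes and truth", {
  spec <- soil_phantom_spec(grid_shape = c(48, 48, 48), n_tubes = 4,
                            n_spheres = 8, n_blobs = 10, saturation = 0.4,
                            seed = 23)
  a <- make_soil_phantom(spec)
  b <- make_soil_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$primitives, b$truth$primitives)
  expect_identical(a$labels, b$labels)
})

test_that("voxelization of spheres and tubes with radius >= 5 voxels is within 2%", {
  for (r in c(5, 8, 12)) {
    m <- sphere_mask(r)
    expect_equal(sum(m$data), 4 / 3 * pi * r^3, tolerance = 0.02,
                 label = sprintf("sphere r=%g voxel count", r))
  }
  spec <- phantom_spec(grid_shape = c(80, 24, 24), voxel_size = 1,
                       primitives = list(list(type = "tube",
                                              p0 = c(10, 12.5, 12.5),
                                              p1 = c(70, 12.5, 12.5),
                                              radius_um = 6)),
                       phase_levels = default_phase_levels(0.1))
  ph <- make_soil_phantom(spec)
  expect_equal(ph$truth$primitives$volume_um3, pi * 36 * 60,
               tolerance = 0.02)
})

test_that("greedy smallest-first water fill stops before overshooting", {
  truth <- list(primitives = data.frame(
    id = 1:3, family = "near-spherical", material = "pore",
    true_volume_um3 = c(1, 2, 7), voxel_count = c(1, 2, 7),
    volume_um3 = c(1, 2, 7), overlap_voxels = 0L,
    true_diameter_um = equivalent_diameter_3d(c(1, 2, 7)),
    water = FALSE, embolized = FALSE))
  # independent enumeration of every greedy stopping point: cumulative
  # volumes 1, 3, 10 against a target of 0.3 * 10 = 3 -> stop after {1, 2}
  filled <- assign_water(truth, 0.3, "smallest-first")$primitives$water
  expect_identical(filled, c(TRUE, TRUE, FALSE))
  expect_false(any(assign_water(truth, 0, "smallest-first")$primitives$water))
  expect_true(all(assign_water(truth, 1, "smallest-first")$primitives$water))
})

test_that("water assignment conserves volume and respects saturation bounds", {
  spec <- soil_phantom_spec(grid_shape = c(64, 64, 64), n_tubes = 6,
                            n_spheres = 12, n_blobs = 15, saturation = 0.5,
                            seed = 9)
  ph <- make_soil_phantom(spec)
  g <- ph$truth$global
  expect_lte(g$water_volume_um3, g$pore_volume_um3)
  expect_lte(g$saturation_achieved, 0.5)
  pr <- ph$truth$primitives
  pore <- pr$material == "pore"
  by_class <- tapply(pr$volume_um3[pore], pr$family[pore], sum)
  expect_equal(sum(by_class), g$pore_volume_um3, tolerance = 1e-9)
})

test_that("sampled tube radii follow the stated clipped lognormal", {
  spec <- soil_phantom_spec(grid_shape = c(160, 300, 300), n_tubes = 200,
                            n_spheres = 0, n_blobs = 0, seed = 31)
  radii <- vapply(Filter(function(p) p$type == "tube", spec$primitives),
                  `[[`, numeric(1), "radius_um")
  expect_length(radii, 200)
  # Monte-Carlo oracle for the mean of the clipped lognormal
  set.seed(1)
  oracle <- mean(pmin(pmax(rlnorm(2e5, log(12), 0.35), 5), 40))
  expect_equal(mean(radii), oracle, tolerance = 0.05)
})

test_that("stem phantom embolizes exactly round(rate * n) tubes", {
  spec <- stem_phantom_spec(grid_shape = c(32, 140, 140), n_vessels = 20,
                            embolism_rate = 0.25, seed = 4)
  ph <- make_stem_phantom(spec)
  expect_identical(sum(ph$truth$primitives$embolized), 5L)
  expect_identical(ph$truth$global$embolism_rate, 25)
  spec0 <- stem_phantom_spec(grid_shape = c(32, 140, 140), n_vessels = 20,
                             embolism_rate = 0, seed = 4)
  ph0 <- make_stem_phantom(spec0)
  expect_true(all(ph0$truth$primitives$water))
})

test_that("sub-voxel vessel radii are rejected with the resolution floor named", {
  spec <- phantom_spec(grid_shape = c(32, 64, 64), voxel_size = 3,
                       primitives = list(list(type = "tube",
                                              p0 = c(1, 32, 32),
                                              p1 = c(32, 32, 32),
                                              radius_um = 2)))
  expect_error(make_stem_phantom(spec), "resolution floor")
})

test_that("degenerate phantom specs are refused", {
  expect_error(phantom_spec(c(32, 32, 32), 6, list(), saturation = 2),
               "saturation")
  spec <- phantom_spec(c(32, 32, 32), 6, list())
  expect_error(make_soil_phantom(spec), "empty")
  expect_error(phantom_spec(c(32, 32, 32), 6, list(list(type = "sphere")),
                            phase_levels = list(air = c(30, 5),
                                                water = c(30, 5),
                                                root = c(120, 5),
                                                solid = c(180, 5))),
               "distinct")
})

test_that("excessive primitive overlap triggers the bookkeeping warning", {
  prims <- list(
    list(type = "sphere", center = c(16, 16, 16), radius_um = 8),
    list(type = "sphere", center = c(18, 16, 16), radius_um = 8))
  spec <- phantom_spec(c(32, 32, 32), 1, prims,
                       phase_levels = default_phase_levels(0.1),
                       max_overlap_frac = 0.01)
  expect_warning(make_soil_phantom(spec), "overlap fraction")
})
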