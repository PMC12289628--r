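test_that("hydraulic diameter is the fourth-power mean", {
  expect_equal(hydraulic_diameter(c(10, 10)), 10)
  expect_equal(hydraulic_diameter(c(10, 20)), (mean(c(10, 20)^4))^(1 / 4))
  expect_error(hydraulic_diameter(numeric(0)), "empty")
  set.seed(4)
  for (i in 1:20) {
    D <- runif(sample(2:50, 1), 5, 60)
    expect_gte(hydraulic_diameter(D), mean(D))   # power-mean inequality
  }
})

test_that("D95 matches the exhaustive prefix-search oracle", {
  expect_equal(d95(c(30, 20, 10)), 25)
  expect_equal(d95(rep(15, 7)), 15)
  expect_error(d95(numeric(0)), "empty")
  set.seed(11)
  for (i in 1:200) {
    D <- runif(sample(1:12, 1), 5, 80)
    expect_identical(d95(D), d95_oracle(D))
  }
})

test_that("D95 orderings: mean <= D95 <= max and monotone under largest removal", {
  # note: Dh <= D95 does NOT hold in general (e.g. D = {20, 10} gives
  # Dh = 17.07 but D95 = 15, since both vessels are needed for 95% of the
  # conductance); the provable bounds are mean(D) <= D95 <= max(D)
  set.seed(12)
  for (i in 1:50) {
    D <- rlnorm(sample(3:200, 1), log(22), 0.4)
    expect_gte(d95(D), mean(D))
    expect_lte(d95(D), max(D))
    Dm <- sort(D, decreasing = TRUE)[-1]
    if (length(Dm) >= 1) expect_lte(d95(Dm), d95(D) + 1e-12)
  }
  expect_equal(d95(c(20, 10)), 15)
  expect_gt(hydraulic_diameter(c(20, 10)), 15)  # the counterexample, frozen
})

test_that("Poiseuille conductivity follows the printed closed form", {
  # single 10 um vessel at the default 20 C viscosity
  expect_equal(poiseuille_conductivity(10),
               pi * (10e-6)^4 / (128 * 1.002e-9), tolerance = 1e-12)
  expect_equal(poiseuille_conductivity(10), 2.449e-13, tolerance = 1e-3)
  expect_identical(poiseuille_conductivity(numeric(0)), 0)
  # additivity to 1e-12 relative; fourth-power law
  set.seed(5)
  a <- runif(40, 5, 60); b <- runif(25, 5, 60)
  expect_equal(poiseuille_conductivity(c(a, b)),
               poiseuille_conductivity(a) + poiseuille_conductivity(b),
               tolerance = 1e-12)
  expect_equal(poiseuille_conductivity(20) / poiseuille_conductivity(10), 16)
})

test_that("Km = Ks + Kn for arbitrary status assignments", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(2:100, 1)
    pop <- data.frame(diameter_um = runif(n, 5, 60),
                      status = sample(c("water-filled", "embolized"), n,
                                      replace = TRUE))
    ks <- conductivity_partition(pop)
    expect_identical(ks$Km, ks$Ks + ks$Kn)
    expect_equal(ks$Km, poiseuille_conductivity(pop$diameter_um),
                 tolerance = 1e-12)
    expect_equal(ks$Kn,
                 poiseuille_conductivity(
                   pop$diameter_um[pop$status == "water-filled"]),
                 tolerance = 1e-12)
  }
  all_w <- data.frame(diameter_um = c(10, 20), status = "water-filled")
  expect_identical(conductivity_partition(all_w)$Ks, 0)
  all_e <- data.frame(diameter_um = c(10, 20), status = "embolized")
  expect_equal(conductivity_partition(all_e)$Kn, 0)
})

test_that("vessel tables derive diameters from mid-slice areas", {
  # vertical tube of radius 10 voxels at 1 um: lumen area ~ 100 pi um2
  cyl <- cylinder_mask(10, 30, voxel_size = 1)
  pop <- vessel_table_from_mask(cyl, stem_area_um2 = 1e4)
  expect_identical(nrow(pop), 1L)
  expect_equal(pop$diameter_um, 20, tolerance = 0.03)
  expect_identical(pop$status, "water-filled")   # no embolized mask given
  # vessels spanning < 3 slices are dropped
  thin <- array(FALSE, c(10, 12, 12)); thin[5, 3:5, 3:5] <- TRUE
  expect_message(p2 <- vessel_table_from_mask(phase_mask(thin, "vessel-lumen",
                                                         1)),
                 "dropped")
  expect_identical(nrow(p2), 0L)
})

test_that("vessel summary bins, rates and densities are consistent", {
  pop <- structure(data.frame(id = 1:20, area_um2 = pi * (15 / 2)^2,
                              diameter_um = 15,
                              status = rep(c("embolized", "water-filled"),
                                           c(5, 15)),
                              n_slices = 10L),
                   stem_area_um2 = 2e6,
                   class = c("vessel_population", "data.frame"))
  vs <- vessel_summary(pop)
  expect_equal(vs$embolism_rate_percent, 25)
  expect_equal(vs$vessel_density_per_mm2, 20 / 2)
  expect_equal(vs$lumen_fraction, 20 * pi * (7.5)^2 / 2e6)
  # one vessel per diameter class
  pop2 <- pop[1:5, ]
  pop2$diameter_um <- c(5, 15, 25, 40, 60)
  vs2 <- vessel_summary(pop2)
  expect_identical(vs2$per_bin$n, rep(1L, 5))
  empty <- pop[0, ]
  expect_true(is.na(vessel_summary(empty)$embolism_rate_percent))
})

test_that("stem phantom vessel statuses and bins match construction exactly", {
  spec <- stem_phantom_spec(grid_shape = c(48, 150, 150), n_vessels = 32,
                            embolism_rate = 0.25, seed = 19)
  ph <- make_stem_phantom(spec)
  roi <- cylindrical_roi(ph$volume,
                         margin = 0.12 * min(dim(ph$volume$data)[2:3]) / 2 *
                           ph$volume$voxel_size)
  lev <- spec$phase_levels
  dried <- phase_mask(ph$volume$data < (lev$water[1] + lev$solid[1]) / 2 &
                        roi$data, "vessel-lumen", spec$voxel_size)
  natural <- phase_mask(ph$volume$data < (lev$air[1] + lev$water[1]) / 2 &
                          roi$data, "embolized-vessel", spec$voxel_size)
  pop <- vessel_table_from_mask(dried, embolized = natural,
                                stem_area_um2 = ph$stem_area_um2)
  expect_identical(nrow(pop), 32L)
  expect_identical(sum(pop$status == "embolized"),
                   sum(ph$truth$primitives$embolized))
  vs <- vessel_summary(pop)
  expect_equal(vs$embolism_rate_percent, ph$truth$global$embolism_rate)
})

test_that("downstream diameter bins recover the constructed counts", {
  # edge-safe constructed diameters: 1, 2, 1, 1 vessels in the four upper bins
  dia <- c(15, 24, 26, 42, 55)
  xc <- c(40, 100, 40, 100, 70); yc <- c(40, 40, 100, 100, 70)
  prims <- lapply(seq_along(dia), function(i)
    list(type = "tube", p0 = c(1, xc[i], yc[i]), p1 = c(40, xc[i], yc[i]),
         radius_um = dia[i] / 2))
  spec <- phantom_spec(c(40, 140, 140), voxel_size = 3, primitives = prims,
                       embolism_rate = 0, rng_seed = 2)
  ph <- make_stem_phantom(spec)
  lev <- spec$phase_levels
  roi <- cylindrical_roi(ph$volume, margin = 0.12 * 69.5 * 3)
  dried <- phase_mask(ph$volume$data < (lev$water[1] + lev$solid[1]) / 2 &
                        roi$data, "vessel-lumen", 3)
  pop <- vessel_table_from_mask(dried, stem_area_um2 = ph$stem_area_um2)
  vs <- vessel_summary(pop)
  gt_bins <- as.integer(table(cut(dia, c(0, 10, 20, 30, 50, Inf))))
  expect_identical(vs$per_bin$n, gt_bins)
})
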