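test_that("a straight tube skeletonizes to one centered branch", {
  sk <- skeletonize(cylinder_mask(4, 40))
  expect_identical(sk$n_branches, 1L)
  expect_identical(sk$n_junctions, 0L)
  expect_identical(nrow(sk$nodes), 2L)
  expect_false(any(sk$nodes$junction))
  br <- sk$branches
  expect_lte(br$Lt_mm / br$Li_mm, 1.05)
  expect_gte(br$Lt_mm / br$Li_mm, 1.0)
})

test_that("branch angles follow the vertical-axis convention", {
  vert <- skeletonize(cylinder_mask(3, 30, axis = 1))
  expect_equal(vert$branches$theta_deg, 0)
  horiz <- skeletonize(cylinder_mask(3, 30, axis = 3))
  expect_equal(horiz$branches$theta_deg, 90)
})

test_that("a Y of three tubes gives three branches and one junction node", {
  sk <- skeletonize(y_mask(3, 60))
  expect_identical(sk$n_branches, 3L)
  expect_identical(sk$n_junctions, 1L)
})

test_that("hydraulic radius recovers constructed cylinder radii within 10%", {
  for (r in c(3, 5, 10, 20)) {
    cyl <- cylinder_mask(r, 20 * r)
    rt <- label_components(cyl)
    sk <- skeletonize(cyl)
    roi_m3 <- prod(dim(cyl$data)) * 1e-18
    ns <- network_summary(rt, sk, roi_m3)
    expect_equal(ns$HR_mm * 1000, r, tolerance = 0.10,
                 label = sprintf("HR for r=%d voxels", r))
    expect_gte(ns$tortuosity, 1.0)
    expect_lte(ns$tortuosity, 1.1)
  }
})

test_that("tortuosity of a half-circle arc approaches pi/2", {
  sk <- skeletonize(arc_mask(30, 3))
  br <- sk$branches[which.max(sk$branches$Lt_mm), ]
  expect_equal(br$Lt_mm / br$Li_mm, pi / 2, tolerance = 0.10)
})

test_that("network summary implements the density and angle formulas", {
  regions <- data.frame(volume_um3 = rep(1e6, 10), surface_um2 = rep(1e4, 10))
  skel <- structure(list(
    branches = data.frame(branch = 1:2, node_from = 1, node_to = 2,
                          Lt_mm = c(2, 2), Li_mm = c(2, 2),
                          theta_deg = c(0, 90), n_voxels = c(10, 10)),
    n_branches = 2L, n_junctions = 1L, total_Lt_mm = 4,
    voxel_size = 1), class = "skeleton_graph")
  ns <- network_summary(regions, skel, roi_volume_m3 = 2e-5)
  expect_equal(ns$ND_per_m3, 5e5)           # 10 components / 2e-5 m3
  expect_equal(ns$BD_per_m3, 1e5)
  expect_equal(ns$NoD_per_m3, 5e4)
  expect_equal(ns$MA_deg, 45)               # equal-length 0 and 90 degrees
  expect_equal(ns$CN, 2)
  expect_equal(ns$SD_m2_per_m3, 10 * 1e4 * 1e-12 / 2e-5)
  # HR recovers the radius of a single 0.5 mm x 10 mm cylinder
  cylreg <- data.frame(volume_um3 = pi * 0.25 * 10 * 1e9,
                       surface_um2 = 1)
  cylskel <- structure(list(
    branches = data.frame(branch = 1, node_from = 1, node_to = 2,
                          Lt_mm = 10, Li_mm = 10, theta_deg = 0,
                          n_voxels = 100),
    n_branches = 1L, n_junctions = 0L, total_Lt_mm = 10, voxel_size = 1),
    class = "skeleton_graph")
  ns2 <- network_summary(cylreg, cylskel, roi_volume_m3 = 1e-6)
  expect_equal(ns2$HR_mm, 0.5)
  expect_true(is.na(ns2$CN))                 # no junction nodes
})

test_that("Euler-based connectivity distinguishes a ball from a torus-like loop", {
  ball <- sphere_mask(6)
  ns_ball <- network_summary(label_components(ball), skeletonize(ball),
                             prod(dim(ball$data)) * 1e-18, mask = ball)
  expect_equal(ns_ball$connectivity_per_m3, 0)   # chi = 1 -> (1 - 1)/V
  # closed loop: bend a full circle tube
  n <- 48
  co <- as.matrix(expand.grid(1:10, 1:n, 1:n))
  cen <- c(5.5, n / 2, n / 2)
  ang <- seq(0, 2 * pi, length.out = 600)
  pts <- cbind(cen[1], cen[2] + 15 * cos(ang), cen[3] + 15 * sin(ang))
  d2 <- rep(Inf, nrow(co))
  for (i in seq_len(nrow(pts)))
    d2 <- pmin(d2, rowSums(sweep(co, 2, pts[i, ])^2))
  loop <- array(FALSE, c(10, n, n))
  loop[co[d2 <= 9, , drop = FALSE]] <- TRUE
  lp <- phase_mask(loop, "pore", 1)
  ns_loop <- network_summary(label_components(lp), skeletonize(lp),
                             prod(dim(loop)) * 1e-18, mask = lp)
  # chi of a solid torus = 0 -> connectivity density (1 - 0)/V > 0
  expect_gt(ns_loop$connectivity_per_m3, 0)
})

test_that("root metrics recover a constructed root cylinder", {
  # radius 0.26 mm at 20 um voxels = 13 voxels; length 6 mm (long enough
  # that end erosion by the thinning is negligible against Lt)
  cyl <- cylinder_mask(13, 300, voxel_size = 20)
  sk <- skeletonize(cyl)
  roi_m3 <- prod(dim(cyl$data)) * (20e-6)^3
  rm <- root_metrics(cyl, sk, roi_m3)
  expect_equal(rm$mean_radius_mm, 0.26, tolerance = 0.05)
  vol_frac <- sum(cyl$data) / prod(dim(cyl$data))
  expect_equal(rm$volume_density, vol_frac, tolerance = 1e-9)
  expect_equal(rm$BD_per_m3, 1 / roi_m3)
  expect_warning(zero <- root_metrics(phase_mask(array(FALSE, c(4, 4, 4)),
                                                 "root", 1),
                                      sk, roi_m3), "empty")
  expect_identical(zero$volume_density, 0)
})

test_that("an empty mask yields an empty graph with a warning", {
  expect_warning(sk <- skeletonize(phase_mask(array(FALSE, c(5, 5, 5)),
                                              "pore", 1)), "empty")
  expect_identical(sk$n_branches, 0L)
})
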