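test_that("heights follow their definitions and consistency rules", {
  cl <- make_cloud(c(0, 1, 2), c(1.2, 3.9, 2.0), c(0, 1, 2))
  expect_equal(plant_height(cl), 3.9)
  expect_equal(plant_height(make_cloud(0, 2, 0)), 2.0)
  canopy <- make_cloud(c(0, 0), c(0.7, 4.1), c(0, 0))
  expect_equal(canopy_height(canopy), 3.4)
  expect_equal(trunk_height(4.1, canopy_height(canopy)), 0.7)
  # canopy = whole plant cloud: HTL reduces to the cloud's minimum height
  cl2 <- make_cloud(runif(50), runif(50, 0.4, 3), runif(50))
  expect_equal(trunk_height(plant_height(cl2), canopy_height(cl2)),
               min(cl2$y))
  expect_error(trunk_height(2, 3), class = "olivescan_inconsistency_error")
  expect_error(plant_height(make_cloud(double(), double(), double())))
})

test_that("canopy diameter is the maximum horizontal caliper", {
  two <- make_cloud(c(0, 3), c(1, 9), c(0, 0))
  expect_equal(canopy_diameter(two), 3.0)
  withr::with_seed(4, {
    ang <- runif(4000, 0, 2 * pi)
    rad <- sqrt(runif(4000))
    disk <- make_cloud(rad * cos(ang), runif(4000, 1, 2), rad * sin(ang))
  })
  expect_equal(canopy_diameter(disk), 2.0, tolerance = 0.02)
  expect_error(canopy_diameter(make_cloud(0, 1, 0)))
})

test_that("cylinder and sphere simplifications evaluate their formulas", {
  expect_equal(cylinder_volume(2, 1), pi)
  expect_equal(cylinder_volume(0, 5), 0)
  expect_equal(cylinder_volume(3.47, 3.41), 32.248, tolerance = 1e-3)
  expect_equal(sphere_volume(2, 2), 4 / 3 * pi)
  expect_equal(sphere_volume(3.47, 3.41), 4 / 3 * pi * 1.72^3,
               tolerance = 1e-9)
  expect_equal(sphere_volume(3.47, 3.41), 21.31, tolerance = 0.01)
  expect_equal(sphere_volume(0, 0), 0)
})

test_that("slice-hull volume handles degenerate and planar inputs", {
  # two occupied slices far apart: the empty slices between contribute 0
  cl <- dplyr::bind_rows(
    make_cloud(rep(0.05, 4), c(0, 0, 1, 1), c(0, 1, 0, 1)),
    make_cloud(rep(0.95, 4), c(0, 0, 2, 2), c(0, 2, 0, 2)))
  est <- convex_hull_volume(cl, slice_width = 0.1)
  # slices anchor at the minimum x (0.05), spanning an extent of 0.9
  expect_equal(nrow(est$slices), 9L)
  expect_equal(sum(est$slices$area > 0), 2L)
  expect_equal(est$volume, 0.1 * 1 + 0.1 * 4)
  # all points in one x plane: a single slice worth slice_width * hull area
  plane <- make_cloud(rep(0.3, 4), c(0, 0, 1, 1), c(0, 1, 0, 1))
  est2 <- convex_hull_volume(plane, slice_width = 0.1)
  expect_equal(est2$volume, 0.1 * 1)
  # fewer than 3 affinely independent projected points: zero area
  line <- make_cloud(c(0, 0, 0), c(0, 1, 2), c(0, 1, 2))
  expect_equal(convex_hull_volume(line)$volume, 0)
})

test_that("slice-hull volume converges to the solid volume on a sampled sphere", {
  sph <- solid_sphere_cloud(2e5, r = 1, seed = 10)
  vch <- convex_hull_volume(sph, slice_width = 0.1)$volume
  expect_lt(abs(vch - 4 / 3 * pi) / (4 / 3 * pi), 0.05)
})

test_that("voxel volume counts occupied voxels exactly", {
  # 1000 points in 1000 distinct voxels
  g <- seq(0, 0.9, by = 0.1)
  grid <- expand.grid(x = g, y = g, z = g)
  vv <- voxel_volume(make_cloud(grid$x, grid$y, grid$z), v = 1e-5)
  expect_equal(vv$n_voxels, 1000L)
  expect_equal(vv$volume, 0.01)
  # corner-aligned cube: 20^3 voxels, VV = 0.08 exactly
  cube <- cube_corner_cloud(0.43, 1e-5)
  vvc <- voxel_volume(cube, v = 1e-5)
  expect_identical(vvc$n_voxels, 8000L)
  expect_identical(vvc$volume, 0.08)
  empty <- voxel_volume(make_cloud(double(), double(), double()))
  expect_equal(empty$n_voxels, 0L)
  expect_equal(empty$volume, 0)
})

test_that("estimators are invariant to point order and duplicates", {
  cl <- solid_sphere_cloud(2000, seed = 3)
  perm <- cl[sample(nrow(cl)), ]
  expect_equal(convex_hull_volume(perm)$volume, convex_hull_volume(cl)$volume)
  dup <- dplyr::bind_rows(cl, cl[1:500, ])
  expect_equal(voxel_volume(dup)$n_voxels, voxel_volume(cl)$n_voxels)
  expect_equal(voxel_volume(perm)$volume, voxel_volume(cl)$volume)
})

test_that("per-plant tables agree with the single-cloud operations", {
  scene <- small_scene(n_plants = 2, seed = 6)
  crowns <- dplyr::bind_rows(
    dplyr::mutate(surface_crown_cloud(scene, 1, seed = 1), plant_id = 1L),
    dplyr::mutate(surface_crown_cloud(scene, 2, seed = 2), plant_id = 2L))
  bio <- biometrics_table(crowns)
  vol <- volumes_table(crowns)
  c1 <- crowns[crowns$plant_id == 1L, ]
  expect_equal(bio$HPL[1], plant_height(c1))
  expect_equal(bio$DCL[1], canopy_diameter(c1))
  expect_equal(vol$VCH[1], convex_hull_volume(c1)$volume)
  expect_equal(vol$VV[1], voxel_volume(c1)$volume)
  expect_equal(vol$VCY[1], cylinder_volume(bio$DCL[1], bio$HCL[1]))
})
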