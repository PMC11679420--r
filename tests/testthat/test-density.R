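test_that("height profile densities follow the bin definition", {
  # all points inside one 0.4 m bin
  one <- make_cloud(runif(64, 0, 0.3), runif(64, 1, 1.3), runif(64, 0, 0.3))
  prof <- height_density_profile(one)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$mean_density, 64 / 0.064)
  # two layers with one occupied bin each, holding 64 and 128 points
  two <- dplyr::bind_rows(
    make_cloud(runif(64, 0, 0.3), runif(64, 0.0, 0.35), runif(64, 0, 0.3)),
    make_cloud(runif(128, 0, 0.3), runif(128, 0.45, 0.75), runif(128, 0, 0.3)))
  prof2 <- height_density_profile(two)
  expect_equal(prof2$mean_density, c(1000, 2000))
  # a 3.4 m canopy spans ceiling(3.4 / 0.4) = 9 layers
  tall <- make_cloud(runif(500), c(0, 3.4, runif(498, 0, 3.4)), runif(500))
  expect_equal(nrow(height_density_profile(tall)), 9L)
  expect_error(height_density_profile(make_cloud(double(), double(), double())))
})

test_that("height binning conserves the point count", {
  cl <- make_cloud(runif(2000, 0, 2), runif(2000, 0, 3), runif(2000, 0, 4))
  prof <- height_density_profile(cl)
  expect_equal(sum(prof$n_points), 2000L)
})

test_that("thickness partitioning makes 2a sections of width Wb", {
  cl <- make_cloud(c(0, 7, runif(998, 0, 7)), runif(1000, 0, 2),
                   runif(1000, 0, 3))
  prof <- thickness_density_profile(cl, a = 3.5)
  expect_equal(nrow(prof), 7L)
  expect_equal(attr(prof, "Wb"), 1.0)
  expect_equal(as.character(prof$section),
               c("E1", "E2", "E3", "C", "W3", "W2", "W1"))
  expect_equal(prof$x_lo, 0:6)
  expect_equal(sum(prof$n_points), 1000L)
  expect_error(thickness_density_profile(make_cloud(0, 1, 0)))
  expect_error(thickness_density_profile(make_cloud(c(0, 0), 1:2, 1:2)),
               class = "olivescan_geometry_error")
})

test_that("a uniform box yields near-equal section percentages", {
  withr::with_seed(8, {
    cl <- make_cloud(runif(50000, 0, 4.2), runif(50000, 0, 2.5),
                     runif(50000, 0, 3))
  })
  prof <- thickness_density_profile(cl)
  expect_true(all(abs(prof$percentage - 100 / 7) < 2))
  expect_equal(sum(prof$percentage), 100, tolerance = 1e-6)
})

test_that("single-point sections stay finite through the extent floor", {
  cl <- dplyr::bind_rows(
    make_cloud(runif(200, 0, 1), runif(200, 0, 2), runif(200, 0, 2)),
    make_cloud(6.9, 1, 1))    # a lone point in the outermost section
  prof <- thickness_density_profile(cl)
  lone <- prof[7, ]             # the outermost west section holds the point
  expect_equal(lone$n_points, 1L)
  expect_true(is.finite(lone$density) && lone$density > 0)
  expect_equal(lone$density, 1 / (attr(prof, "Wb") * 0.01 * 0.01))
})

test_that("percentages normalize densities and reject all-zero profiles", {
  cl <- make_cloud(runif(700, 0, 7), runif(700, 0, 2), runif(700, 0, 2))
  prof <- thickness_density_profile(cl)
  expect_equal(sum(density_percentages(prof)$percentage), 100,
               tolerance = 1e-6)
  zero <- prof
  zero$density <- 0
  expect_error(density_percentages(zero), class = "olivescan_geometry_error")
})

test_that("profiles are invariant to rigid translation along the row", {
  withr::with_seed(5, {
    cl <- make_cloud(runif(3000, -2, 2), runif(3000, 0.7, 3.5),
                     runif(3000, 0, 4))
  })
  sh <- cl
  sh$z <- sh$z + 12.3
  h1 <- height_density_profile(cl); h2 <- height_density_profile(sh)
  expect_equal(h1$mean_density, h2$mean_density)
  t1 <- thickness_density_profile(cl); t2 <- thickness_density_profile(sh)
  expect_equal(t1$density, t2$density)
  expect_equal(t1$percentage, t2$percentage)
})

test_that("pruning low outboard material moves the density mode upward", {
  withr::with_seed(9, {
    cl <- make_cloud(runif(6000, -2.2, 2.2), runif(6000, 0.7, 3.5),
                     runif(6000, 0, 4))
  })
  pruned <- cl[!(cl$y < 1.6 & abs(cl$x) > 1.0), ]
  mode_y <- function(p) {
    m <- p[which.max(p$mean_density), ]
    (m$y_lo + m$y_hi) / 2
  }
  expect_gte(mode_y(height_density_profile(pruned)),
             mode_y(height_density_profile(cl)) - 1e-9)
})

test_that("occupied-only averaging exceeds the all-bin average on sparse crowns", {
  withr::with_seed(12, {
    cl <- make_cloud(runif(800, 0, 3), runif(800, 0, 1.1), runif(800, 0, 3))
  })
  occ <- height_density_profile(cl, occupied_only = TRUE)
  all_bins <- height_density_profile(cl, occupied_only = FALSE)
  expect_true(all(occ$mean_density >= all_bins$mean_density - 1e-9))
})
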