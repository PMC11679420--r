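test_that("polar frames convert by the stated trigonometry", {
  pass <- scan_pass_spec("east")
  p1 <- polar_to_cartesian(data.frame(angle = 0, range = 2), pass, z = 5)
  expect_equal(unlist(p1[, c("x", "y", "z")], use.names = FALSE),
               c(2, 1.95, 5))
  p2 <- polar_to_cartesian(data.frame(angle = 90, range = 1), pass, z = 5)
  expect_equal(unlist(p2[, c("x", "y", "z")], use.names = FALSE),
               c(0, 2.95, 5), tolerance = 1e-12)
  p3 <- polar_to_cartesian(data.frame(angle = 45, range = 2), pass, z = 5)
  expect_equal(unlist(p3[, c("x", "y", "z")], use.names = FALSE),
               c(sqrt(2), 1.95 + sqrt(2), 5), tolerance = 1e-9)
  # sentinel beams and out-of-sector angles produce no point
  none <- polar_to_cartesian(data.frame(angle = c(0, 250), range = c(-1, 3)),
                             pass, z = 0)
  expect_equal(nrow(none), 0L)
})

test_that("pass assembly spans (n - 1) spacings and flags broken series", {
  pass <- scan_pass_spec("east", range_noise_sd = 0)
  frames <- tibble::tibble(
    station = rep(1:11, each = 2),
    z = rep(seq(0, 2, by = 0.2), each = 2),
    angle = rep(c(0, 10), 11),
    range = 3
  )
  attr(frames, "pass") <- pass
  class(frames) <- c("scan_series", class(frames))
  cloud <- assemble_pass(frames)
  expect_equal(diff(range(cloud$z)), 2.0)
  single <- frames[frames$station == 1, ]
  attr(single, "pass") <- pass
  class(single) <- c("scan_series", class(single))
  expect_equal(unique(assemble_pass(single)$z), 0)
  empty <- frames[0, ]
  attr(empty, "pass") <- pass
  class(empty) <- c("scan_series", class(empty))
  expect_equal(nrow(assemble_pass(empty)), 0L)

  broken <- frames
  broken$z[broken$station == 6] <- 0.95   # uneven spacing
  attr(broken, "pass") <- pass
  expect_error(assemble_pass(broken), class = "olivescan_format_error")
})

test_that("reference markers are recovered at their true positions", {
  scene <- generate_orchard(orchard_config(n_plants = 3), seed = 5)
  pass <- noiseless_pass("east", seed = 1)
  cloud <- assemble_pass(simulate_scan(scene, pass))
  mk <- detect_markers(cloud)
  expect_equal(nrow(mk), 2L)
  expect_lte(max(abs(mk$z - scene$markers$z)), 0.1)
  expect_equal(diff(mk$z), 5.0, tolerance = 0.1)
  expect_true(all(mk$y >= 0.8 & mk$y <= 1.3))
  # a cloud with no isolated low clusters yields no markers
  expect_equal(nrow(detect_markers(make_cloud(0, 3, 0))), 0L)
})

test_that("side pairing closes the crown and conserves points", {
  scene <- generate_orchard(orchard_config(n_plants = 2), seed = 7)
  se <- simulate_scan(scene, noiseless_pass("east", seed = 1))
  sw <- simulate_scan(scene, noiseless_pass("west", seed = 2))
  ce <- assemble_pass(se); cw <- assemble_pass(sw)
  me <- detect_markers(ce); mw <- detect_markers(cw)
  row <- pair_sides(ce, cw, me, mw)
  expect_equal(nrow(row), nrow(ce) + nrow(cw))
  expect_lt(attr(row, "marker_residual"), 0.1)

  # reconstructed crown thickness within 5% of the true envelope extent
  truth <- olivescan:::scene_truth(scene)
  rg <- remove_ground(row)
  rg <- label_markers(rg, detect_markers(rg))
  seg <- segment_plants(split_plants(rg, detect_markers(rg)))
  for (pid in truth$plant_id) {
    canopy <- seg[seg$label == "canopy" & !is.na(seg$plant_id) &
                    seg$plant_id == pid, ]
    width <- diff(range(canopy$x))
    expect_lt(abs(width - truth$crown_width[pid]) / truth$crown_width[pid],
              0.05)
  }
  expect_error(pair_sides(ce, cw, me[0, ], mw),
               class = "olivescan_pairing_error")
})

test_that("ground removal spares the crown and strips pure ground", {
  crown <- make_cloud(runif(500, -1, 1), runif(500, 0.7, 3.5),
                      runif(500, 0, 5))
  ground <- make_cloud(runif(400, -3, 3), rnorm(400, 0, 0.01),
                       runif(400, 0, 5))
  both <- dplyr::bind_rows(crown, ground)
  kept <- remove_ground(both)
  expect_equal(nrow(kept), 500L)
  expect_true(all(kept$y >= 0.5))
  expect_equal(nrow(remove_ground(crown)), 500L)       # nothing below 0.5 m
  expect_equal(nrow(remove_ground(ground)), 0L)        # pure ground plane
  expect_equal(nrow(attr(remove_ground(both), "removed")), 400L)
})

test_that("plant splitting honors markers, fallbacks and the boundary tie-break", {
  set.seed(1)
  two <- dplyr::bind_rows(
    make_cloud(runif(300, -1, 1), runif(300, 1, 3), rnorm(300, 2.5, 0.5)),
    make_cloud(runif(300, -1, 1), runif(300, 1, 3), rnorm(300, 7.5, 0.5)))
  mk <- tibble::tibble(marker_id = 1L, x = 0, y = 1.1, z = 5,
                       support_point_count = 10L)
  sp <- split_plants(two, mk)
  cent <- tapply(sp$z, sp$plant_id, mean)
  expect_equal(as.numeric(cent), c(2.5, 7.5), tolerance = 0.2)

  one <- make_cloud(runif(100), runif(100, 1, 3), runif(100, 0, 2))
  expect_warning(sp1 <- split_plants(one, NULL), "single plant")
  expect_true(all(sp1$plant_id == 1L))

  onb <- make_cloud(c(0, 0), c(2, 2), c(5, 5.01))
  spb <- split_plants(onb, mk)
  expect_equal(spb$plant_id, c(1L, 2L))   # the boundary point goes low
})

test_that("trunk separation finds the split height and partitions the cloud", {
  set.seed(2)
  trunk <- make_cloud(rnorm(150, 0, 0.05), runif(150, 0.05, 0.7),
                      rnorm(150, 0, 0.05))
  crown <- make_cloud(runif(800, -2, 2), runif(800, 0.7, 3.5),
                      runif(800, -1.5, 1.5))
  plant <- dplyr::bind_rows(trunk, crown)
  seg <- separate_trunk(plant)
  expect_equal(nrow(seg), nrow(plant))
  expect_lte(abs(attr(seg, "split_height") - 0.7), 0.15)
  expect_equal(sum(seg$label == "trunk") + sum(seg$label == "canopy"),
               nrow(plant))
  expect_gt(sum(seg$label == "trunk"), 100)

  crown_only <- separate_trunk(crown)
  expect_equal(sum(crown_only$label == "trunk"), 0L)
  expect_error(separate_trunk(crown[0, ]))
})

test_that("noiseless end-to-end reconstruction stays on the true surfaces", {
  scene <- generate_orchard(orchard_config(n_plants = 2), seed = 9)
  scene$branches$porosity <- 0
  se <- simulate_scan(scene, noiseless_pass("east", seed = 1))
  sw <- simulate_scan(scene, noiseless_pass("west", seed = 2))
  rec <- reconstruct_row(se, sw)
  seg <- segment_plants(split_plants(rec$cloud, rec$markers))
  canopy <- seg[seg$label == "canopy" & !is.na(seg$plant_id), ]
  q <- do.call(pmin, lapply(seq_len(nrow(scene$branches)), function(j) {
    b <- scene$branches[j, ]
    abs(sqrt(envelope_q(canopy, b)) - 1) * min(b$ex, b$ey, b$ez)
  }))
  expect_gte(mean(q <= 0.02), 0.95)
})
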