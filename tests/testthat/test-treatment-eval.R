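test_that("the treatment zone is segmented to sub-voxel centroid accuracy", {
  rc <- render_config(fov_side = 48, voxel_size = 1, noise_sigma = 10, seed = 5)
  tc <- treatment_phantom_config(zone_center = c(4.3, -6.2, 3.4))
  pair <- render_treatment_pair(tc, rc)
  mask <- segment_treatment_zone(pair$post, seed_point = pair$zone_centroid)
  m <- measure_targeting(mask, pair$zone_centroid)
  expect_lt(max(abs(m$directional_error)), 0.5)
  # the cleanup stages are projections: largest component, closing and
  # hole-fill are exact fixpoints on the segmented zone, and a further
  # median pass moves the measured centroid by far less than half a voxel
  once <- mask$data
  expect_identical(largest_component(once, 26), once)
  expect_identical(close_mask(once), once)
  expect_identical(fill_holes(once), once)
  twice <- postprocess_mask(once, mask$spacing)
  m2 <- measure_targeting(voxel_volume(twice, mask$spacing, mask$origin),
                          pair$zone_centroid)
  expect_lt(sqrt(sum((m2$observed_centroid - m$observed_centroid)^2)), 0.25)
})

test_that("post-processing keeps the largest object and fills cavities", {
  mask <- array(FALSE, c(24, 24, 24))
  mask[4:16, 4:16, 4:16] <- TRUE   # large blob
  mask[20:21, 20:21, 20:21] <- TRUE  # small distractor
  out <- largest_component(mask, 26)
  expect_true(all(out[4:16, 4:16, 4:16]))
  expect_false(any(out[20:21, 20:21, 20:21]))

  hollow <- array(FALSE, c(16, 16, 16))
  hollow[4:12, 4:12, 4:12] <- TRUE
  hollow[7:9, 7:9, 7:9] <- FALSE   # interior cavity
  filled <- fill_holes(hollow)
  expect_true(all(filled[4:12, 4:12, 4:12]))
  # the full pipeline also removes the cavity
  post <- postprocess_mask(hollow, spacing = rep(1, 3))
  expect_true(all(post[7:9, 7:9, 7:9]))
})

test_that("region growing fails loudly outside any homogeneous zone", {
  rc <- render_config(fov_side = 32, voxel_size = 1, noise_sigma = 0, seed = 6)
  pair <- render_treatment_pair(treatment_phantom_config(zone_center = c(2, 2, 2)), rc)
  expect_error(segment_treatment_zone(pair$post, c(100, 0, 0)),
               class = "helixreg_out_of_bounds")
  # a tolerance of zero in a noisy volume grows nothing beyond the seed
  rcn <- render_config(fov_side = 32, voxel_size = 1, noise_sigma = 10, seed = 6)
  pairn <- render_treatment_pair(treatment_phantom_config(zone_center = c(2, 2, 2)), rcn)
  expect_error(segment_treatment_zone(pairn$post, c(2, 2, 2), tolerance = 0),
               class = "helixreg_segmentation_failure")
})

test_that("targeting errors decompose into direction and norm", {
  data <- array(FALSE, c(9, 9, 9)); data[5, 5, 5] <- TRUE
  mask <- voxel_volume(data, rep(1, 3), rep(-4, 3))
  hit <- measure_targeting(mask, c(0, 0, 0))
  expect_equal(hit$tre, 0)
  expect_equal(hit$directional_error, c(0, 0, 0))

  off <- measure_targeting(mask, c(-1, -2, -2))
  expect_equal(off$directional_error, c(1, 2, 2))
  expect_equal(off$tre, 3)
  expect_equal(off$tre, sqrt(sum(off$directional_error^2)))
})

test_that("TRE is invariant when mask and target move together", {
  data <- array(FALSE, c(12, 12, 12)); data[4:6, 5:7, 6:8] <- TRUE
  mask <- voxel_volume(data, rep(1, 3), rep(0, 3))
  planned <- c(3.2, 5.1, 8.4)
  base <- measure_targeting(mask, planned)
  # common translation
  shifted <- voxel_volume(data, rep(1, 3), c(10, -5, 2.5))
  m2 <- measure_targeting(shifted, planned + c(10, -5, 2.5))
  expect_equal(m2$tre, base$tre, tolerance = 1e-12)
  # common 90-degree rotation about Z: (x,y,z) -> (-y,x,z)
  rot <- voxel_volume(aperm(data[, dim(data)[2]:1, ], c(2, 1, 3)),
                      rep(1, 3), c(-11, 0, 0))
  m3 <- measure_targeting(rot, c(-planned[2], planned[1], planned[3]))
  expect_equal(m3$tre, base$tre, tolerance = 1e-12)
})

test_that("the closed targeting loop reproduces a planned focal point", {
  # plan a target, derive the robot pose, "deliver" at the induced focal
  # point, render, segment and measure: with no injected error the TRE is
  # below one voxel
  set.seed(46)
  te2h <- random_rigid("e", "h", t_scale = 20)
  tr2c <- random_rigid("r", "c", t_scale = 20)
  target <- c(3.7, -2.4, 1.6)
  pose <- targeting_pose(target_plan(target), te2h, tr2c)
  induced <- compose(compose(tr2c, invert(pose)), invert(te2h))
  focal <- apply_point(induced, c(0, 0, 0))
  rc <- render_config(fov_side = 48, voxel_size = 1, noise_sigma = 5, seed = 7)
  pair <- render_treatment_pair(treatment_phantom_config(zone_center = focal), rc)
  mask <- segment_treatment_zone(pair$post, seed_point = focal)
  m <- measure_targeting(mask, target)
  expect_lt(m$tre, 1)
})
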