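test_that("distance-pattern costs are rigid invariants with zero cost at truth", {
  model <- generate_model()
  large <- model_points(model, "large")
  set.seed(41)
  t <- random_rigid("p", "c")
  moved <- apply_point(t, large)
  res <- match_large_fiducials(moved, large)
  expect_equal(res$pairs$model_index, 1:10)
  expect_lt(max(res$cost_per_pair), 1e-9)
  # Eq-style costs depend on distances only: any rigid motion leaves them fixed
  base_cost <- oracle_match_costs(large[2:6, ], large)
  for (rep in 1:5) {
    t2 <- random_rigid("p", "c")
    moved_cost <- oracle_match_costs(apply_point(t2, large[2:6, ]), large)
    expect_equal(moved_cost, base_cost, tolerance = 1e-9)
  }
})

test_that("jittered runs match correctly and agree with the exhaustive oracle", {
  model <- generate_model()
  large <- model_points(model, "large")
  set.seed(42)
  for (trial in 1:100) {
    m <- sample(5:8, 1)
    t0 <- sample.int(10 - m + 1, 1)
    run <- t0:(t0 + m - 1)
    t <- random_rigid("p", "c")
    pts <- apply_point(t, large[run, , drop = FALSE]) +
      matrix(stats::rnorm(3 * m, 0, 0.1), m, 3)
    # margin 0: assert correctness of the assignment itself; the 0.5 mm
    # ambiguity guard is validated on clean patterns elsewhere
    got <- match_large_fiducials(pts, large, margin = 0)
    expect_equal(got$pairs$model_index, run)
    cost <- oracle_match_costs(pts, large)
    expect_equal(oracle_best_assignment(cost), run)
  }
})

test_that("degenerate correspondences are rejected loudly", {
  model <- generate_model()
  large <- model_points(model, "large")
  expect_error(match_large_fiducials(large[1:3, ], large),
               class = "helixreg_insufficient_fiducials")
  expect_error(match_large_fiducials(large, large[1:6, ]),
               class = "helixreg_insufficient_fiducials")
  # a symmetric constellation (regular octagon) is ambiguous by construction
  theta <- seq(0, 2 * pi, length.out = 9)[1:8]
  oct <- cbind(30 * cos(theta), 30 * sin(theta), 0)
  expect_error(match_large_fiducials(oct[1:4, ], oct),
               class = "helixreg_ambiguous_correspondence")
})

test_that("affine least squares recovers generating transforms exactly", {
  model <- generate_model()
  large <- model_points(model, "large")
  corr <- structure(list(pairs = data.frame(cbct_index = 1:10, model_index = 1:10)),
                    class = "fiducial_correspondence")
  ident <- estimate_affine(corr, large, large)
  expect_lt(max(abs(ident$matrix - diag(4))), 1e-9)

  set.seed(43)
  for (rep in 1:5) {
    t <- random_rigid("p", "c")
    est <- estimate_affine(corr, apply_point(t, large), large)
    expect_lt(max(abs(est$matrix - t$matrix)), 1e-9)
    # scale is recovered too: the affine fit does not enforce rigidity
    scaled <- t$matrix; scaled[1:3, 1:3] <- 1.02 * scaled[1:3, 1:3]
    est2 <- estimate_affine(corr,
                            large %*% t(scaled[1:3, 1:3]) +
                              matrix(scaled[1:3, 4], 10, 3, TRUE),
                            large)
    expect_lt(max(abs(est2$matrix - scaled)), 1e-9)
  }
  coplanar <- cbind(large[, 1:2], 0)
  expect_error(estimate_affine(corr, coplanar, coplanar),
               class = "helixreg_rank_deficient")
})

test_that("refinement converges under the three stopping criteria", {
  model <- generate_model()
  pts <- model_points(model)
  truth <- as_homogeneous(rigid_transform(rotation_about_axis(c(0, 1, 0), 0.02),
                                          c(2, -1, 3)), "p", "c")
  vis <- fiducials_in_fov(model, 160, truth)
  detected <- apply_point(truth, pts)[vis$visible, , drop = FALSE]

  # already optimal: terminates without moving
  r0 <- refine_registration(truth, detected, model)
  expect_lt(r0$rmse, 1e-6)
  expect_lt(max(abs(r0$tp2c$matrix - truth$matrix)), 1e-3)
  expect_true(r0$termination_reason %in%
                c("cost-tolerance", "step-tolerance", "max-iterations"))

  # perturbed by 2 mm translation and 2 degrees rotation
  perturb <- as_homogeneous(
    rigid_transform(rotation_about_axis(c(1, 0.5, 0), 2 * pi / 180),
                    c(2, 0, 0)), "p", "p")
  init <- compose(truth, perturb)
  r1 <- refine_registration(init, detected, model)
  expect_true(r1$converged)
  expect_lte(r1$iterations, 2000L)
  expect_lt(sqrt(sum((r1$tp2c$matrix[1:3, 4] - truth$matrix[1:3, 4])^2)), 0.01)
  expect_lt(rotation_angle_deg(r1$tp2c$matrix[1:3, 1:3], truth$matrix[1:3, 1:3]),
            0.01)
  # refinement never worsens the starting cost
  expect_lte(r1$rmse, compute_fre(init, detected, model))
})

test_that("refinement reaches the centroid-jitter noise floor", {
  model <- generate_model()
  pts <- model_points(model)
  set.seed(44)
  for (rep in 1:20) {
    truth <- random_phantom_pose()
    vis <- fiducials_in_fov(model, 160, truth)
    detected <- apply_point(truth, pts)[vis$visible, , drop = FALSE] +
      matrix(stats::rnorm(3 * vis$n_visible, 0, 0.05), vis$n_visible, 3)
    init <- compose(truth, as_homogeneous(
      rigid_transform(rotation_about_axis(stats::rnorm(3), 0.01),
                      stats::rnorm(3, 0, 1)), "p", "p"))
    r <- refine_registration(init, detected, model)
    expect_lte(r$rmse, 0.15)
    expect_true(r$converged)
  }
})

test_that("FRE matches hand-computed root mean square distances", {
  model <- generate_model()
  pts <- model_points(model)
  ident <- identity_transform("p", "c")
  expect_lt(compute_fre(ident, pts, model), 1e-6)
  one <- matrix(c(10, 0, 0), 1, 3)
  shifted <- one + c(0.1, 0, 0)
  pairs <- data.frame(cbct_index = 1L, model_index = 1L)
  expect_equal(compute_fre(ident, shifted, one, pairs), 0.1)
  two <- rbind(c(0, 0, 0), c(20, 0, 0))
  moved <- two + rbind(c(0.1, 0, 0), c(0, 0.2, 0))
  pairs2 <- data.frame(cbct_index = 1:2, model_index = 1:2)
  expect_equal(compute_fre(ident, moved, two, pairs2),
               sqrt((0.01 + 0.04) / 2), tolerance = 1e-12)
})

test_that("full registration recovers truth and rejects sparse scenes", {
  model <- generate_model()
  truth <- as_homogeneous(rigid_transform(rotation_about_axis(c(0, 1, 0), 0.04),
                                          c(30, 5, 10)), "p", "c")
  # off-center pose truncates down to 7 large fiducials, as in the worst
  # observed experimental trial
  expect_equal(fiducials_in_fov(model, 160, truth)$n_large, 7L)
  cfg <- render_config(fov_side = 160, voxel_size = 1, noise_sigma = 10, seed = 9)
  r <- render_phantom_cbct(model, truth, cfg)
  res <- register_cbct(r$volume, model,
                       spec = threshold_spec(mode = "expected-volume"))
  expect_lt(sqrt(sum((res$tp2c$matrix[1:3, 4] - truth$matrix[1:3, 4])^2)), 0.2)
  expect_lt(rotation_angle_deg(res$tp2c$matrix[1:3, 1:3], truth$matrix[1:3, 1:3]),
            0.1)
  expect_equal(res$n_large_used, 7L)
  expect_true(res$converged)

  # a scene containing only three large fiducials cannot be registered
  three <- model[model$size_class == "large", ][1:3, ]
  cfg2 <- render_config(fov_side = 160, voxel_size = 1, noise_sigma = 10, seed = 10)
  pose <- as_homogeneous(rigid_transform(diag(3), -colMeans(model_points(three))),
                         "p", "c")
  r2 <- render_phantom_cbct(three, pose, cfg2)
  expect_equal(sum(r2$truth$visible), 3L)
  expect_error(register_cbct(r2$volume, model,
                             spec = threshold_spec(mode = "expected-volume")),
               class = "helixreg_insufficient_fiducials")
})
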