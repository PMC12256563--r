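test_that("composition matches the brute-force matrix product and chains frames", {
  T1 <- identity_transform("p", "c")
  T2 <- random_rigid("e", "p")
  expect_equal(compose(T1, T2)$matrix, T2$matrix)

  set.seed(11)
  for (rep in 1:10) {
    a <- random_rigid("p", "c")
    b <- random_rigid("e", "p")
    ab <- compose(a, b)
    # brute-force element-wise product oracle
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4)
      oracle[i, j] <- sum(a$matrix[i, ] * b$matrix[, j])
    expect_equal(ab$matrix, oracle, tolerance = 1e-12)
    expect_identical(ab$frame_from, "e")
    expect_identical(ab$frame_to, "c")
  }
  expect_error(compose(random_rigid("p", "c"), random_rigid("r", "e")),
               class = "helixreg_frame_mismatch")
})

test_that("composition is associative on random rigid triples", {
  set.seed(12)
  for (rep in 1:20) {
    a <- random_rigid("p", "c"); b <- random_rigid("e", "p"); c <- random_rigid("r", "e")
    lhs <- compose(compose(a, b), c)
    rhs <- compose(a, compose(b, c))
    expect_lt(max(abs(lhs$matrix - rhs$matrix)), 1e-9)
  }
})

test_that("inversion matches the closed-form rigid inverse", {
  expect_equal(invert(identity_transform("p", "c"))$matrix, diag(4))
  tr <- as_homogeneous(rigid_transform(diag(3), c(1, 2, 3)), "p", "c")
  expect_equal(invert(tr)$matrix[1:3, 4], c(-1, -2, -3))

  set.seed(13)
  for (rep in 1:10) {
    t <- random_rigid("p", "c")
    inv <- invert(t)
    R <- t$matrix[1:3, 1:3]
    expect_equal(inv$matrix[1:3, 1:3], t(R), tolerance = 1e-12)
    expect_equal(inv$matrix[1:3, 4], drop(-t(R) %*% t$matrix[1:3, 4]),
                 tolerance = 1e-12)
    expect_lt(max(abs(compose(t, inv)$matrix - diag(4))), 1e-9)
    expect_identical(inv$frame_from, "c")
  }
  singular <- diag(4); singular[1, 1] <- 0
  expect_error(homogeneous_transform(singular, "p", "c"),
               class = "helixreg_degenerate_transform")
})

test_that("points map through translations and rotations as expected", {
  expect_equal(apply_point(identity_transform("p", "c"), c(5, 5, 5)), c(5, 5, 5))
  tr <- as_homogeneous(rigid_transform(diag(3), c(1, 0, 0)), "p", "c")
  expect_equal(apply_point(tr, c(0, 0, 0)), c(1, 0, 0))
  rz <- as_homogeneous(rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 2)), "p", "c")
  expect_equal(apply_point(rz, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  # matrix form maps each row
  pts <- rbind(c(1, 0, 0), c(0, 2, 0))
  expect_equal(apply_point(rz, pts), rbind(c(0, 1, 0), c(-2, 0, 0)),
               tolerance = 1e-12)
})

test_that("projection to the rigid group matches the polar decomposition oracle", {
  # eigen-based polar factor A (A^T A)^{-1/2} as the independent oracle
  polar_oracle <- function(A) {
    e <- eigen(crossprod(A), symmetric = TRUE)
    A %*% (e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors))
  }
  scaled <- diag(4); scaled[1:3, 1:3] <- 2 * diag(3); scaled[1:3, 4] <- c(1, 2, 3)
  pr <- project_to_rigid(homogeneous_transform(scaled, "p", "c"))
  expect_equal(pr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(pr$translation, c(1, 2, 3))

  set.seed(14)
  for (rep in 1:10) {
    R <- random_rotation()
    A <- R %*% diag(c(1.01, 1, 0.99))   # 1% anisotropic scale perturbation
    m <- diag(4); m[1:3, 1:3] <- A
    got <- project_to_rigid(homogeneous_transform(m, "p", "c"))$rotation
    expect_lt(max(abs(got - polar_oracle(A))), 1e-9)
    expect_lt(max(abs(got - R)), 1e-6)
    # idempotence
    again <- project_to_rigid(as_homogeneous(rigid_transform(got), "p", "c"))
    expect_lt(max(abs(again$rotation - got)), 1e-9)
  }
  refl <- diag(4); refl[1, 1] <- -1
  expect_error(project_to_rigid(homogeneous_transform(refl, "p", "c")),
               class = "helixreg_reflection")
})

test_that("the registration chain reproduces step-by-step point mapping", {
  expect_equal(robot_to_cbct(identity_transform("p", "c"),
                             identity_transform("e", "p"),
                             identity_transform("r", "e"))$matrix, diag(4))
  tp2c <- as_homogeneous(rigid_transform(diag(3), c(1, 2, 3)), "p", "c")
  expect_equal(robot_to_cbct(tp2c, identity_transform("e", "p"),
                             identity_transform("r", "e"))$matrix[1:3, 4],
               c(1, 2, 3))
  set.seed(15)
  for (rep in 1:10) {
    tp2c <- random_rigid("p", "c"); te2p <- random_rigid("e", "p")
    tr2e <- random_rigid("r", "e")
    tr2c <- robot_to_cbct(tp2c, te2p, tr2e)
    p <- stats::rnorm(3, sd = 30)
    chained <- apply_point(tp2c, apply_point(te2p, apply_point(tr2e, p)))
    expect_equal(apply_point(tr2c, p), chained, tolerance = 1e-9)
    expect_identical(tr2c$frame_from, "r")
    expect_identical(tr2c$frame_to, "c")
  }
})

test_that("targeting pose places the transducer focal point on the target", {
  # direct substitution: everything identity, target (10,20,30)
  pose <- targeting_pose(target_plan(c(10, 20, 30)),
                         identity_transform("e", "h"),
                         identity_transform("r", "c"))
  expect_equal(pose$matrix[1:3, 1:3], diag(3))
  expect_equal(pose$matrix[1:3, 4], c(-10, -20, -30))

  set.seed(16)
  for (rep in 1:100) {
    te2h <- random_rigid("e", "h")
    tr2c <- random_rigid("r", "c")
    x <- stats::runif(3, -60, 60)
    rh2c <- random_rotation()
    pose <- targeting_pose(target_plan(x, rh2c), te2h, tr2c)
    induced <- compose(compose(tr2c, invert(pose)), invert(te2h))
    expect_lt(max(abs(induced$matrix[1:3, 1:3] - rh2c)), 1e-9)
    expect_lt(max(abs(induced$matrix[1:3, 4] - x)), 1e-9)
    # the transducer-frame origin lands on the target
    expect_equal(apply_point(induced, c(0, 0, 0)), x, tolerance = 1e-9)
  }
})

test_that("transform JSON serialization validates frames and round-trips", {
  t <- random_rigid("r", "c")
  f <- tempfile(fileext = ".json")
  write_transform_json(t, f)
  r <- read_transform_json(f)
  expect_equal(r$matrix, t$matrix, tolerance = 1e-12)
  expect_identical(r$frame_from, "r")

  bad <- tempfile(fileext = ".json")
  writeLines('{"frame_from": "r", "frame_to": "c", "matrix": [[1,0,0,0],[0,1,0,0],[0,0,1,0],[1,0,0,1]]}', bad)
  expect_error(read_transform_json(bad), class = "helixreg_invalid_transform")
  writeLines('{"frame_to": "c"}', bad)
  expect_error(read_transform_json(bad), class = "helixreg_format_error")
  expect_error(homogeneous_transform(diag(4), "q", "c"),
               class = "helixreg_invalid_transform")
})
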