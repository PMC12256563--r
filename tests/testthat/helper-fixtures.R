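# Shared fixtures: random rigid transforms, small rendered scenes, and an
# independent brute-force scorer for the distance-pattern correspondence.

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, pi))
}

random_rigid <- function(frame_from, frame_to, t_scale = 50) {
  as_homogeneous(rigid_transform(random_rotation(),
                                 stats::runif(3, -t_scale, t_scale)),
                 frame_from, frame_to)
}

# small perturbation of the centered phantom pose, as a user aligning the
# phantom to the isocenter lasers would produce
random_phantom_pose <- function(max_angle = 0.06, max_shift = 5) {
  as_homogeneous(
    rigid_transform(rotation_about_axis(stats::rnorm(3),
                                        stats::runif(1, 0.01, max_angle)),
                    stats::runif(3, -max_shift, max_shift)),
    "p", "c")
}

model_points <- function(model, class = NULL) {
  if (!is.null(class)) model <- model[model$size_class == class, , drop = FALSE]
  unname(base::as.matrix(model[, c("x", "y", "z")]))
}

# independent double-loop implementation of the distance-pattern cost used
# as the oracle for correspondence tests
oracle_match_costs <- function(cbct_pts, model_pts) {
  m <- nrow(cbct_pts); nl <- nrow(model_pts)
  cost <- matrix(0, m, nl)
  for (i in seq_len(m)) {
    for (j in seq_len(nl)) {
      s <- 0
      for (k in seq_len(m)[-i]) {
        dik <- sqrt(sum((cbct_pts[i, ] - cbct_pts[k, ])^2))
        best <- Inf
        for (jp in seq_len(nl)[-j]) {
          djj <- sqrt(sum((model_pts[j, ] - model_pts[jp, ])^2))
          best <- min(best, abs(dik - djj))
        }
        s <- s + best
      }
      cost[i, j] <- s
    }
  }
  cost
}

# all injective assignments of m detected fiducials onto nl model indices
injective_assignments <- function(m, nl) {
  out <- matrix(seq_len(nl), ncol = 1)
  for (step in seq_len(m - 1L)) {
    rows <- nrow(out)
    grown <- vector("list", rows)
    for (r in seq_len(rows)) {
      free <- setdiff(seq_len(nl), out[r, ])
      grown[[r]] <- cbind(out[rep(r, length(free)), , drop = FALSE], free)
    }
    out <- do.call(rbind, grown)
  }
  dimnames(out) <- NULL
  out
}

# globally optimal assignment by exhaustive scoring of every candidate
oracle_best_assignment <- function(cost) {
  A <- injective_assignments(nrow(cost), ncol(cost))
  totals <- numeric(nrow(A))
  for (i in seq_len(nrow(cost))) totals <- totals + cost[i, A[, i]]
  unname(A[which.min(totals), ])
}
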