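# Phantom-to-CBCT registration: distance-pattern correspondence of large
# fiducials, affine least-squares estimation, rigid direct-search refinement
# against all detected fiducials, FRE, and the end-to-end single-pose
# pipeline producing the robot-to-CBCT transform.

.pairwise_dist <- function(A, B = A) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# Distance-pattern cost of assigning detected large fiducial i to model
# large fiducial j: sum over the other detected fiducials of the smallest
# absolute mismatch between the detected distance and any model distance
# from j (candidate partners j' != j). Distances are rigid invariants, so
# the cost needs no pose estimate.
.large_match_costs <- function(cbct_pts, model_pts) {
  m <- nrow(cbct_pts); nl <- nrow(model_pts)
  Dc <- .pairwise_dist(cbct_pts)
  Dm <- .pairwise_dist(model_pts)
  cost <- matrix(0, m, nl)
  for (i in seq_len(m)) {
    di <- Dc[i, -i]
    for (j in seq_len(nl)) {
      dj <- Dm[j, -j]
      cost[i, j] <- sum(vapply(di, function(d) min(abs(d - dj)), 0))
    }
  }
  cost
}

# per-fiducial argmin assignment with ambiguity margins; no error raising
.match_distance_pattern <- function(cbct_pts, model_pts, margin = 0.5) {
  cost <- .large_match_costs(cbct_pts, model_pts)
  m <- nrow(cost)
  assignment <- integer(m)
  margins <- numeric(m)
  best_cost <- numeric(m)
  for (i in seq_len(m)) {
    o <- order(cost[i, ])
    assignment[i] <- o[1]
    best_cost[i] <- cost[i, o[1]]
    margins[i] <- if (length(o) > 1L) cost[i, o[2]] - cost[i, o[1]] else Inf
  }
  ok <- !anyDuplicated(assignment) && all(margins >= margin)
  list(ok = ok, assignment = assignment, cost = best_cost,
       margins = margins, cost_matrix = cost)
}

.as_points <- function(x) {
  if (is.data.frame(x)) base::as.matrix(x[, c("x", "y", "z")]) else base::as.matrix(x)
}

#' Match detected large fiducials to model large fiducials
#'
#' For each detected large fiducial the corresponding model fiducial is the
#' one minimizing the distance-pattern cost (brute force over all model
#' candidates): the summed absolute mismatch between the detected fiducial's
#' distances to its peers and the nearest model inter-fiducial distances.
#' The assignment is checked for injectivity and for an ambiguity margin
#' between best and second-best candidate.
#'
#' @param cbct_large detected large fiducials (data frame with x/y/z or
#'   n x 3 matrix, CBCT mm).
#' @param model_large model large fiducials (data frame or matrix, phantom
#'   mm).
#' @param margin ambiguity margin (mm).
#' @return list of class `fiducial_correspondence` with `pairs` (data frame
#'   `cbct_index`, `model_index`), `cost_per_pair` and `margins`.
#' @export
match_large_fiducials <- function(cbct_large, model_large, margin = 0.5) {
  cp <- .as_points(cbct_large)
  mp <- .as_points(model_large)
  if (nrow(cp) < 4L)
    .helixreg_error("helixreg_insufficient_fiducials",
                    sprintf("need at least 4 detected large fiducials, got %d", nrow(cp)))
  if (nrow(mp) < nrow(cp))
    .helixreg_error("helixreg_insufficient_fiducials",
                    "more detected large fiducials than model large fiducials")
  res <- .match_distance_pattern(cp, mp, margin)
  if (anyDuplicated(res$assignment))
    .helixreg_error("helixreg_ambiguous_correspondence",
                    "correspondence is not injective")
  if (any(res$margins < margin))
    .helixreg_error("helixreg_ambiguous_correspondence",
                    sprintf("correspondence ambiguity margin below %.3g mm", margin))
  structure(list(pairs = data.frame(cbct_index = seq_len(nrow(cp)),
                                    model_index = res$assignment),
                 cost_per_pair = res$cost, margins = res$margins),
            class = "fiducial_correspondence")
}

#' Affine phantom-to-CBCT estimate from corresponding fiducials
#'
#' Solves `Tp2c * [f(model); 1] = [f(CBCT); 1]` in the least-squares sense
#' (QR on the homogeneous model coordinates; the affine fit does not enforce
#' rigidity).
#'
#' @param correspondence a `fiducial_correspondence`.
#' @param cbct_large,model_large the point sets the correspondence indexes.
#' @return an affine `homogeneous_transform` (p -> c) with attribute
#'   `residual_rmse`.
#' @export
estimate_affine <- function(correspondence, cbct_large, model_large) {
  stopifnot(inherits(correspondence, "fiducial_correspondence"))
  cp <- .as_points(cbct_large)[correspondence$pairs$cbct_index, , drop = FALSE]
  mp <- .as_points(model_large)[correspondence$pairs$model_index, , drop = FALSE]
  if (nrow(cp) < 4L)
    .helixreg_error("helixreg_insufficient_fiducials",
                    "need at least 4 corresponding pairs")
  A <- cbind(mp, 1)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    .helixreg_error("helixreg_rank_deficient",
                    "corresponding fiducials are coplanar or degenerate")
  X <- qr.coef(qrA, cp)              # 4 x 3; columns map [model,1] -> cbct coord
  m <- rbind(t(X), c(0, 0, 0, 1))
  t <- homogeneous_transform(m, "p", "c")
  fitted <- A %*% X
  attr(t, "residual_rmse") <- sqrt(mean(rowSums((fitted - cp)^2)))
  t
}

# RMSE of detected fiducials to nearest transformed model fiducials
.nearest_rmse <- function(Tmat, detected_pts, model_pts) {
  mp <- model_pts %*% t(Tmat[1:3, 1:3]) +
    matrix(Tmat[1:3, 4], nrow(model_pts), 3, byrow = TRUE)
  D <- .pairwise_dist(detected_pts, mp)
  sqrt(mean(apply(D, 1, min)^2))
}

#' Rigid refinement of the phantom-to-CBCT transform
#'
#' Starting from the rigid projection of `init`, a derivative-free pattern
#' (compass) search over 6 rigid parameters minimizes the RMSE of Euclidean
#' distances between all detected fiducials (small and large) and the
#' closest model fiducials under the current transform. Rotation is
#' parameterized as an axis-angle vector scaled by the 54 mm phantom radius
#' so rotational and translational steps are commensurable in mm. The search
#' terminates at `max_iter` iterations, when the cost change has fallen
#' below `cost_tol` (mm) with no coarser step left to try, or when the poll
#' step size falls below `step_tol` (mm).
#'
#' @param init initial phantom-to-CBCT transform (affine allowed).
#' @param detected detected fiducials (all size classes; data frame or
#'   matrix, CBCT mm).
#' @param model phantom model (data frame or matrix, phantom mm).
#' @param max_iter maximum iterations.
#' @param cost_tol,step_tol stopping tolerances (mm).
#' @param initial_step initial poll step (mm).
#' @param rot_scale rotation scaling (mm per radian), default the phantom
#'   radius.
#' @return list with `transform` (a `rigid_transform`), `tp2c` (the same as
#'   a homogeneous p -> c transform), `rmse`, `iterations`,
#'   `termination_reason` and `converged`.
#' @export
refine_registration <- function(init, detected, model, max_iter = 2000L,
                                cost_tol = 1e-3, step_tol = 1e-3,
                                initial_step = 1, rot_scale = 54) {
  dp <- .as_points(detected)
  mp <- .as_points(model)
  r0 <- if (inherits(init, "rigid_transform")) init else project_to_rigid(init)
  R0 <- r0$rotation; t0 <- r0$translation
  tmat <- function(p) {
    Rd <- .rotvec_to_matrix(p[1:3] / rot_scale)
    m <- diag(4)
    m[1:3, 1:3] <- Rd %*% R0
    m[1:3, 4] <- Rd %*% t0 + p[4:6]
    m
  }
  p <- numeric(6)
  cost <- .nearest_rmse(tmat(p), dp, mp)
  h <- initial_step
  iter <- 0L
  reason <- "max-iterations"
  while (iter < max_iter) {
    iter <- iter + 1L
    best_cost <- cost; best_p <- NULL
    for (d in seq_len(6)) {
      for (s in c(-1, 1)) {
        pc <- p; pc[d] <- pc[d] + s * h
        cc <- .nearest_rmse(tmat(pc), dp, mp)
        if (cc < best_cost) { best_cost <- cc; best_p <- pc }
      }
    }
    if (!is.null(best_p)) {
      improvement <- cost - best_cost
      p <- best_p; cost <- best_cost
      if (improvement < cost_tol) {
        # progress at this scale has stalled; poll finer steps before
        # declaring the cost change converged
        h <- h / 2
        if (h < step_tol) { reason <- "cost-tolerance"; break }
      }
    } else {
      h <- h / 2
      if (h < step_tol) { reason <- "step-tolerance"; break }
    }
  }
  m <- tmat(p)
  rt <- rigid_transform(m[1:3, 1:3], m[1:3, 4])
  list(transform = rt,
       tp2c = as_homogeneous(rt, "p", "c"),
       rmse = cost, iterations = iter,
       termination_reason = reason,
       converged = reason != "max-iterations")
}

#' Fiducial registration error (FRE)
#'
#' RMSE of Euclidean distances between detected CBCT fiducials and their
#' corresponding model fiducials after mapping the model into the CBCT frame.
#' With `pairs = NULL` each detected fiducial is paired with the nearest
#' transformed model fiducial.
#'
#' @param transform phantom-to-CBCT transform (`homogeneous_transform` or
#'   `rigid_transform`).
#' @param detected detected fiducials (CBCT mm).
#' @param model model fiducials (phantom mm).
#' @param pairs optional data frame (`cbct_index`, `model_index`) of fixed
#'   correspondences.
#' @return FRE in mm.
#' @export
compute_fre <- function(transform, detected, model, pairs = NULL) {
  dp <- .as_points(detected)
  mp <- .as_points(model)
  Tmat <- if (inherits(transform, "rigid_transform"))
    as_homogeneous(transform, "p", "c")$matrix else transform$matrix
  mpc <- mp %*% t(Tmat[1:3, 1:3]) + matrix(Tmat[1:3, 4], nrow(mp), 3, byrow = TRUE)
  if (is.null(pairs)) {
    if (nrow(dp) < 1L)
      .helixreg_error("helixreg_insufficient_fiducials", "no fiducials to pair")
    D <- .pairwise_dist(dp, mpc)
    sqrt(mean(apply(D, 1, min)^2))
  } else {
    dd <- dp[pairs$cbct_index, , drop = FALSE] - mpc[pairs$model_index, , drop = FALSE]
    sqrt(mean(rowSums(dd^2)))
  }
}

#' Single-pose CBCT image-to-robot registration
#'
#' Runs the full pipeline on a CBCT volume of the helical fiducial phantom:
#' percentile threshold, connected-component fiducial extraction, size
#' classification, distance-pattern correspondence of the large fiducials,
#' affine least-squares initialization, rigid refinement against all
#' detected fiducials, and finally the chain
#' `Tr2c = Tp2c * Te2p * Tr2e(Reg)`.
#'
#' @param volume CBCT `voxel_volume` of the fiducial phantom.
#' @param model phantom model data frame from [generate_model()].
#' @param tr2e_reg robot pose during registration (r -> e).
#' @param te2p fixed tool-to-phantom calibration (e -> p).
#' @param spec a `threshold_spec`.
#' @param size_split small/large equivalent-diameter split (mm).
#' @param min_voxels minimum component size (voxels).
#' @param margin correspondence ambiguity margin (mm).
#' @param ... further arguments passed to [refine_registration()].
#' @return object of class `registration_result`: `tp2c_initial` (affine),
#'   `tp2c_refined` (rigid), `tr2c`, `fre` (mm), `n_large_used`,
#'   `n_small_used`, `converged`, `iterations`, `termination_reason`,
#'   `detected`, `correspondence`.
#' @export
register_cbct <- function(volume, model,
                          tr2e_reg = identity_transform("r", "e"),
                          te2p = identity_transform("e", "p"),
                          spec = threshold_spec(), size_split = 2.25,
                          min_voxels = 4L, margin = 0.5, ...) {
  tau <- compute_threshold(volume, spec, model = model)
  detected <- classify_sizes(extract_fiducials(volume, tau, min_voxels), size_split)
  det_large <- detected[detected$size_class == "large", , drop = FALSE]
  if (nrow(det_large) < 4L)
    .helixreg_error("helixreg_insufficient_fiducials",
                    sprintf("only %d large fiducials detected; need at least 4",
                            nrow(det_large)))
  model_large <- model[model$size_class == "large", , drop = FALSE]
  corr <- match_large_fiducials(det_large, model_large, margin)
  tp2c0 <- estimate_affine(corr, det_large, model_large)
  ref <- refine_registration(tp2c0, detected, model, ...)
  fre <- compute_fre(ref$tp2c, detected, model)
  tr2c <- robot_to_cbct(ref$tp2c, te2p, tr2e_reg)
  structure(list(tp2c_initial = tp2c0,
                 tp2c_refined = ref$transform,
                 tp2c = ref$tp2c,
                 tr2c = tr2c,
                 fre = fre,
                 threshold = tau,
                 n_large_used = nrow(det_large),
                 n_small_used = sum(detected$size_class == "small"),
                 converged = ref$converged,
                 iterations = ref$iterations,
                 termination_reason = ref$termination_reason,
                 detected = detected,
                 correspondence = corr),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Single-pose image-to-robot registration\n")
  cat(sprintf("  fiducials used: %d large + %d small\n",
              x$n_large_used, x$n_small_used))
  cat(sprintf("  FRE: %.4f mm\n", x$fre))
  cat(sprintf("  refinement: %d iterations (%s)\n",
              x$iterations, x$termination_reason))
  invisible(x)
}
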