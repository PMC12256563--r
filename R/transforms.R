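FRAME_LABELS <- c("r", "e", "p", "c", "h")

.helixreg_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "helixreg_error")))
}

#' Homogeneous coordinate transform between two frames
#'
#' A 4x4 homogeneous matrix mapping points in frame `frame_from` to frame
#' `frame_to` (translation components in mm). The frame labels follow the
#' registration setup: robot base (`r`), robot tool attachment point (`e`),
#' helical fiducial phantom (`p`), CBCT volume (`c`) and histotripsy
#' transducer (`h`).
#'
#' @param matrix 4x4 numeric matrix; bottom row must be `c(0, 0, 0, 1)`.
#' @param frame_from,frame_to single frame labels (one of `r`, `e`, `p`,
#'   `c`, `h`).
#' @return An object of class `homogeneous_transform`.
#' @export
homogeneous_transform <- function(matrix, frame_from, frame_to) {
  matrix <- base::as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (!identical(dim(matrix), c(4L, 4L)))
    .helixreg_error("helixreg_invalid_transform", "transform matrix must be 4x4")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12)
    .helixreg_error("helixreg_invalid_transform",
                    "bottom row of a homogeneous transform must be [0 0 0 1]")
  if (abs(det(matrix)) < 1e-12)
    .helixreg_error("helixreg_degenerate_transform", "transform matrix is singular")
  for (f in c(frame_from, frame_to)) {
    if (!is.character(f) || length(f) != 1L || !(f %in% FRAME_LABELS))
      .helixreg_error("helixreg_invalid_transform",
                      sprintf("frame label must be one of %s",
                              paste(FRAME_LABELS, collapse = ", ")))
  }
  structure(list(matrix = matrix, frame_from = frame_from, frame_to = frame_to),
            class = "homogeneous_transform")
}

#' Identity transform between two frames
#' @param frame_from,frame_to frame labels.
#' @export
identity_transform <- function(frame_from, frame_to) {
  homogeneous_transform(diag(4), frame_from, frame_to)
}

#' Rigid (rotation + translation) transform
#'
#' Rigid specialization with unit scale: `rotation` must be orthonormal with
#' determinant +1, `translation` is in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- base::as.matrix(rotation)
  storage.mode(rotation) <- "double"
  if (!identical(dim(rotation), c(3L, 3L)))
    .helixreg_error("helixreg_invalid_transform", "rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    .helixreg_error("helixreg_invalid_transform", "rotation is not orthonormal")
  if (det(rotation) < 0)
    .helixreg_error("helixreg_reflection", "rotation has determinant -1 (reflection)")
  translation <- as.numeric(translation)
  if (length(translation) != 3L)
    .helixreg_error("helixreg_invalid_transform", "translation must have length 3")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Promote a rigid transform to a homogeneous transform
#' @param x a `rigid_transform`.
#' @param frame_from,frame_to frame labels for the result.
#' @export
as_homogeneous <- function(x, frame_from, frame_to) {
  stopifnot(inherits(x, "rigid_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  homogeneous_transform(m, frame_from, frame_to)
}

#' Compose two transforms
#'
#' `compose(a, b)` applies `b` first, then `a`; the frames must chain
#' (`a$frame_from == b$frame_to`) and the result maps `b$frame_from` to
#' `a$frame_to`.
#'
#' @param a,b `homogeneous_transform` objects.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "homogeneous_transform"), inherits(b, "homogeneous_transform"))
  if (!identical(a$frame_from, b$frame_to))
    .helixreg_error("helixreg_frame_mismatch",
                    sprintf("cannot chain %s->%s after %s->%s",
                            b$frame_from, b$frame_to, a$frame_from, a$frame_to))
  homogeneous_transform(a$matrix %*% b$matrix, b$frame_from, a$frame_to)
}

#' Invert a transform
#' @param t a `homogeneous_transform`.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "homogeneous_transform"))
  m <- tryCatch(solve(t$matrix),
                error = function(e) .helixreg_error("helixreg_degenerate_transform",
                                                    "transform matrix is singular"))
  homogeneous_transform(m, frame_from = t$frame_to, frame_to = t$frame_from)
}

#' Apply a transform to points
#'
#' @param t a `homogeneous_transform`.
#' @param p length-3 point or n x 3 matrix of points (mm) in `t$frame_from`.
#' @return points in `t$frame_to`, same shape as input.
#' @export
apply_point <- function(t, p) {
  stopifnot(inherits(t, "homogeneous_transform"))
  single <- is.null(dim(p))
  pm <- if (single) matrix(as.numeric(p), nrow = 1L) else base::as.matrix(p)
  if (ncol(pm) != 3L)
    .helixreg_error("helixreg_invalid_point", "points must have 3 coordinates")
  out <- pm %*% t(t$matrix[1:3, 1:3]) +
    matrix(t$matrix[1:3, 4], nrow(pm), 3, byrow = TRUE)
  if (single) drop(out) else out
}

#' Project an affine transform onto the rigid group
#'
#' Replaces the upper-left 3x3 block by its orthonormal polar factor (the
#' nearest rotation in the Frobenius sense, via SVD) and copies the
#' translation. Used to regularize the affine least-squares estimate before
#' rigid refinement, since a physical robot motion cannot realize scale.
#'
#' @param t a `homogeneous_transform`.
#' @return a `rigid_transform`.
#' @export
project_to_rigid <- function(t) {
  stopifnot(inherits(t, "homogeneous_transform"))
  A <- t$matrix[1:3, 1:3]
  if (det(A) <= 0)
    .helixreg_error("helixreg_reflection",
                    "linear block has non-positive determinant; cannot project to a rotation")
  s <- svd(A)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { # cannot occur when det(A) > 0, kept as a guard
    s$u[, 3] <- -s$u[, 3]
    R <- s$u %*% t(s$v)
  }
  rigid_transform(R, t$matrix[1:3, 4])
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) return(diag(3))
  k <- axis / n
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

.rotvec_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-15) return(diag(3))
  rotation_about_axis(rvec, theta)
}

#' Angle between two rotations
#' @param r1,r2 3x3 rotation matrices.
#' @return geodesic angle in degrees.
#' @export
rotation_angle_deg <- function(r1, r2 = diag(3)) {
  ctheta <- (sum(diag(crossprod(r1, r2))) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Robot-to-CBCT transform from the registration chain
#'
#' Composes `Tr2c = Tp2c * Te2p * Tr2e(Reg)`: the robot pose held during
#' registration, the fixed phantom-mount calibration and the estimated
#' phantom-to-CBCT transform.
#'
#' @param tp2c phantom-to-CBCT transform (p -> c).
#' @param te2p tool-to-phantom calibration (e -> p).
#' @param tr2e_reg robot pose during registration (r -> e).
#' @return the robot-base-to-CBCT transform (r -> c).
#' @export
robot_to_cbct <- function(tp2c, te2p, tr2e_reg) {
  compose(compose(tp2c, te2p), tr2e_reg)
}

#' Targeting plan: CBCT target point and transducer orientation
#'
#' @param target length-3 target location in CBCT coordinates (mm).
#' @param transducer_orientation 3x3 rotation giving the desired
#'   transducer-to-CBCT orientation (angular tilt for the energy pathway);
#'   defaults to identity (no tilt).
#' @export
target_plan <- function(target, transducer_orientation = diag(3)) {
  target <- as.numeric(target)
  if (length(target) != 3L)
    .helixreg_error("helixreg_invalid_point", "target must have 3 coordinates")
  Rm <- base::as.matrix(transducer_orientation)
  if (max(abs(crossprod(Rm) - diag(3))) > 1e-9 || det(Rm) < 0)
    .helixreg_error("helixreg_invalid_transform",
                    "transducer_orientation must be a proper rotation")
  structure(list(target = target, transducer_orientation = Rm),
            class = "target_plan")
}

#' Robot pose aligning the transducer focal point on a CBCT target
#'
#' Computes `Tr2e(Tx) = Te2h^-1 * [Rh2c | x]^-1 * Tr2c`: the robot pose that
#' places the transducer focal point (the origin of the transducer frame) at
#' the planned CBCT target `x` with the planned orientation. The induced
#' transducer-to-CBCT transform `Tr2c * Tr2e(Tx)^-1 * Te2h^-1` then equals
#' `[Rh2c | x]`.
#'
#' @param plan a `target_plan`.
#' @param te2h fixed tool-to-transducer calibration (e -> h).
#' @param tr2c registered robot-base-to-CBCT transform (r -> c).
#' @return the targeting robot pose (r -> e).
#' @export
targeting_pose <- function(plan, te2h, tr2c) {
  stopifnot(inherits(plan, "target_plan"))
  h2c <- diag(4)
  h2c[1:3, 1:3] <- plan$transducer_orientation
  h2c[1:3, 4] <- plan$target
  th2c <- homogeneous_transform(h2c, "h", "c")
  compose(compose(invert(te2h), invert(th2c)), tr2c)
}

#' @export
print.homogeneous_transform <- function(x, ...) {
  cat(sprintf("Homogeneous transform %s -> %s\n", x$frame_from, x$frame_to))
  print(round(x$matrix, 6))
  invisible(x)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform; rotation angle",
      sprintf("%.4f deg,", rotation_angle_deg(x$rotation)),
      "translation [", paste(sprintf("%.4f", x$translation), collapse = ", "),
      "] mm\n")
  invisible(x)
}

#' Read a transform from JSON
#'
#' Expects `{"frame_from": ..., "frame_to": ..., "matrix": [[...], ...]}` with
#' the matrix stored row-major as four rows of four.
#'
#' @param path JSON file path.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(x$matrix) || is.null(x$frame_from) || is.null(x$frame_to))
    .helixreg_error("helixreg_format_error",
                    "transform JSON needs fields frame_from, frame_to, matrix")
  homogeneous_transform(x$matrix, x$frame_from, x$frame_to)
}

#' Write a transform to JSON
#' @param t a `homogeneous_transform`.
#' @param path output file path.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "homogeneous_transform"))
  jsonlite::write_json(
    list(frame_from = t$frame_from, frame_to = t$frame_to,
         matrix = unname(t$matrix)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
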