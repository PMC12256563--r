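# Digital model of the helical fiducial phantom and its FOV / uniqueness
# analyses.

#' Shipped large-fiducial helix positions
#'
#' The physical phantom's large/small arrangement is fixed but the exact
#' assignment is part of its (unpublished) digital model. The pattern shipped
#' here is a reconstruction chosen by deterministic search subject to the
#' documented constraints: (a) any contiguous run of 4 large fiducials (in
#' either helix orientation) identifies itself uniquely with a 0.5 mm
#' ambiguity margin, runs of 3 do not; (b) exactly one large fiducial sits
#' among the two outermost helix positions at each end, so a centered
#' (16 cm)^3 FOV truncates one large and one small fiducial per end.
#'
#' @return integer vector of 1-based helix positions carrying 3 mm fiducials.
#' @export
default_large_indices <- function() c(1L, 3L, 6L, 11L, 15L, 18L, 24L, 25L, 29L, 31L)

#' Helical fiducial phantom geometry
#'
#' Defaults describe the PVC registration phantom: a 10.8 cm diameter,
#' 25.7 cm long cylinder with 32 stainless-steel fiducials (22 small, 1.5 mm;
#' 10 large, 3 mm) placed 3.2 cm apart (arc length) along a helical path of
#' 6.2 cm pitch on the cylinder surface.
#'
#' @param cylinder_diameter,cylinder_length cylinder dimensions (mm).
#' @param helix_pitch axial advance per full helix turn (mm).
#' @param fiducial_spacing_along_helix arc length between consecutive
#'   fiducials (mm).
#' @param n_small,n_large fiducial counts by size class.
#' @param small_diameter,large_diameter fiducial diameters (mm).
#' @param large_indices helix positions (1-based) carrying large fiducials.
#' @export
phantom_geometry <- function(cylinder_diameter = 108,
                             cylinder_length = 257,
                             helix_pitch = 62,
                             fiducial_spacing_along_helix = 32,
                             n_small = 22L,
                             small_diameter = 1.5,
                             n_large = 10L,
                             large_diameter = 3.0,
                             large_indices = default_large_indices()) {
  n <- n_small + n_large
  large_indices <- sort(as.integer(large_indices))
  if (length(large_indices) != n_large ||
      any(large_indices < 1L | large_indices > n) ||
      anyDuplicated(large_indices))
    .helixreg_error("helixreg_geometry_error",
                    "large_indices must be n_large distinct positions in [1, n_small+n_large]")
  g <- list(cylinder_diameter = cylinder_diameter,
            cylinder_length = cylinder_length,
            helix_pitch = helix_pitch,
            fiducial_spacing_along_helix = fiducial_spacing_along_helix,
            n_small = as.integer(n_small), small_diameter = small_diameter,
            n_large = as.integer(n_large), large_diameter = large_diameter,
            large_indices = large_indices)
  span <- (n - 1) * .axial_advance(g)
  if (span > cylinder_length)
    .helixreg_error("helixreg_geometry_error",
                    sprintf("helix axial span %.1f mm exceeds cylinder length %.1f mm",
                            span, cylinder_length))
  structure(g, class = "phantom_geometry")
}

# axial advance per fiducial: arc spacing s along a helix of radius R and
# pitch P advances z by s * P / sqrt((2 pi R)^2 + P^2)
.axial_advance <- function(g) {
  R <- g$cylinder_diameter / 2
  g$fiducial_spacing_along_helix * g$helix_pitch /
    sqrt((2 * pi * R)^2 + g$helix_pitch^2)
}

.angular_advance <- function(g) {
  R <- g$cylinder_diameter / 2
  g$fiducial_spacing_along_helix * 2 * pi /
    sqrt((2 * pi * R)^2 + g$helix_pitch^2)
}

#' Generate the digital phantom model
#'
#' Places the fiducial centers on the cylinder surface along the helix, with
#' the helix centered axially on the phantom origin, local Z along the
#' cylinder axis and phase 0 at local +X. Deterministic: identical geometry
#' gives bitwise-identical centers.
#'
#' @param geometry a `phantom_geometry`.
#' @return data frame with columns `index`, `x`, `y`, `z` (phantom mm),
#'   `diameter` (mm), `size_class` (`"small"`/`"large"`).
#' @export
generate_model <- function(geometry = phantom_geometry()) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  g <- geometry
  n <- g$n_small + g$n_large
  R <- g$cylinder_diameter / 2
  dz <- .axial_advance(g)
  dphi <- .angular_advance(g)
  i <- seq_len(n)
  phi <- (i - 1) * dphi
  z <- (i - (n + 1) / 2) * dz
  large <- i %in% g$large_indices
  data.frame(index = i,
             x = R * cos(phi), y = R * sin(phi), z = z,
             diameter = ifelse(large, g$large_diameter, g$small_diameter),
             size_class = ifelse(large, "large", "small"),
             stringsAsFactors = FALSE)
}

#' Fiducial visibility inside a cubic FOV
#'
#' A fiducial is visible iff its entire sphere lies inside the axis-aligned
#' cube of side `fov_side` centered at the CBCT origin, after mapping the
#' phantom through `phantom_pose`.
#'
#' @param model model data frame from [generate_model()].
#' @param fov_side side of the cubic field of view (mm).
#' @param phantom_pose phantom-to-CBCT transform (p -> c); defaults to the
#'   centered pose with the cylinder axis on the gantry rotational axis.
#' @return list with `n_visible`, `n_large`, `n_small`, `visible_indices`
#'   and the per-fiducial logical vector `visible`.
#' @export
fiducials_in_fov <- function(model, fov_side,
                             phantom_pose = identity_transform("p", "c")) {
  stopifnot(fov_side > 0)
  pts <- apply_point(phantom_pose, base::as.matrix(model[, c("x", "y", "z")]))
  half <- fov_side / 2
  r <- model$diameter / 2
  visible <- apply(abs(pts) + r <= half, 1, all)
  list(n_visible = sum(visible),
       n_large = sum(visible & model$size_class == "large"),
       n_small = sum(visible & model$size_class == "small"),
       visible_indices = model$index[visible],
       visible = visible)
}

#' Minimum number of large fiducials for unique self-identification
#'
#' Exhaustively enumerates every contiguous run of `m` large fiducials along
#' the helix, in forward and reversed orientation, and returns the smallest
#' `m` for which the distance-pattern correspondence matches every run member
#' to its true model position uniquely (ambiguity margin `margin`) and
#' injectively. Truncation by a FOV removes fiducials from the helix ends,
#' so detectable large subsets are exactly these contiguous runs.
#'
#' @param model model data frame from [generate_model()].
#' @param margin ambiguity margin (mm) required between best and second-best
#'   correspondence cost.
#' @return smallest sufficient run length (integer).
#' @export
min_unique_large_count <- function(model, margin = 0.5) {
  large <- model[model$size_class == "large", , drop = FALSE]
  nl <- nrow(large)
  if (nl < 2L)
    .helixreg_error("helixreg_pattern_error", "model needs at least 2 large fiducials")
  mpts <- base::as.matrix(large[, c("x", "y", "z")])
  for (m in 2:nl) {
    ok <- TRUE
    for (t0 in seq_len(nl - m + 1L)) {
      idx <- t0:(t0 + m - 1L)
      for (run in list(idx, rev(idx))) {
        res <- .match_distance_pattern(mpts[run, , drop = FALSE], mpts, margin)
        if (!res$ok || !identical(res$assignment, run)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(m)
  }
  .helixreg_error("helixreg_pattern_error",
                  "no run length up to n_large identifies the pattern uniquely")
}

#' Export a phantom model as CSV
#' @param model model data frame.
#' @param path output path.
#' @export
write_model_csv <- function(model, path) {
  utils::write.csv(model, path, row.names = FALSE)
  invisible(path)
}

#' Export a phantom model as JSON
#' @param model model data frame.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model, path, digits = NA)
  invisible(path)
}

#' Read phantom geometry from a JSON config
#'
#' Accepts a JSON object whose keys are [phantom_geometry()] arguments;
#' missing keys take the defaults, unknown keys are an error.
#'
#' @param path JSON file path.
#' @export
read_phantom_geometry <- function(path) {
  x <- jsonlite::fromJSON(path)
  known <- names(formals(phantom_geometry))
  bad <- setdiff(names(x), known)
  if (length(bad))
    .helixreg_error("helixreg_format_error",
                    paste("unknown phantom geometry keys:", paste(bad, collapse = ", ")))
  do.call(phantom_geometry, x)
}
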