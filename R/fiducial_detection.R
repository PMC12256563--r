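# Fiducial segmentation from CBCT volumes: global percentile threshold,
# connected-component analysis, geometric centroids, equivalent diameters,
# and the small/large size split.

#' Threshold specification for fiducial segmentation
#'
#' In `fixed-percentile` mode the threshold is the stated percentile of all
#' voxel intensities (99.99 by default, chosen to pass roughly the number of
#' voxels the phantom's fiducials occupy). In `expected-volume` mode the
#' percentile is derived from the phantom model itself:
#' `100 * (1 - expected fiducial voxels / total voxels)`, with the expected
#' voxel count summed over the fiducial spheres visible in the FOV.
#'
#' @param percentile percentile in (0, 100).
#' @param mode `"fixed-percentile"` or `"expected-volume"`.
#' @export
threshold_spec <- function(percentile = 99.99,
                           mode = c("fixed-percentile", "expected-volume")) {
  mode <- match.arg(mode)
  if (percentile <= 0 || percentile >= 100)
    .helixreg_error("helixreg_config_error", "percentile must be in (0, 100)")
  structure(list(percentile = percentile, mode = mode), class = "threshold_spec")
}

# nearest-rank (ceiling) percentile, avoiding interpolation dialects
.nearest_rank <- function(x, percentile) {
  n <- length(x)
  sort(x, method = "quick")[max(1L, min(n, ceiling(n * percentile / 100)))]
}

#' Percentile implied by the expected fiducial volume
#'
#' `100 * (1 - expected fiducial voxels / total voxels)`, where the expected
#' voxel count sums the sphere volumes of the fiducials visible in the cubic
#' FOV spanned by the volume. This is how the segmentation percentile is
#' calibrated to the phantom: the threshold should pass roughly as many
#' voxels as the fiducials occupy.
#'
#' @param dims length-3 voxel counts.
#' @param spacing length-3 voxel size (mm).
#' @param model phantom model data frame.
#' @param phantom_pose pose used for the visibility count (p -> c).
#' @export
expected_volume_percentile <- function(dims, spacing, model,
                                       phantom_pose = identity_transform("p", "c")) {
  fov <- min(dims * spacing)
  vis <- fiducials_in_fov(model, fov, phantom_pose)
  sphere_vol <- 4 / 3 * pi * (model$diameter[vis$visible] / 2)^3
  expected <- sum(sphere_vol) / prod(spacing)
  100 * (1 - expected / prod(dims))
}

#' Global segmentation threshold for a CBCT volume
#'
#' @param v a `voxel_volume`.
#' @param spec a `threshold_spec`.
#' @param model phantom model data frame; required for `expected-volume`
#'   mode, where visibility is evaluated for the volume's own cubic extent
#'   with the phantom at the nominal centered pose unless `phantom_pose`
#'   says otherwise.
#' @param phantom_pose pose used for the expected-volume visibility count.
#' @return the scalar threshold tau.
#' @export
compute_threshold <- function(v, spec = threshold_spec(), model = NULL,
                              phantom_pose = identity_transform("p", "c")) {
  stopifnot(inherits(v, "voxel_volume"), inherits(spec, "threshold_spec"))
  if (length(v$data) == 0L)
    .helixreg_error("helixreg_invalid_volume", "empty volume")
  pct <- spec$percentile
  if (spec$mode == "expected-volume") {
    if (is.null(model))
      .helixreg_error("helixreg_config_error",
                      "expected-volume mode requires the phantom model")
    pct <- expected_volume_percentile(dim(v$data), v$spacing, model, phantom_pose)
  }
  .nearest_rank(as.numeric(v$data), pct)
}

#' Extract fiducials from a thresholded CBCT volume
#'
#' Components of the mask `data > tau` under 26-connectivity become detected
#' fiducials; components smaller than `min_voxels` are treated as noise, and
#' components touching the volume border (fiducials truncated by the FOV)
#' are discarded. The centroid is the unweighted mean of member-voxel world
#' positions; the equivalent diameter is that of the sphere with the
#' component's volume.
#'
#' @param v a `voxel_volume`.
#' @param tau scalar threshold (strict `>` mask).
#' @param min_voxels minimum component size in voxels.
#' @param exclude_border drop components touching the volume border.
#' @return data frame with columns `x`, `y`, `z` (mm), `equivalent_diameter`
#'   (mm), `voxel_count` and `size_class` (`NA` until [classify_sizes()]).
#' @export
extract_fiducials <- function(v, tau, min_voxels = 4L, exclude_border = TRUE) {
  stopifnot(inherits(v, "voxel_volume"))
  mask <- v$data > tau
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      equivalent_diameter = numeric(0),
                      voxel_count = integer(0), size_class = character(0),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  lab <- label_components(mask, 26)
  n <- attr(lab, "n")
  d <- dim(v$data)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  i0 <- (idx - 1L) %% d[1]
  j0 <- ((idx - 1L) %/% d[1]) %% d[2]
  k0 <- (idx - 1L) %/% (d[1] * d[2])
  counts <- tabulate(labs, nbins = n)
  on_border <- i0 == 0L | i0 == d[1] - 1L | j0 == 0L | j0 == d[2] - 1L |
    k0 == 0L | k0 == d[3] - 1L
  border_labs <- unique(labs[on_border])
  keep <- which(counts >= min_voxels & !(seq_len(n) %in% border_labs))
  if (!length(keep)) return(empty)
  wx <- v$origin[1] + i0 * v$spacing[1]
  wy <- v$origin[2] + j0 * v$spacing[2]
  wz <- v$origin[3] + k0 * v$spacing[3]
  cx <- vapply(keep, function(l) mean(wx[labs == l]), 0)
  cy <- vapply(keep, function(l) mean(wy[labs == l]), 0)
  cz <- vapply(keep, function(l) mean(wz[labs == l]), 0)
  voxvol <- prod(v$spacing)
  eqd <- (6 * counts[keep] * voxvol / pi)^(1 / 3)
  out <- data.frame(x = cx, y = cy, z = cz, equivalent_diameter = eqd,
                    voxel_count = counts[keep],
                    size_class = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(out$z, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify detected fiducials by equivalent diameter
#'
#' @param fiducials data frame from [extract_fiducials()].
#' @param split size split (mm); equivalent diameter >= `split` is `large`
#'   (the boundary value counts as large).
#' @export
classify_sizes <- function(fiducials, split = 2.25) {
  if (nrow(fiducials) == 0L) return(fiducials)
  fiducials$size_class <- ifelse(fiducials$equivalent_diameter >= split,
                                 "large", "small")
  fiducials
}
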