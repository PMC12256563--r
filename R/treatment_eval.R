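# Treatment-zone segmentation from post-treatment CBCT volumes of the
# layered agar phantom, and directional / Euclidean targeting errors (TRE).

#' Post-processing for treatment-zone segmentations
#'
#' Keeps only the largest connected component, smooths with a binary median
#' filter, then closes and fills interior holes; the median and
#' closing/hole-fill kernels are `kernel_mm` (converted to whole voxels per
#' axis).
#'
#' @param mask 3D logical array.
#' @param spacing length-3 voxel spacing (mm).
#' @param kernel_mm filter kernel size (mm).
#' @export
postprocess_mask <- function(mask, spacing, kernel_mm = 1) {
  if (!any(mask)) return(mask)
  r <- .kernel_radius_vox(kernel_mm, spacing)
  out <- largest_component(mask, 26)
  out <- median_filter_mask(out, r)
  out <- close_mask(out, r)
  fill_holes(out)
}

#' Segment the homogenized treatment zone
#'
#' Seeded region growing from `seed_point`: neighbors (6-connectivity) are
#' added while their intensity is within `tolerance` of the running mean
#' intensity of the region grown so far. The grown region is then cleaned
#' with [postprocess_mask()] (largest component, median smoothing, 1 mm
#' closing/hole-fill), mirroring how semi-automatic treatment segmentations
#' are post-processed.
#'
#' @param post post-treatment `voxel_volume`.
#' @param seed_point length-3 seed location in CBCT mm (inside the zone).
#' @param tolerance intensity tolerance around the running region mean.
#' @param kernel_mm post-processing kernel (mm).
#' @return a `voxel_volume` whose data is the logical zone mask.
#' @export
segment_treatment_zone <- function(post, seed_point, tolerance = 150,
                                   kernel_mm = 1) {
  stopifnot(inherits(post, "voxel_volume"))
  d <- dim(post$data)
  seed <- world_to_voxel(post, seed_point) + 1L   # 1-based
  if (any(seed < 1L) || any(seed > d))
    .helixreg_error("helixreg_out_of_bounds", "seed point outside the volume")
  data <- post$data
  lin <- function(i, j, k) i + d[1] * ((j - 1L) + d[2] * (k - 1L))
  mask <- array(FALSE, d)
  queue <- integer(2048); qh <- 1L; qt <- 0L
  push <- function(v) {
    qt <<- qt + 1L
    if (qt > length(queue)) queue <<- c(queue, integer(length(queue)))
    queue[qt] <<- v
  }
  s <- lin(seed[1], seed[2], seed[3])
  mask[s] <- TRUE
  push(s)
  total <- data[s]; count <- 1L
  nxy <- d[1] * d[2]
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    i <- (v - 1L) %% d[1] + 1L
    j <- ((v - 1L) %/% d[1]) %% d[2] + 1L
    k <- (v - 1L) %/% nxy + 1L
    for (nb in list(c(i - 1L, j, k), c(i + 1L, j, k), c(i, j - 1L, k),
                    c(i, j + 1L, k), c(i, j, k - 1L), c(i, j, k + 1L))) {
      if (nb[1] < 1L || nb[1] > d[1] || nb[2] < 1L || nb[2] > d[2] ||
          nb[3] < 1L || nb[3] > d[3]) next
      w <- lin(nb[1], nb[2], nb[3])
      if (mask[w]) next
      if (abs(data[w] - total / count) <= tolerance) {
        mask[w] <- TRUE
        total <- total + data[w]; count <- count + 1L
        push(w)
      }
    }
  }
  if (count <= 1L)
    .helixreg_error("helixreg_segmentation_failure",
                    "region growing found no voxels beyond the seed")
  out <- postprocess_mask(mask, post$spacing, kernel_mm)
  if (!any(out))
    .helixreg_error("helixreg_segmentation_failure",
                    "segmentation empty after post-processing")
  voxel_volume(out, post$spacing, post$origin, post$frame)
}

#' Directional and Euclidean targeting errors
#'
#' The observed treatment centroid is the unweighted centroid of the mask
#' voxels in world mm; the directional error is observed minus planned on
#' the CBCT axes (-Z points toward the transducer), and the TRE is its
#' Euclidean norm.
#'
#' @param mask a `voxel_volume` with logical data (from
#'   [segment_treatment_zone()]).
#' @param planned_target length-3 planned target in CBCT mm.
#' @return object of class `treatment_measurement` with `planned_target`,
#'   `observed_centroid`, `directional_error` and `tre` (mm).
#' @export
measure_targeting <- function(mask, planned_target) {
  stopifnot(inherits(mask, "voxel_volume"))
  idx <- which(mask$data != 0)
  if (!length(idx))
    .helixreg_error("helixreg_segmentation_failure", "empty treatment mask")
  d <- dim(mask$data)
  i0 <- (idx - 1L) %% d[1]
  j0 <- ((idx - 1L) %/% d[1]) %% d[2]
  k0 <- (idx - 1L) %/% (d[1] * d[2])
  centroid <- c(mean(i0) * mask$spacing[1] + mask$origin[1],
                mean(j0) * mask$spacing[2] + mask$origin[2],
                mean(k0) * mask$spacing[3] + mask$origin[3])
  planned_target <- as.numeric(planned_target)
  derr <- centroid - planned_target
  structure(list(planned_target = planned_target,
                 observed_centroid = centroid,
                 directional_error = derr,
                 tre = sqrt(sum(derr^2))),
            class = "treatment_measurement")
}

#' @export
print.treatment_measurement <- function(x, ...) {
  cat(sprintf("Targeting: TRE %.3f mm; directional error [%s] mm\n",
              x$tre, paste(sprintf("%.3f", x$directional_error), collapse = ", ")))
  invisible(x)
}
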