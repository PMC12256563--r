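# Synthetic CBCT rendering: the helical fiducial phantom as bright spheres
# with supersampled partial-volume edges on a noisy background, and the
# multi-layered agar treatment phantom with a homogenized treatment zone.
# These emulate the experimental CBCT inputs with known ground truth; they do
# not model projection physics (scatter, beam hardening, streaks).

#' Rendering configuration for synthetic CBCT volumes
#'
#' @param fov_side cubic field-of-view side (mm); `fov_side / voxel_size`
#'   must be an integer.
#' @param voxel_size isotropic voxel size (mm).
#' @param fiducial_intensity intensity added at full sphere coverage
#'   (arbitrary attenuation units).
#' @param background_intensity baseline intensity.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param supersampling per-axis subdivisions for partial-volume edge
#'   weighting.
#' @param seed RNG seed used for the noise; identical seeds give
#'   bitwise-identical volumes.
#' @export
render_config <- function(fov_side = 160, voxel_size = 0.5,
                          fiducial_intensity = 3000, background_intensity = 0,
                          noise_sigma = 10, supersampling = 3L, seed = 1L) {
  n <- fov_side / voxel_size
  if (abs(n - round(n)) > 1e-9)
    .helixreg_error("helixreg_config_error", "fov_side / voxel_size must be an integer")
  if (supersampling < 1L)
    .helixreg_error("helixreg_config_error", "supersampling must be >= 1")
  structure(list(fov_side = fov_side, voxel_size = voxel_size,
                 fiducial_intensity = fiducial_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 supersampling = as.integer(supersampling),
                 seed = as.integer(seed)),
            class = "render_config")
}

# fraction of each voxel (rows of `idx0`, 0-based) covered by the sphere,
# estimated on a supersampling^3 sub-grid of cell centers
.sphere_coverage <- function(centers_mm, center, radius, voxel_size, ss) {
  sub <- ((seq_len(ss) - (ss + 1) / 2) / ss) * voxel_size
  offs <- base::as.matrix(expand.grid(x = sub, y = sub, z = sub))
  cov <- numeric(nrow(centers_mm))
  for (o in seq_len(nrow(offs))) {
    p <- centers_mm + matrix(offs[o, ], nrow(centers_mm), 3, byrow = TRUE)
    dd <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 + (p[, 3] - center[3])^2
    cov <- cov + (dd <= radius^2)
  }
  cov / nrow(offs)
}

#' Render the fiducial phantom into a CBCT-like volume
#'
#' Each fiducial becomes a sphere of `fiducial_intensity` (with supersampled
#' partial-volume edges) at its pose-transformed center; spheres are
#' truncated exactly by the cubic FOV; Gaussian noise with the configured
#' seed is added last. The ground-truth table reports the true centroids in
#' CBCT mm and whether each sphere lies entirely inside the FOV.
#'
#' @param model model data frame from [generate_model()].
#' @param tp2c phantom-to-CBCT pose (p -> c).
#' @param cfg a `render_config`.
#' @return list with `volume` (a `voxel_volume`) and `truth` (data frame:
#'   `index`, `x`, `y`, `z`, `diameter`, `size_class`, `visible`).
#' @export
render_phantom_cbct <- function(model, tp2c = identity_transform("p", "c"),
                                cfg = render_config()) {
  stopifnot(inherits(cfg, "render_config"))
  n <- as.integer(round(cfg$fov_side / cfg$voxel_size))
  dims <- c(n, n, n)
  spacing <- rep(cfg$voxel_size, 3)
  origin <- centered_origin(dims, spacing)
  set.seed(cfg$seed)
  vol <- array(cfg$background_intensity, dims)
  centers <- apply_point(tp2c, base::as.matrix(model[, c("x", "y", "z")]))
  half <- cfg$fov_side / 2
  r <- model$diameter / 2
  visible <- apply(abs(centers) + r <= half, 1, all)
  for (f in seq_len(nrow(model))) {
    ctr <- centers[f, ]
    rad <- r[f]
    lo <- pmax(0L, as.integer(floor((ctr - rad - origin) / spacing)) - 1L)
    hi <- pmin(dims - 1L, as.integer(ceiling((ctr + rad - origin) / spacing)) + 1L)
    if (any(lo > hi)) next
    idx <- base::as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
    centers_mm <- idx * matrix(spacing, nrow(idx), 3, byrow = TRUE) +
      matrix(origin, nrow(idx), 3, byrow = TRUE)
    cov <- .sphere_coverage(centers_mm, ctr, rad, cfg$voxel_size, cfg$supersampling)
    nz <- cov > 0
    if (!any(nz)) next
    lin <- idx[nz, 1] + dims[1] * (idx[nz, 2] + dims[2] * idx[nz, 3]) + 1L
    vol[lin] <- vol[lin] + cfg$fiducial_intensity * cov[nz]
  }
  if (cfg$noise_sigma > 0)
    vol <- vol + array(stats::rnorm(prod(dims), 0, cfg$noise_sigma), dims)
  truth <- data.frame(index = model$index,
                      x = centers[, 1], y = centers[, 2], z = centers[, 3],
                      diameter = model$diameter, size_class = model$size_class,
                      visible = visible, stringsAsFactors = FALSE)
  list(volume = voxel_volume(vol, spacing, origin), truth = truth)
}

#' Multi-layered treatment phantom configuration
#'
#' Emulates the agar/barium layered phantom used to make histotripsy
#' treatments visible on CBCT: alternating agar (~3.5 mm) and agar-barium
#' (~1 mm) layers; after treatment the layers mix into an area of homogeneous
#' attenuation (the treatment zone), modeled as an ellipsoid at the mean
#' layer intensity.
#'
#' @param agar_layer_thickness,barium_layer_thickness layer thicknesses (mm).
#' @param layer_intensities intensities of the agar and barium layers.
#' @param zone_center ellipsoid center in CBCT mm.
#' @param zone_radii ellipsoid semi-axes (mm); a histotripsy bubble cloud is
#'   a few mm across, slightly elongated along the beam (Z) axis.
#' @param zone_intensity intensity inside the homogenized zone; defaults to
#'   the mean of the layer intensities.
#' @export
treatment_phantom_config <- function(agar_layer_thickness = 3.5,
                                     barium_layer_thickness = 1.0,
                                     layer_intensities = c(100, 800),
                                     zone_center = c(0, 0, 0),
                                     zone_radii = c(3, 3, 5),
                                     zone_intensity = mean(layer_intensities)) {
  if (agar_layer_thickness <= 0 || barium_layer_thickness <= 0)
    .helixreg_error("helixreg_config_error", "layer thicknesses must be positive")
  structure(list(agar_layer_thickness = agar_layer_thickness,
                 barium_layer_thickness = barium_layer_thickness,
                 layer_intensities = as.numeric(layer_intensities),
                 zone_center = as.numeric(zone_center),
                 zone_radii = as.numeric(zone_radii),
                 zone_intensity = zone_intensity),
            class = "treatment_phantom_config")
}

#' Render a pre-/post-treatment volume pair
#'
#' The pre-treatment volume has periodic layers along Z; the post-treatment
#' volume is identical (same noise realization) except that voxels whose
#' centers lie inside the ellipsoidal treatment zone are replaced by the
#' homogenized zone intensity.
#'
#' @param cfg a `treatment_phantom_config`.
#' @param render a `render_config` (the FOV/voxel/noise/seed settings).
#' @return list with `pre`, `post` (both `voxel_volume`) and `zone_centroid`
#'   (the true ellipsoid center, mm).
#' @export
render_treatment_pair <- function(cfg = treatment_phantom_config(),
                                  render = render_config()) {
  stopifnot(inherits(cfg, "treatment_phantom_config"),
            inherits(render, "render_config"))
  n <- as.integer(round(render$fov_side / render$voxel_size))
  dims <- c(n, n, n)
  spacing <- rep(render$voxel_size, 3)
  origin <- centered_origin(dims, spacing)
  half <- render$fov_side / 2
  if (any(abs(cfg$zone_center) + cfg$zone_radii > half))
    .helixreg_error("helixreg_config_error", "treatment zone does not fit inside the FOV")
  period <- cfg$agar_layer_thickness + cfg$barium_layer_thickness
  zw <- origin[3] + (0:(n - 1)) * spacing[3]          # voxel-center world Z
  phase <- (zw + half) %% period
  layer <- ifelse(phase < cfg$agar_layer_thickness,
                  cfg$layer_intensities[1], cfg$layer_intensities[2])
  pre <- array(rep(layer, each = n * n), dims)
  set.seed(render$seed)
  if (render$noise_sigma > 0)
    pre <- pre + array(stats::rnorm(prod(dims), 0, render$noise_sigma), dims)
  post <- pre
  if (all(cfg$zone_radii > 0)) {
    xs <- origin[1] + (0:(n - 1)) * spacing[1]
    u2 <- ((xs - cfg$zone_center[1]) / cfg$zone_radii[1])^2
    v2 <- ((xs - cfg$zone_center[2]) / cfg$zone_radii[2])^2
    w2 <- ((zw - cfg$zone_center[3]) / cfg$zone_radii[3])^2
    inside <- outer(outer(u2, v2, "+"), w2, "+") < 1
    post[inside] <- cfg$zone_intensity
    if (render$noise_sigma > 0)
      post[inside] <- post[inside] + stats::rnorm(sum(inside), 0, render$noise_sigma)
  }
  list(pre = voxel_volume(pre, spacing, origin),
       post = voxel_volume(post, spacing, origin),
       zone_centroid = cfg$zone_center)
}
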