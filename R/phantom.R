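#' Closed-form solid volumes
#'
#' @param radius Radius in mm (> 0).
#' @param length Cylinder length in mm (> 0).
#' @return Volume in mm^3.
#' @examples
#' sphere_volume(1)        # 4.18879
#' cylinder_volume(0.5, 1) # 0.78540
#' @export
sphere_volume <- function(radius) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop_murinod("value", "`radius` must be > 0.")
  4 / 3 * pi * radius^3
}

#' @rdname sphere_volume
#' @export
cylinder_volume <- function(radius, length) {
  if (any(!is.finite(radius)) || any(radius <= 0) ||
      any(!is.finite(length)) || any(length <= 0))
    stop_murinod("value", "`radius` and `length` must be > 0.")
  pi * radius^2 * length
}

#' Declarative thorax-phantom geometry
#'
#' Describes a synthetic micro-CT thorax: a soft-tissue body cylinder (axis
#' along z) enclosing a lung cavity of low-density parenchyma, an optional
#' flat diaphragm slab, tubular vessels, spherical nodules, calibration
#' inserts outside the body, and additive Gaussian noise.  All geometry is
#' in mm; densities in HU.  Defaults emulate a 50 um isotropic mouse
#' thorax scan: parenchyma -400 HU, soft tissue +50 HU, air -1000 HU,
#' bone +2600 HU, noise SD 60 HU.
#'
#' @param grid_shape Integer length-3 voxel counts.
#' @param spacing Voxel spacing in mm (default 0.05 isotropic).
#' @param parenchyma_hu,soft_tissue_hu,air_hu,bone_hu Tissue densities (HU).
#' @param noise_sd Additive Gaussian noise SD (HU).
#' @param body_center_xy Body cylinder axis position (mm), default grid centre.
#' @param body_radius Outer body radius (mm).
#' @param wall_thickness Chest-wall thickness (mm).
#' @param diaphragm_z If not `NULL`, lung voxels with z <= this value (mm)
#'   are soft tissue — a flat wall analog used for juxtapleural and
#'   two-attachment geometries.
#' @param nodules Tibble with columns `x, y, z, radius, density, placement`
#'   (placement one of `isolated`, `juxtapleural`, `vessel_attached`,
#'   `two_attachments`); see [phantom_nodule()].
#' @param vessels Tibble with columns `x1, y1, z1, x2, y2, z2, radius,
#'   density` describing tubular segments.
#' @param inserts Tibble with columns `x, y, z, radius, density`:
#'   spherical calibration inserts (air/water/bone analogs) placed in the
#'   exterior air.
#' @param seed Integer RNG seed for the noise field.
#' @return A list of class `phantom_spec`.
#' @seealso [build_thorax_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(160, 160, 128),
                         spacing = c(0.05, 0.05, 0.05),
                         parenchyma_hu = -400,
                         soft_tissue_hu = 50,
                         air_hu = -1000,
                         bone_hu = 2600,
                         noise_sd = 60,
                         body_center_xy = NULL,
                         body_radius = NULL,
                         wall_thickness = 0.5,
                         diaphragm_z = NULL,
                         nodules = NULL,
                         vessels = NULL,
                         inserts = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.double(spacing)
  extent <- grid_shape * spacing
  if (is.null(body_center_xy)) body_center_xy <- extent[1:2] / 2
  if (is.null(body_radius)) body_radius <- 0.45 * min(extent[1:2])
  if (is.null(nodules))
    nodules <- phantom_nodule(center = extent / 2, radius = 0.75)
  if (is.null(vessels))
    vessels <- tibble(x1 = double(), y1 = double(), z1 = double(),
                      x2 = double(), y2 = double(), z2 = double(),
                      radius = double(), density = double())
  if (is.null(inserts))
    inserts <- tibble(x = double(), y = double(), z = double(),
                      radius = double(), density = double())
  spec <- structure(list(
    grid_shape = grid_shape, spacing = spacing,
    parenchyma_hu = parenchyma_hu, soft_tissue_hu = soft_tissue_hu,
    air_hu = air_hu, bone_hu = bone_hu, noise_sd = noise_sd,
    body_center_xy = as.double(body_center_xy),
    body_radius = body_radius, wall_thickness = wall_thickness,
    diaphragm_z = diaphragm_z,
    nodules = nodules, vessels = vessels, inserts = inserts,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param center Nodule centre (mm), length 3.
#' @param radius Nodule radius (mm).
#' @param density Nodule density (HU).
#' @param placement Placement label (documentation of intent; geometry is
#'   what the coordinates say).
#' @export
phantom_nodule <- function(center, radius, density = 50,
                           placement = c("isolated", "juxtapleural",
                                         "vessel_attached", "two_attachments")) {
  placement <- match.arg(placement)
  tibble(x = center[1], y = center[2], z = center[3],
         radius = radius, density = density, placement = placement)
}

validate_phantom_spec <- function(spec) {
  extent <- spec$grid_shape * spec$spacing
  nd <- spec$nodules
  if (nrow(nd)) {
    if (any(nd$radius <= 0))
      stop_murinod("geometry", "Nodule radii must be > 0.")
    if (any(nd$density <= spec$parenchyma_hu))
      stop_murinod("geometry", "Nodule density must exceed parenchyma density.")
    lo <- cbind(nd$x, nd$y, nd$z) - nd$radius
    hi <- cbind(nd$x, nd$y, nd$z) + nd$radius
    if (any(lo < 0) || any(t(t(hi) > extent)))
      stop_murinod("geometry", "Nodule geometry extends outside the grid.")
    if (nrow(nd) > 1) {
      for (a in seq_len(nrow(nd) - 1)) for (b in seq(a + 1, nrow(nd))) {
        d <- sqrt((nd$x[a] - nd$x[b])^2 + (nd$y[a] - nd$y[b])^2 +
                  (nd$z[a] - nd$z[b])^2)
        if (d < nd$radius[a] + nd$radius[b])
          stop_murinod("geometry", sprintf("Nodules %d and %d overlap.", a, b))
      }
    }
  }
  ins <- spec$inserts
  if (nrow(ins)) {
    lo <- cbind(ins$x, ins$y, ins$z) - ins$radius
    hi <- cbind(ins$x, ins$y, ins$z) + ins$radius
    if (any(lo < 0) || any(t(t(hi) > extent)))
      stop_murinod("geometry", "Insert geometry extends outside the grid.")
  }
  invisible(spec)
}

#' Build a synthetic thorax phantom with ground truth
#'
#' Voxelises a [phantom_spec] into a calibrated HU volume together with
#' exact per-nodule truth masks, a lung (parenchyma) mask, and both
#' analytic and voxel-counting nodule volumes.  A voxel belongs to a solid
#' iff its centre lies inside the analytic surface, so voxelisation is
#' deterministic and resolution-consistent.  The noise field is
#' reproducible from `spec$seed`.
#'
#' Nodule truth masks are the part of each sphere inside the lung cavity
#' (wall and diaphragm overlap excluded), and the analytic volumes
#' integrate the same geometry, so juxtapleural truth is a spherical cap.
#'
#' @param spec A [phantom_spec].
#' @return A list of class `thorax_phantom` with elements `image` (a
#'   [vol_image]), `truth` (list: `nodule_masks`, `lung_mask`,
#'   `analytic_volumes`, `voxel_volumes`), and `spec`.
#' @examples
#' ph <- build_thorax_phantom(phantom_spec(grid_shape = c(64, 64, 48),
#'                                         noise_sd = 0,
#'                                         nodules = phantom_nodule(c(1.6, 1.6, 1.2), 0.4)))
#' ph$truth$analytic_volumes
#' @export
build_thorax_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  sp <- spec$spacing
  # voxel-centre coordinates (origin at 0: centre of voxel i is (i + 0.5) h)
  xs <- (seq_len(dm[1]) - 0.5) * sp[1]
  ys <- (seq_len(dm[2]) - 0.5) * sp[2]
  zs <- (seq_len(dm[3]) - 0.5) * sp[3]
  X <- array(xs, dm)
  Y <- array(rep(ys, each = dm[1]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)

  cxy <- spec$body_center_xy
  r2_xy <- (X - cxy[1])^2 + (Y - cxy[2])^2
  body <- r2_xy <= spec$body_radius^2
  lung_r <- spec$body_radius - spec$wall_thickness
  cavity <- r2_xy <= lung_r^2
  lung <- cavity
  if (!is.null(spec$diaphragm_z)) lung <- lung & (Z > spec$diaphragm_z)

  data <- array(spec$air_hu, dm)
  data[body] <- spec$soft_tissue_hu
  data[lung] <- spec$parenchyma_hu

  vs <- spec$vessels
  for (v in seq_len(nrow(vs))) {
    seg <- capsule_mask(X, Y, Z, c(vs$x1[v], vs$y1[v], vs$z1[v]),
                        c(vs$x2[v], vs$y2[v], vs$z2[v]), vs$radius[v])
    data[seg] <- vs$density[v]
  }

  nd <- spec$nodules
  nodule_masks <- vector("list", nrow(nd))
  voxel_volumes <- analytic_volumes <- double(nrow(nd))
  voxvol <- prod(sp)
  for (i in seq_len(nrow(nd))) {
    sph <- (X - nd$x[i])^2 + (Y - nd$y[i])^2 + (Z - nd$z[i])^2 <= nd$radius[i]^2
    data[sph & body] <- nd$density[i]
    m <- sph & lung
    nodule_masks[[i]] <- m
    voxel_volumes[i] <- sum(m) * voxvol
    analytic_volumes[i] <- nodule_analytic_volume(spec, i)
  }

  ins <- spec$inserts
  for (i in seq_len(nrow(ins))) {
    sph <- (X - ins$x[i])^2 + (Y - ins$y[i])^2 + (Z - ins$z[i])^2 <= ins$radius[i]^2
    data[sph] <- ins$density[i]
  }

  lung_truth <- lung
  for (m in nodule_masks) lung_truth <- lung_truth & !m

  if (spec$noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(spec$seed)
    data <- data + array(rnorm(length(data), 0, spec$noise_sd), dm)
  }

  structure(list(
    image = vol_image(data, spacing = sp, origin = c(0, 0, 0) + sp / 2),
    truth = list(
      nodule_masks = nodule_masks,
      lung_mask = lung_truth,
      analytic_volumes = analytic_volumes,
      voxel_volumes = voxel_volumes
    ),
    spec = spec
  ), class = "thorax_phantom")
}

capsule_mask <- function(X, Y, Z, p1, p2, radius) {
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) return((X - p1[1])^2 + (Y - p1[2])^2 + (Z - p1[3])^2 <= radius^2)
  t <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2] + (Z - p1[3]) * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (X - (p1[1] + t * d[1]))^2 + (Y - (p1[2] + t * d[2]))^2 +
    (Z - (p1[3] + t * d[3]))^2 <= radius^2
}

# area of the intersection of two discs with radii R and r, centre distance d
circle_lens_area <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(pi * min(R, r)^2)
  r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r)) +
    R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R)) -
    0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
}

# geometric (grid-free) volume of nodule i intersected with the lung
# cavity: integrate the slicewise disc/lung-disc intersection over z,
# truncated at the diaphragm plane
nodule_analytic_volume <- function(spec, i) {
  nd <- spec$nodules[i, ]
  lung_r <- spec$body_radius - spec$wall_thickness
  d_axis <- sqrt(sum((c(nd$x, nd$y) - spec$body_center_xy)^2))
  z_lo <- nd$z - nd$radius
  z_hi <- nd$z + nd$radius
  if (!is.null(spec$diaphragm_z)) z_lo <- max(z_lo, spec$diaphragm_z)
  if (z_lo >= z_hi) return(0)
  slice_area <- function(z) {
    vapply(z, function(zz) {
      rho2 <- nd$radius^2 - (zz - nd$z)^2
      if (rho2 <= 0) return(0)
      circle_lens_area(lung_r, sqrt(rho2), d_axis)
    }, double(1))
  }
  integrate(slice_area, z_lo, z_hi, rel.tol = 1e-9,
            subdivisions = 500L)$value
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat("<thorax_phantom>\n")
  print(x$image)
  cat(sprintf("  %d nodule(s); analytic volumes (mm^3): %s\n",
              nrow(x$spec$nodules),
              paste(signif(x$truth$analytic_volumes, 5), collapse = ", ")))
  invisible(x)
}

#' Ground-truth summary of a phantom
#'
#' @param x A `thorax_phantom`.
#' @param ... Unused.
#' @return A tibble with one row per nodule: placement, radius, analytic
#'   and voxel-counting volumes, and their relative difference.
#' @export
tidy.thorax_phantom <- function(x, ...) {
  nd <- x$spec$nodules
  tibble(
    nodule = seq_len(nrow(nd)),
    placement = nd$placement,
    radius_mm = nd$radius,
    analytic_volume_mm3 = x$truth$analytic_volumes,
    voxel_volume_mm3 = x$truth$voxel_volumes,
    rel_diff = abs(x$truth$voxel_volumes - x$truth$analytic_volumes) /
      x$truth$analytic_volumes
  )
}

#' Write a phantom volume plus its truth manifest
#'
#' @param phantom A `thorax_phantom`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.  Writes `phantom.nii.gz`,
#'   `nodule_<i>_truth.nii.gz`, `lung_truth.nii.gz` and `truth.json`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "thorax_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- phantom$image
  write_volume(img, file.path(dir, "phantom.nii.gz"))
  for (i in seq_along(phantom$truth$nodule_masks)) {
    m <- phantom$truth$nodule_masks[[i]]
    write_volume(vol_image(array(as.integer(m), dim(m)), img$spacing, img$origin),
                 file.path(dir, sprintf("nodule_%d_truth.nii.gz", i)))
  }
  lm <- phantom$truth$lung_mask
  write_volume(vol_image(array(as.integer(lm), dim(lm)), img$spacing, img$origin),
               file.path(dir, "lung_truth.nii.gz"))
  manifest <- list(
    nodules = tidy(phantom),
    spacing_mm = img$spacing,
    grid_shape = dim(img$data),
    seed = phantom$spec$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
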