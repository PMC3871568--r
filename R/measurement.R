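#' Volume of a binary mask
#'
#' Exact voxel counting: volume = count x dx dy dz.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Volume in mm^3.
#' @examples
#' volume_from_mask(array(TRUE, c(20, 20, 20)), c(0.05, 0.05, 0.05))  # 1 mm^3
#' @export
volume_from_mask <- function(mask, spacing) {
  mask <- as_mask(mask)
  n <- sum(mask)
  if (n == 0L) stop_murinod("empty_mask", "The mask selects no voxels.")
  n * prod(as.double(spacing))
}

#' Volume-equivalent diameter
#'
#' Diameter of the sphere with the same volume: d = (6 V / pi)^(1/3).
#'
#' @param volume Volume(s) in mm^3 (> 0).
#' @return Diameter(s) in mm.
#' @examples
#' equivalent_diameter(pi / 6)    # 1
#' equivalent_diameter(4.18879)   # 2
#' @export
equivalent_diameter <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop_murinod("value", "`volume` must be > 0.")
  (6 * volume / pi)^(1 / 3)
}

#' Cylindrical bi-dimensional volume approximation
#'
#' The manual approximation used as a comparator for the semi-automated
#' algorithm: on every `step`-th slice through the tumor an observer draws
#' the longest in-plane extent and its perpendicular; their average is the
#' diameter of a cylinder spanning `step` slices, and the cylinder volumes
#' are summed:
#' `V = sum (pi/4) * ((a_i + b_i)/2)^2 * step * slice_thickness`.
#'
#' @param measurements Data frame with columns `slice_index`, `long_axis`,
#'   `perp_axis` (mm), one row per measured slice, slice indices strictly
#'   increasing.
#' @param slice_thickness Slice thickness in mm.
#' @param step Number of slices each measurement represents (default 5);
#'   each measured slice represents the slab `[slice, slice + step)`.
#' @return Approximate volume in mm^3.
#' @export
cylindrical_approximation <- function(measurements, slice_thickness, step = 5) {
  if (is.null(measurements) || nrow(measurements) == 0L)
    stop_murinod("empty_input", "No bi-dimensional measurements supplied.")
  req <- c("slice_index", "long_axis", "perp_axis")
  if (!all(req %in% names(measurements)))
    stop_murinod("value", paste("`measurements` needs columns:",
                                paste(req, collapse = ", ")))
  if (slice_thickness <= 0)
    stop_murinod("value", "`slice_thickness` must be > 0.")
  if (is.unsorted(measurements$slice_index, strictly = TRUE))
    stop_murinod("order", "Slice indices must be strictly increasing.")
  a <- measurements$long_axis
  b <- measurements$perp_axis
  if (any(a <= 0) || any(b <= 0) || any(b > a + 1e-12))
    stop_murinod("value", "Axes must satisfy long_axis >= perp_axis > 0.")
  sum(pi / 4 * ((a + b) / 2)^2 * step * slice_thickness)
}

#' Planimetric volume from manual contours
#'
#' Full manual 3D segmentation: the tumor boundary is outlined on every
#' slice and the volume is the sum of the polygon (shoelace) areas times
#' the slice thickness.
#'
#' @param contours_per_slice List of simple planar polygons, each an
#'   n x 2 matrix (or data frame) of vertex coordinates in mm, one per
#'   consecutive slice.
#' @param slice_thickness Slice thickness in mm.
#' @return Volume in mm^3.
#' @export
volume_from_contours <- function(contours_per_slice, slice_thickness) {
  if (length(contours_per_slice) == 0L)
    stop_murinod("empty_input", "No contours supplied.")
  if (slice_thickness <= 0)
    stop_murinod("value", "`slice_thickness` must be > 0.")
  areas <- vapply(contours_per_slice, function(poly) {
    poly <- as.matrix(poly)
    if (ncol(poly) != 2L || nrow(poly) < 3L)
      stop_murinod("geometry", "Each contour needs >= 3 (x, y) vertices.")
    if (polygon_self_intersects(poly))
      stop_murinod("geometry", "Contour polygon is self-intersecting.")
    shoelace_area(poly)
  }, double(1))
  sum(areas) * slice_thickness
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  segs <- cbind(poly, poly[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    last <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, last)) {
      if (segments_cross(segs[i, 1:2], segs[i, 3:4], segs[j, 1:2], segs[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Bi-dimensional axes of a mask slice
#'
#' Helper used in validation: the longest chord between in-plane mask
#' voxel centres and the maximum extent perpendicular to it.
#'
#' @param mask2d Logical matrix (one slice).
#' @param spacing2d In-plane spacing (mm), length 2.
#' @return A named numeric vector `c(long_axis, perp_axis)` in mm.
#' @keywords internal
#' @export
bidim_axes_from_slice <- function(mask2d, spacing2d) {
  idx <- which(mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_murinod("empty_mask", "Empty slice.")
  pts <- sweep(idx - 1, 2, spacing2d, `*`)
  d2 <- as.matrix(stats::dist(pts))
  w <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  long_axis <- max(d2)
  dir <- (pts[w[2], ] - pts[w[1], ])
  dir <- dir / sqrt(sum(dir^2))
  perp <- c(-dir[2], dir[1])
  proj <- pts %*% perp
  c(long_axis = long_axis, perp_axis = max(proj) - min(proj))
}

#' Tabulate tumor measurements
#'
#' Collects volumes from any of the three measurement methods into the
#' standard reporting row: volume and volume-equivalent diameter.
#'
#' @param volume_mm3 Volume(s) in mm^3.
#' @param method Measurement method label(s): `semi_automated`,
#'   `cylindrical_approx` or `full_manual_3d`.
#' @param tumor_id Optional identifier(s).
#' @return A tibble with columns `tumor_id`, `method`, `volume_mm3`,
#'   `equivalent_diameter_mm`.
#' @export
tumor_measurement <- function(volume_mm3,
                              method = c("semi_automated", "cylindrical_approx",
                                         "full_manual_3d"),
                              tumor_id = NA_character_) {
  method <- match.arg(method, several.ok = TRUE)
  tibble(
    tumor_id = tumor_id,
    method = method,
    volume_mm3 = volume_mm3,
    equivalent_diameter_mm = equivalent_diameter(volume_mm3)
  )
}
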