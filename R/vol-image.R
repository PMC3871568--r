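#' Volumetric micro-CT image
#'
#' `vol_image()` builds the package's universal carrier for calibrated CT
#' data: a 3D grid of densities in Hounsfield units (HU) together with the
#' voxel spacing and the physical position of the first voxel.  The physical
#' position of voxel index `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`, in millimetres.
#'
#' @param data Numeric 3D array of densities in HU.  Must be finite
#'   everywhere.
#' @param spacing Numeric length-3 vector, voxel edge lengths in mm
#'   (strictly positive).
#' @param origin Numeric length-3 vector, physical position (mm) of voxel
#'   `(0, 0, 0)`.
#'
#' @return An object of class `vol_image`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @examples
#' img <- vol_image(array(-400, c(10, 10, 10)), spacing = c(0.05, 0.05, 0.05))
#' dim(img)
#' voxel_volume(img)
#' @export
vol_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_murinod("value", "`data` must be a 3D array.")
  if (!all(is.finite(data)))
    stop_murinod("value", "`data` must be finite everywhere (no NA/NaN/Inf).")
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_murinod("value", "`spacing` must be three strictly positive values (mm).")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_murinod("value", "`origin` must be three finite values (mm).")
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "vol_image"
  )
}

#' @export
dim.vol_image <- function(x) dim(x$data)

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<vol_image> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    d[1], d[2], d[3],
    paste(signif(x$spacing, 4), collapse = " x "),
    paste(signif(x$origin, 4), collapse = ", ")
  ))
  cat(sprintf("  density range [%.1f, %.1f] HU\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname vol_image
#' @param img A `vol_image`.
#' @return `voxel_volume()`: the volume of one voxel in mm^3.
#' @export
voxel_volume <- function(img) {
  stopifnot(inherits(img, "vol_image"))
  prod(img$spacing)
}

#' Convert between world (mm) and voxel index coordinates
#'
#' Indices are 0-based, matching the grid convention `world = origin +
#' index * spacing`.  `world_to_index()` returns fractional (continuous)
#' indices; round to land on a voxel.
#'
#' @param img A [vol_image].
#' @param xyz Numeric length-3 world position (mm) or 0-based index.
#' @return A numeric length-3 vector.
#' @keywords internal
#' @export
world_to_index <- function(img, xyz) {
  (as.double(xyz) - img$origin) / img$spacing
}

#' @rdname world_to_index
#' @export
index_to_world <- function(img, xyz) {
  img$origin + as.double(xyz) * img$spacing
}

in_bounds <- function(img, idx) {
  all(idx >= -0.5) && all(idx <= dim(img$data) - 0.5)
}
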