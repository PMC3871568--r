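# 3D binary morphology on logical arrays, built on the compiled kernels.
# The structuring element is a ball of physical radius `radius_mm`
# discretised on the (possibly anisotropic) voxel grid: all offsets whose
# centre-to-centre distance is <= radius_mm.

ball_offsets <- function(radius_mm, spacing) {
  if (radius_mm < 0)
    stop_murinod("value", "Structuring-element radius must be >= 0.")
  rv <- floor(radius_mm / spacing)
  g <- expand.grid(
    dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3]
  )
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  keep <- d2 <= radius_mm^2 + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

as_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_murinod("value", "Mask must be a 3D array.")
  storage.mode(mask) <- "logical"
  mask
}

morph_erode <- function(mask, radius_mm, spacing) {
  mask <- as_mask(mask)
  off <- ball_offsets(radius_mm, spacing)
  if (nrow(off) <= 1L) return(mask)
  out <- cpp_binary_erode(as.vector(mask), dim(mask), off)
  array(out, dim(mask))
}

morph_dilate <- function(mask, radius_mm, spacing) {
  mask <- as_mask(mask)
  off <- ball_offsets(radius_mm, spacing)
  if (nrow(off) <= 1L) return(mask)
  out <- cpp_binary_dilate(as.vector(mask), dim(mask), off)
  array(out, dim(mask))
}

morph_open <- function(mask, radius_mm, spacing) {
  morph_dilate(morph_erode(mask, radius_mm, spacing), radius_mm, spacing)
}

# 1-voxel (6-neighbourhood) dilation, used for contact/adjacency queries
dilate_1vox <- function(mask) {
  mask <- as_mask(mask)
  off <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0),
                ncol = 3, byrow = TRUE)
  array(cpp_binary_dilate(as.vector(mask), dim(mask), off), dim(mask))
}

label_components <- function(mask, connectivity = 6) {
  mask <- as_mask(mask)
  array(cpp_label_components(as.vector(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

fill_holes_slicewise <- function(mask) {
  mask <- as_mask(mask)
  array(cpp_fill_holes_2d(as.vector(mask), dim(mask)), dim(mask))
}

# voxel (1-based array) index of the component containing a 0-based voxel index
component_at <- function(labels, idx0) {
  idx1 <- round(idx0) + 1L
  d <- dim(labels)
  if (any(idx1 < 1L) || any(idx1 > d)) return(0L)
  labels[idx1[1], idx1[2], idx1[3]]
}
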