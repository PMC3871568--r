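#' Seed stroke across a nodule
#'
#' The user initialises segmentation by drawing a line across the nodule on
#' one slice; its midpoint anchors the region of interest and its length
#' approximates the nodule diameter.
#'
#' @param p1,p2 Physical endpoints in mm (length-3 numeric).
#' @return A list of class `seed_stroke` with `p1`, `p2`, `midpoint`,
#'   `length` (mm).
#' @export
seed_stroke <- function(p1, p2) {
  p1 <- as.double(p1); p2 <- as.double(p2)
  if (length(p1) != 3L || length(p2) != 3L || !all(is.finite(c(p1, p2))))
    stop_murinod("value", "Stroke endpoints must be finite length-3 mm vectors.")
  len <- sqrt(sum((p2 - p1)^2))
  if (len == 0)
    stop_murinod("value", "Stroke endpoints must be distinct.")
  structure(list(p1 = p1, p2 = p2, midpoint = (p1 + p2) / 2, length = len),
            class = "seed_stroke")
}

#' Segmentation parameters
#'
#' @param roi_edge Cubic region-of-interest edge length (mm, default 5.0).
#' @param roi_increment Step by which the ROI is enlarged when the stroke
#'   does not fit (mm, default 1.0).
#' @param bin_width Histogram bin width for the adaptive threshold (HU,
#'   default 10).
#' @param vessel_filter_radius Radius of the morphological vessel filter
#'   (mm); `NULL` selects `max(1 voxel, 0.1 * stroke length)`.
#' @param juxtapleural `"auto"` (classify from the lung mask), `TRUE` or
#'   `FALSE` (force).
#' @param threshold_override Fixed threshold in HU, or `NULL` for the
#'   adaptive bimodal estimate.
#' @param contact_min Minimum wall-contact size (voxels) for the
#'   juxtapleural call (default 10).
#' @param plane_tol,quad_tol Residual RMS tolerances (mm) under which the
#'   pleural surface is accepted as a plane / quadratic; beyond both, the
#'   attachment is not a single smooth surface and wall separation fails
#'   with a multiple-attachment error.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(roi_edge = 5.0,
                                roi_increment = 1.0,
                                bin_width = 10,
                                vessel_filter_radius = NULL,
                                juxtapleural = "auto",
                                threshold_override = NULL,
                                contact_min = 10L,
                                plane_tol = 0.1,
                                quad_tol = 0.3) {
  if (roi_edge <= 0 || roi_increment <= 0 || bin_width <= 0)
    stop_murinod("value", "`roi_edge`, `roi_increment`, `bin_width` must be > 0.")
  if (!is.null(vessel_filter_radius) && vessel_filter_radius < 0)
    stop_murinod("value", "`vessel_filter_radius` must be >= 0.")
  if (!identical(juxtapleural, "auto") && !is.logical(juxtapleural))
    stop_murinod("value", "`juxtapleural` must be \"auto\", TRUE or FALSE.")
  structure(list(
    roi_edge = roi_edge, roi_increment = roi_increment, bin_width = bin_width,
    vessel_filter_radius = vessel_filter_radius, juxtapleural = juxtapleural,
    threshold_override = threshold_override, contact_min = as.integer(contact_min),
    plane_tol = plane_tol, quad_tol = quad_tol
  ), class = "segmentation_params")
}

#' Extract a cubic region of interest around a stroke
#'
#' Clips the scan to a cube of edge `roi_edge` centred at the stroke
#' midpoint.  The voxel count per edge is the nearest odd integer to
#' `roi_edge / spacing` so the midpoint sits on the centre voxel; the cube
#' is clamped to the image bounds (recorded in the `clamped` flag).
#'
#' @param img A [vol_image].
#' @param stroke A [seed_stroke].
#' @param roi_edge Cube edge length in mm.
#' @return A list with `roi` (a [vol_image]), `offset` (0-based index of
#'   the ROI corner in the parent grid) and `clamped` (logical).
#' @export
extract_roi <- function(img, stroke, roi_edge = 5.0) {
  stopifnot(inherits(img, "vol_image"), inherits(stroke, "seed_stroke"))
  if (roi_edge <= 0) stop_murinod("value", "`roi_edge` must be > 0.")
  for (p in list(stroke$p1, stroke$p2)) {
    if (!in_bounds(img, world_to_index(img, p)))
      stop_murinod("out_of_bounds", "Stroke endpoint lies outside the image.")
  }
  ctr <- round(world_to_index(img, stroke$midpoint))
  dm <- dim(img$data)
  n_edge <- 2L * as.integer(floor(roi_edge / (2 * img$spacing))) + 1L
  half <- (n_edge - 1L) %/% 2L
  lo <- pmax(ctr - half, 0)
  hi <- pmin(ctr + half, dm - 1L)
  clamped <- any(lo != ctr - half) || any(hi != ctr + half)
  sub <- img$data[(lo[1] + 1):(hi[1] + 1),
                  (lo[2] + 1):(hi[2] + 1),
                  (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  roi <- vol_image(sub, spacing = img$spacing,
                   origin = index_to_world(img, lo))
  list(roi = roi, offset = as.integer(lo), clamped = clamped)
}

#' Adaptive bimodal threshold of a region of interest
#'
#' A density histogram of the ROI (10 HU bins by default) is assumed
#' bimodal: one mode for the lung parenchyma, one for soft tissue.  The
#' histogram is smoothed with a 5-bin moving average; the two peaks are
#' the two highest local maxima separated by at least `min_separation`
#' HU, and the threshold is the midpoint of the two peak locations.
#'
#' @param roi A [vol_image] (the unresampled ROI).
#' @param bin_width Histogram bin width (HU).
#' @param region_mask Optional logical array restricting the histogram.
#' @param min_separation Minimum HU distance between the two modes.
#' @param smooth_bins Moving-average window (bins).
#' @return A list of class `threshold_estimate` with `peak_parenchyma`,
#'   `peak_soft`, `threshold` (HU) and the underlying `histogram`.
#' @export
estimate_adaptive_threshold <- function(roi, bin_width = 10, region_mask = NULL,
                                        min_separation = 100, smooth_bins = 5) {
  h <- density_histogram(roi, region_mask, bin_width)
  sm <- moving_average(h$count, smooth_bins)
  peaks <- local_maxima(sm)
  if (length(peaks) >= 2) {
    ord <- peaks[order(sm[peaks], decreasing = TRUE)]
    p1 <- ord[1]
    p2 <- NA_integer_
    for (cand in ord[-1]) {
      if (abs(h$bin_mid[cand] - h$bin_mid[p1]) >= min_separation) {
        p2 <- cand
        break
      }
    }
  } else p2 <- NA_integer_
  if (length(peaks) < 2 || is.na(p2))
    stop_murinod("bimodality", paste(
      "The ROI histogram is not bimodal: cannot separate parenchyma from",
      "soft tissue. Supply `threshold_override`."))
  lo_mid <- min(h$bin_mid[p1], h$bin_mid[p2])
  hi_mid <- max(h$bin_mid[p1], h$bin_mid[p2])
  structure(list(
    peak_parenchyma = lo_mid,
    peak_soft = hi_mid,
    threshold = (lo_mid + hi_mid) / 2,
    histogram = h
  ), class = "threshold_estimate")
}

moving_average <- function(x, w) {
  half <- (w - 1) %/% 2
  padded <- c(rep(0, half), x, rep(0, half))
  vapply(seq_along(x), function(i) mean(padded[i:(i + 2 * half)]), double(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else x[i - 1]
    right <- if (i == n) -Inf else x[i + 1]
    x[i] > left && x[i] >= right && x[i] > 0
  }, logical(1)))
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> parenchyma peak %.1f HU, soft-tissue peak %.1f HU, threshold %.1f HU\n",
    x$peak_parenchyma, x$peak_soft, x$threshold))
  invisible(x)
}

#' @export
tidy.threshold_estimate <- function(x, ...) {
  tibble(peak_parenchyma_hu = x$peak_parenchyma,
         peak_soft_hu = x$peak_soft,
         threshold_hu = x$threshold)
}

#' @export
autoplot.threshold_estimate <- function(object, ...) {
  autoplot(object$histogram) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(object$peak_parenchyma, object$peak_soft),
                        colour = "steelblue", linetype = "dotted") +
    ggplot2::labs(subtitle = sprintf("adaptive threshold %.0f HU", object$threshold))
}

#' Resample a region of interest to an isotropic grid
#'
#' Trilinear interpolation onto an isotropic grid at the minimum input
#' spacing; the physical extent is preserved.  An already-isotropic input
#' is returned unchanged.
#'
#' @param roi A [vol_image].
#' @return A [vol_image] with isotropic spacing.
#' @export
resample_isotropic <- function(roi) {
  stopifnot(inherits(roi, "vol_image"))
  sp <- roi$spacing
  if (diff(range(sp)) == 0) return(roi)
  target <- min(sp)
  dm <- dim(roi$data)
  new_n <- pmax(as.integer(round((dm - 1L) * sp / target)) + 1L, 2L)
  # sampling positions in (1-based) source index space
  tx <- 1 + (seq_len(new_n[1]) - 1) * target / sp[1]
  ty <- 1 + (seq_len(new_n[2]) - 1) * target / sp[2]
  tz <- 1 + (seq_len(new_n[3]) - 1) * target / sp[3]
  tx <- pmin(tx, dm[1]); ty <- pmin(ty, dm[2]); tz <- pmin(tz, dm[3])
  x0 <- pmin(floor(tx), dm[1] - 1L); fx <- tx - x0
  y0 <- pmin(floor(ty), dm[2] - 1L); fy <- ty - y0
  z0 <- pmin(floor(tz), dm[3] - 1L); fz <- tz - z0
  d <- roi$data
  wx <- array(fx, new_n)
  wy <- array(rep(fy, each = new_n[1]), new_n)
  wz <- array(rep(fz, each = new_n[1] * new_n[2]), new_n)
  out <-
    d[x0,     y0,     z0    ] * (1 - wx) * (1 - wy) * (1 - wz) +
    d[x0 + 1, y0,     z0    ] * wx       * (1 - wy) * (1 - wz) +
    d[x0,     y0 + 1, z0    ] * (1 - wx) * wy       * (1 - wz) +
    d[x0 + 1, y0 + 1, z0    ] * wx       * wy       * (1 - wz) +
    d[x0,     y0,     z0 + 1] * (1 - wx) * (1 - wy) * wz +
    d[x0 + 1, y0,     z0 + 1] * wx       * (1 - wy) * wz +
    d[x0,     y0 + 1, z0 + 1] * (1 - wx) * wy       * wz +
    d[x0 + 1, y0 + 1, z0 + 1] * wx       * wy       * wz
  vol_image(out, spacing = rep(target, 3), origin = roi$origin)
}

#' Apply a density threshold
#'
#' @param roi A [vol_image].
#' @param threshold Threshold in HU; voxels with density `>= threshold`
#'   are labelled soft tissue.
#' @return A logical array on the ROI grid.
#' @export
apply_threshold <- function(roi, threshold) {
  stopifnot(inherits(roi, "vol_image"))
  if (!is.finite(threshold))
    stop_murinod("value", "`threshold` must be finite.")
  roi$data >= threshold
}

#' Remove attached pulmonary vessels by morphological opening
#'
#' Opens the soft-tissue mask with a ball of the given physical radius,
#' keeps the opened connected component at the stroke midpoint, then
#' re-dilates that component by the same ball constrained to the original
#' mask so the nodule boundary is restored without regrowing the vessels.
#' The result is always a subset of the input component.
#'
#' @param mask Logical soft-tissue mask on the ROI grid.
#' @param seed_index 0-based voxel index of the stroke midpoint in the ROI.
#' @param vessel_filter_radius Ball radius in mm (0 keeps the seed
#'   component unchanged).
#' @param spacing Voxel spacing of the ROI grid (mm).
#' @return A logical array.
#' @export
remove_attached_vessels <- function(mask, seed_index, vessel_filter_radius,
                                    spacing) {
  mask <- as_mask(mask)
  labels <- label_components(mask, connectivity = 26)
  seed_lab <- component_at(labels, seed_index)
  if (seed_lab == 0L)
    stop_murinod("value", "No soft tissue at the stroke midpoint.")
  seed_comp <- labels == seed_lab
  if (vessel_filter_radius <= 0) return(seed_comp)
  opened <- morph_open(seed_comp, vessel_filter_radius, spacing)
  if (!any(opened))
    stop_murinod("filter_too_large", paste(
      "The vessel filter erased the seed component; decrease",
      "`vessel_filter_radius`."))
  lab2 <- label_components(opened, connectivity = 26)
  keep_lab <- component_at(lab2, seed_index)
  if (keep_lab == 0L) {
    # midpoint eroded away: keep the largest opened piece of the seed component
    keep_lab <- which.max(tabulate(lab2[lab2 > 0L]))
  }
  comp <- lab2 == keep_lab
  morph_dilate(comp, vessel_filter_radius, spacing) & seed_comp
}

#' Compute the lung mask and total lung volume
#'
#' Lung voxels are those below the parenchyma/soft-tissue threshold that
#' do not belong to the exterior air (components touching the lateral x/y
#' faces of the volume are discarded when `exclude_border = TRUE`); holes
#' — vessels and nodules — are filled slice by slice.  If no threshold is
#' supplied, the adaptive bimodal estimate is computed on voxels above
#' `air_cut` so the exterior-air mode does not masquerade as parenchyma.
#'
#' @param img A [vol_image].
#' @param threshold Parenchyma/soft-tissue threshold (HU), or `NULL` for
#'   the adaptive estimate.
#' @param exclude_border Discard low-density components touching the x/y
#'   faces (exterior air).  Use `FALSE` for regions of interest that sit
#'   entirely inside the lung.
#' @param fill_axes Axes along which 2D hole filling is applied (any of
#'   1, 2, 3 = slices orthogonal to x, y, z).
#' @param air_cut Voxels at or below this density are excluded from the
#'   threshold histogram (exterior air).
#' @return A list with `mask` (logical array), `volume_mm3`, and
#'   `threshold` (HU).
#' @export
compute_lung_mask <- function(img, threshold = NULL, exclude_border = TRUE,
                              fill_axes = 3L, air_cut = -800) {
  stopifnot(inherits(img, "vol_image"))
  if (is.null(threshold)) {
    body_mask <- img$data > air_cut
    if (!any(body_mask))
      stop_murinod("lung_not_found", "No tissue above the air cutoff.")
    est <- tryCatch(
      estimate_adaptive_threshold(img, region_mask = body_mask),
      murinod_error_bimodality = function(e) NULL
    )
    if (is.null(est))
      stop_murinod("lung_not_found", paste(
        "No bimodal parenchyma/soft-tissue histogram: the image does not",
        "contain an enclosed low-density lung region."))
    threshold <- est$threshold
  }
  low <- img$data < threshold
  if (exclude_border) {
    labels <- label_components(low, connectivity = 6)
    dm <- dim(low)
    border_labs <- unique(c(labels[1, , ], labels[dm[1], , ],
                            labels[, 1, ], labels[, dm[2], ]))
    border_labs <- border_labs[border_labs > 0L]
    low <- low & !array(labels %in% border_labs, dm)
  }
  if (!any(low))
    stop_murinod("lung_not_found",
                 "No enclosed low-density region below the threshold.")
  mask <- fill_holes_axes(low, fill_axes)
  list(mask = mask,
       volume_mm3 = sum(mask) * voxel_volume(img),
       threshold = threshold)
}

fill_holes_axes <- function(mask, axes) {
  for (ax in axes) {
    perm <- switch(as.integer(ax), c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
    m <- aperm(mask, perm)
    m <- fill_holes_slicewise(m)
    mask <- aperm(m, order(perm))
  }
  mask
}

#' Classify a candidate nodule as juxtapleural
#'
#' A nodule abutting the chest wall merges with wall soft tissue at the
#' segmentation threshold.  The candidate is called juxtapleural when at
#' least `contact_min` of its voxels lie outside the hole-filled lung
#' region, i.e. in wall territory; an isolated nodule (a filled hole in
#' the lung) has essentially none.
#'
#' @param candidate_mask Logical candidate mask (post vessel removal).
#' @param lung_mask Logical hole-filled lung mask on the same grid.
#' @param contact_min Minimum wall-territory voxel count (default 10).
#' @param override `NULL` for automatic classification, or a logical that
#'   forces the result.
#' @return `TRUE` or `FALSE`.
#' @export
classify_juxtapleural <- function(candidate_mask, lung_mask, contact_min = 10L,
                                  override = NULL) {
  if (!is.null(override)) return(isTRUE(override))
  candidate_mask <- as_mask(candidate_mask)
  lung_mask <- as_mask(lung_mask)
  if (!identical(dim(candidate_mask), dim(lung_mask)))
    stop_murinod("value", "Masks must share the ROI grid.")
  sum(candidate_mask & !lung_mask) >= contact_min
}

#' Separate a juxtapleural nodule from the chest wall
#'
#' Fits a least-squares surface (a plane; a quadratic height field when
#' the plane residual exceeds tolerance) to the pleural boundary voxels —
#' lung voxels adjacent to the candidate — flanking the attachment
#' (boundary voxels within one stroke length of the stroke midpoint are
#' excluded so the nodule dome does not bias the fit).  Candidate voxels
#' on the wall side of the fitted surface are removed and the component at
#' the stroke midpoint is retained.
#'
#' If neither a plane nor a quadratic describes the pleural boundary
#' (residual RMS above `quad_tol`), the nodule has more than one major
#' wall attachment, which the algorithm does not support, and a
#' multiple-attachment error is raised.
#'
#' @param mask Logical candidate mask (nodule merged with wall).
#' @param roi The resampled ROI [vol_image].
#' @param lung_mask Logical hole-filled lung mask on the ROI grid.
#' @param stroke_mid_index 0-based voxel index of the stroke midpoint.
#' @param stroke_length Stroke length in mm (nodule extent scale).
#' @param contact_min Below this wall-voxel count the input is considered
#'   non-attached and returned unchanged.
#' @param plane_tol,quad_tol Surface-fit residual tolerances in mm.
#' @return A logical array (subset of `mask`).
#' @export
separate_chest_wall <- function(mask, roi, lung_mask, stroke_mid_index,
                                stroke_length, contact_min = 10L,
                                plane_tol = 0.1, quad_tol = 0.3) {
  mask <- as_mask(mask)
  lung_mask <- as_mask(lung_mask)
  sp <- roi$spacing
  wall_part <- mask & !lung_mask
  if (sum(wall_part) < contact_min) return(mask)  # not actually attached

  # count distinct wall-attachment patches on the nodule surface: wall
  # territory within one nodule radius (plus margin) of the stroke midpoint
  mid_mm0 <- stroke_mid_index * sp
  wp_idx <- which(wall_part, arr.ind = TRUE)
  wp_d <- sqrt(rowSums(sweep(sweep(wp_idx - 1, 2, sp, `*`), 2, mid_mm0, `-`)^2))
  near_r <- stroke_length / 2 + 2 * max(sp)
  patch <- array(FALSE, dim(mask))
  patch[wp_idx[wp_d <= near_r, , drop = FALSE]] <- TRUE
  if (any(patch)) {
    pl <- label_components(patch, connectivity = 26)
    n_major <- sum(tabulate(pl[pl > 0L]) >= contact_min)
    if (n_major >= 2L)
      stop_murinod("multiple_attachment", sprintf(
        paste("Found %d disjoint wall attachments; the algorithm assumes the",
              "nodule has only one major attachment."), n_major))
  }

  # pleural boundary: lung voxels adjacent to the candidate, away from the
  # stroke neighbourhood (which is the nodule dome, not the wall)
  pb <- dilate_1vox(mask) & lung_mask
  pb_idx <- which(pb, arr.ind = TRUE)
  pts_all <- sweep(pb_idx - 1, 2, sp, `*`)  # 0-based index -> mm (ROI frame)
  mid_mm <- stroke_mid_index * sp
  d_mid <- sqrt(rowSums(sweep(pts_all, 2, mid_mm, `-`)^2))
  # keep only boundary voxels of the lung component the nodule sits in, so
  # low-density regions on the far side of the wall (exterior air) cannot
  # contribute a second, parallel surface
  lung_labs <- label_components(lung_mask, connectivity = 6)
  pb_labs <- lung_labs[pb_idx]
  tab <- table(pb_labs)
  big <- as.integer(names(tab[tab >= 30]))  # ignore noise-speck components
  if (length(big)) {
    cand_d <- vapply(big, function(l) min(d_mid[pb_labs == l]), double(1))
    own <- pb_labs == big[which.min(cand_d)]
    pb_idx <- pb_idx[own, , drop = FALSE]
    pts_all <- pts_all[own, , drop = FALSE]
    d_mid <- d_mid[own]
  }
  # flanking band: outside the nodule dome (one stroke length) but close to
  # the attachment, so distant wall elsewhere in the ROI cannot bias the fit
  pts <- NULL
  for (outer_fac in c(2, 3, 4, Inf)) {
    flank <- d_mid > stroke_length & d_mid <= outer_fac * stroke_length
    if (sum(flank) >= 30 || !is.finite(outer_fac)) {
      pts <- pts_all[flank, , drop = FALSE]
      break
    }
  }
  if (nrow(pts) < 10)
    stop_murinod("fit", "Too few pleural boundary voxels to fit a surface.")

  fit <- fit_pleural_surface(pts, plane_tol, quad_tol)
  if (is.null(fit))
    stop_murinod("multiple_attachment", paste(
      "The pleural boundary is not a single smooth surface: the nodule",
      "appears to have more than one major wall attachment, which this",
      "algorithm does not support."))

  # orient the surface: wall-side = sign of the mean signed height of the
  # candidate's wall portion
  wall_idx <- which(wall_part, arr.ind = TRUE)
  wall_pts <- sweep(wall_idx - 1, 2, sp, `*`)
  wall_sign <- mean(surface_signed_height(fit, wall_pts))
  flip <- if (wall_sign >= 0) 1 else -1

  mask_idx <- which(mask, arr.ind = TRUE)
  mask_pts <- sweep(mask_idx - 1, 2, sp, `*`)
  # the surface interpolates lung voxel centres, half a voxel inside the
  # lung; cut a quarter-voxel onto the wall side so the boundary layer of
  # the nodule is not shaved off
  s <- flip * surface_signed_height(fit, mask_pts)
  keep <- s < 0.25 * min(sp)
  cut <- array(FALSE, dim(mask))
  cut[mask_idx[keep, , drop = FALSE]] <- TRUE
  if (!any(cut))
    stop_murinod("fit", "Wall separation removed the entire candidate.")

  # retain the component nearest the stroke midpoint
  labs <- label_components(cut, connectivity = 26)
  lab <- component_at(labs, stroke_mid_index)
  if (lab == 0L) {
    cut_idx <- which(cut, arr.ind = TRUE)
    cut_pts <- sweep(cut_idx - 1, 2, sp, `*`)
    d <- sqrt(rowSums(sweep(cut_pts, 2, mid_mm, `-`)^2))
    near <- d <= max(stroke_length, 3 * max(sp))
    if (!any(near))
      stop_murinod("fit", "No candidate component remains near the stroke.")
    cand_labs <- labs[cut_idx[near, , drop = FALSE]]
    lab <- as.integer(names(which.max(table(cand_labs))))
  }
  labs == lab
}

# plane (orthogonal least squares) with quadratic height-field fallback;
# returns NULL when neither is within tolerance
fit_pleural_surface <- function(pts, plane_tol, quad_tol) {
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr, `-`)
  sv <- svd(centered, nu = 0)
  normal <- sv$v[, 3]
  u <- sv$v[, 1]; v <- sv$v[, 2]
  h <- centered %*% normal
  if (sqrt(mean(h^2)) <= plane_tol)
    return(list(kind = "plane", ctr = ctr, normal = normal))
  uu <- centered %*% u
  vv <- centered %*% v
  X <- cbind(1, uu, vv, uu^2, uu * vv, vv^2)
  beta <- qr.coef(qr(X), h)
  resid <- h - X %*% beta
  if (sqrt(mean(resid^2)) <= quad_tol)
    return(list(kind = "quadratic", ctr = ctr, normal = normal,
                u = u, v = v, beta = as.double(beta)))
  NULL
}

surface_signed_height <- function(fit, pts) {
  centered <- sweep(pts, 2, fit$ctr, `-`)
  h <- centered %*% fit$normal
  if (fit$kind == "plane") return(as.double(h))
  uu <- centered %*% fit$u
  vv <- centered %*% fit$v
  pred <- cbind(1, uu, vv, uu^2, uu * vv, vv^2) %*% fit$beta
  as.double(h - pred)
}

#' Semi-automated nodule segmentation
#'
#' Runs the full pipeline from a seed stroke to a binary nodule mask:
#' cubic ROI extraction, adaptive bimodal threshold (on the unresampled
#' ROI), isotropic resampling, thresholding, morphological vessel removal,
#' lung-mask computation, juxtapleural classification and — when the
#' nodule abuts the chest wall — surface-fitting wall separation.  The
#' final mask contains only voxels belonging to the nodule; the only way
#' to adjust a result is to re-run with different parameters (no manual
#' mask editing).
#'
#' @param img A [vol_image] in HU.
#' @param stroke A [seed_stroke] across the nodule.
#' @param params A [segmentation_params] object.
#' @return An object of class `nodule_segmentation`: the binary `mask`
#'   (on the resampled ROI grid), its `spacing` and `roi_offset`, the
#'   `threshold` estimate used, the `juxtapleural` flag, `params`, any
#'   `warnings`, and the measured `volume_mm3`.
#' @examples
#' ph <- build_thorax_phantom(phantom_spec(grid_shape = c(96, 96, 96),
#'   noise_sd = 0, nodules = phantom_nodule(c(2.4, 2.4, 2.4), 0.5)))
#' seg <- segment_nodule(ph$image,
#'                       seed_stroke(c(1.9, 2.4, 2.4), c(2.9, 2.4, 2.4)))
#' tidy(seg)
#' @export
segment_nodule <- function(img, stroke, params = segmentation_params()) {
  stopifnot(inherits(img, "vol_image"), inherits(stroke, "seed_stroke"),
            inherits(params, "segmentation_params"))
  warnings <- character(0)

  roi_edge <- params$roi_edge
  while (roi_edge < stroke$length) {
    roi_edge <- roi_edge + params$roi_increment
    warnings <- c(warnings, sprintf(
      "ROI edge increased to %.1f mm to cover the stroke.", roi_edge))
  }

  ext <- with_stage("roi_extraction", extract_roi(img, stroke, roi_edge))
  if (ext$clamped)
    warnings <- c(warnings, "ROI clamped to the image bounds.")

  if (is.null(params$threshold_override)) {
    # exterior air entering a clamped ROI must not masquerade as the
    # parenchyma mode: histogram only voxels above the air cutoff
    body_mask <- ext$roi$data > -800
    if (!any(body_mask)) body_mask <- NULL
    thr_est <- with_stage("adaptive_threshold",
                          estimate_adaptive_threshold(ext$roi, params$bin_width,
                                                      region_mask = body_mask))
  } else {
    thr_est <- structure(list(peak_parenchyma = NA_real_, peak_soft = NA_real_,
                              threshold = params$threshold_override,
                              histogram = NULL),
                         class = "threshold_estimate")
  }

  roi_iso <- with_stage("resampling", resample_isotropic(ext$roi))
  soft <- with_stage("thresholding", apply_threshold(roi_iso, thr_est$threshold))

  mid_idx <- round(world_to_index(
    vol_image(roi_iso$data, roi_iso$spacing, roi_iso$origin), stroke$midpoint))
  mid_idx <- pmin(pmax(mid_idx, 0), dim(roi_iso$data) - 1L)
  mid_idx <- nearest_soft_voxel(soft, mid_idx, stroke$length, roi_iso$spacing)

  vfr <- params$vessel_filter_radius %||%
    max(min(roi_iso$spacing), 0.1 * stroke$length)
  cand <- with_stage("vessel_removal",
                     remove_attached_vessels(soft, mid_idx, vfr, roi_iso$spacing))

  lung <- tryCatch(
    compute_lung_mask(roi_iso, threshold = thr_est$threshold,
                      exclude_border = FALSE, fill_axes = c(1L, 2L, 3L)),
    murinod_error_lung_not_found = function(e) {
      list(mask = array(FALSE, dim(roi_iso$data)), volume_mm3 = 0)
    }
  )

  override <- if (identical(params$juxtapleural, "auto")) NULL else params$juxtapleural
  jux <- with_stage("juxtapleural_classification",
                    classify_juxtapleural(cand, lung$mask,
                                          contact_min = params$contact_min,
                                          override = override))

  if (jux) {
    cand <- with_stage("chest_wall_separation",
                       separate_chest_wall(cand, roi_iso, lung$mask, mid_idx,
                                           stroke$length,
                                           contact_min = params$contact_min,
                                           plane_tol = params$plane_tol,
                                           quad_tol = params$quad_tol))
  }

  if (!any(cand))
    stop_murinod("fit", "Segmentation produced an empty mask.")

  structure(list(
    mask = cand,
    spacing = roi_iso$spacing,
    roi_offset = ext$offset,
    roi_origin = roi_iso$origin,
    threshold = thr_est,
    juxtapleural = jux,
    lung_volume_mm3 = lung$volume_mm3,
    params = params,
    stroke = stroke,
    warnings = warnings,
    volume_mm3 = sum(cand) * prod(roi_iso$spacing)
  ), class = "nodule_segmentation")
}

# if the rounded midpoint voxel is not soft tissue (noise pocket), take the
# nearest soft voxel within half a stroke length
nearest_soft_voxel <- function(soft, idx0, stroke_length, spacing) {
  idx1 <- idx0 + 1L
  if (soft[idx1[1], idx1[2], idx1[3]]) return(idx0)
  soft_idx <- which(soft, arr.ind = TRUE)
  if (nrow(soft_idx) == 0L)
    stop_murinod("value", "No soft tissue in the ROI at this threshold.")
  d <- sqrt(rowSums(sweep(sweep(soft_idx, 2, idx1, `-`), 2, spacing, `*`)^2))
  if (min(d) > stroke_length / 2)
    stop_murinod("value", "No soft tissue near the stroke midpoint.")
  as.integer(soft_idx[which.min(d), ]) - 1L
}

with_stage <- function(stage, expr) {
  tryCatch(expr, murinod_error = function(e) {
    if (is.null(e$stage)) {
      e$stage <- stage
      e$message <- paste0("[", stage, "] ", conditionMessage(e))
    }
    stop(e)
  })
}

#' @export
print.nodule_segmentation <- function(x, ...) {
  cat(sprintf(
    "<nodule_segmentation> %d voxels, volume %.4f mm^3, threshold %.1f HU, juxtapleural: %s\n",
    sum(x$mask), x$volume_mm3, x$threshold$threshold,
    ifelse(x$juxtapleural, "yes", "no")))
  if (length(x$warnings))
    cat(paste0("  warning: ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.nodule_segmentation <- function(x, ...) {
  tibble(
    volume_mm3 = x$volume_mm3,
    equivalent_diameter_mm = equivalent_diameter(x$volume_mm3),
    n_voxels = sum(x$mask),
    threshold_hu = x$threshold$threshold,
    juxtapleural = x$juxtapleural,
    lung_volume_mm3 = x$lung_volume_mm3
  )
}

#' Plot the central slice of a segmentation result
#'
#' @param object A `nodule_segmentation`.
#' @param ... Unused.
#' @return A ggplot: the central ROI slice with the mask outline.
#' @export
autoplot.nodule_segmentation <- function(object, ...) {
  k <- ceiling(dim(object$mask)[3] / 2)
  df <- tidyr::expand_grid(
    j = seq_len(dim(object$mask)[2]),
    i = seq_len(dim(object$mask)[1])
  )
  df$mask <- as.vector(object$mask[, , k])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$mask)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey20", `TRUE` = "firebrick")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "nodule",
                  subtitle = sprintf("central slice (k = %d)", k)) +
    ggplot2::theme_minimal()
}
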