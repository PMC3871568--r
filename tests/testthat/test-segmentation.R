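test_that("ROI extraction uses odd voxel counts, clamping and bounds checks", {
  img <- vol_image(array(0, c(200, 200, 160)), spacing = rep(0.05, 3))
  stroke <- seed_stroke(c(4.25, 5, 4), c(5.75, 5, 4))
  ext <- extract_roi(img, stroke, 5.0)
  expect_equal(dim(ext$roi$data), rep(101L, 3))  # 5 mm / 0.05 mm -> 101 odd
  expect_false(ext$clamped)
  # ROI centre voxel sits at the stroke midpoint
  ctr_world <- index_to_world(ext$roi, (dim(ext$roi$data) - 1) / 2)
  expect_equal(ctr_world, stroke$midpoint, tolerance = 0.05)

  ext6 <- extract_roi(img, stroke, 6.0)
  expect_equal(dim(ext6$roi$data), rep(121L, 3))  # enlarged by 1 mm

  # near the border: clamped flag set, all voxels in bounds
  near <- seed_stroke(c(0.5, 5, 4), c(1.5, 5, 4))
  extc <- extract_roi(img, near, 5.0)
  expect_true(extc$clamped)
  expect_true(all(dim(extc$roi$data) <= dim(img$data)))

  out <- seed_stroke(c(-1, 5, 4), c(1, 5, 4))
  expect_error(extract_roi(img, out, 5),
               class = "murinod_error_out_of_bounds")
  expect_error(seed_stroke(c(1, 1, 1), c(1, 1, 1)), class = "murinod_error_value")
})

test_that("adaptive threshold finds the mode midpoint of a bimodal mixture", {
  set.seed(123)
  n <- 101^3
  vals <- c(rnorm(round(0.7 * n), -400, 60), rnorm(n - round(0.7 * n), 50, 60))
  roi <- vol_image(array(sample(vals), c(101, 101, 101)))
  est <- estimate_adaptive_threshold(roi, bin_width = 10)
  expect_lt(abs(est$threshold - (-175)), 10 + 1e-9)
  expect_lt(abs(est$peak_parenchyma - (-400)), 10 + 1e-9)
  expect_lt(abs(est$peak_soft - 50), 10 + 1e-9)
  # threshold strictly between the peaks, at their midpoint
  expect_gt(est$threshold, est$peak_parenchyma)
  expect_lt(est$threshold, est$peak_soft)
  expect_equal(est$threshold, (est$peak_parenchyma + est$peak_soft) / 2)

  # unimodal input: no second mode
  expect_error(estimate_adaptive_threshold(vol_image(array(-300, c(20, 20, 20)))),
               class = "murinod_error_bimodality")
  set.seed(5)
  uni <- vol_image(array(rnorm(8000, -300, 40), c(20, 20, 20)))
  expect_error(estimate_adaptive_threshold(uni),
               class = "murinod_error_bimodality")
})

test_that("equal-mass two-Gaussian mixtures give midpoint thresholds when sigma <= gap/4", {
  for (seed in 1:4) {
    set.seed(seed)
    gap <- 450
    sigma <- gap / 4
    vals <- c(rnorm(3e5, -400, sigma), rnorm(3e5, -400 + gap, sigma))
    roi <- vol_image(array(sample(vals), c(100, 100, 60)))
    est <- estimate_adaptive_threshold(roi, bin_width = 10)
    expect_lt(abs(est$threshold - (-400 + gap / 2)), 10 + 1e-9)
  }
})

test_that("isotropic resampling is identity on isotropic grids and preserves extent", {
  iso <- vol_image(array(rnorm(10^3), c(10, 10, 10)), rep(0.05, 3))
  expect_identical(resample_isotropic(iso), iso)  # bit-equal

  set.seed(8)
  an <- vol_image(array(rnorm(40 * 40 * 20, -400, 100), c(40, 40, 20)),
                  c(0.05, 0.05, 0.10), origin = c(1, 1, 1))
  rs <- resample_isotropic(an)
  expect_equal(rs$spacing, rep(0.05, 3))
  # z extent preserved within one voxel
  ext_in <- (dim(an$data)[3] - 1) * 0.10
  ext_out <- (dim(rs$data)[3] - 1) * 0.05
  expect_lt(abs(ext_in - ext_out), 0.05 + 1e-9)

  const <- vol_image(array(7, c(10, 10, 5)), c(0.05, 0.05, 0.1))
  expect_lt(max(abs(resample_isotropic(const)$data - 7)), 1e-9)
})

test_that("thresholding is exact on delta phantoms and monotone in the cutoff", {
  d <- array(-400, c(20, 20, 20)); d[5:10, 5:10, 5:10] <- 50
  roi <- vol_image(d)
  m <- apply_threshold(roi, -175)
  expect_identical(m, d == 50)
  expect_true(all(apply_threshold(roi, -2000)))

  set.seed(21)
  rnd <- vol_image(array(rnorm(8000, 0, 500), c(20, 20, 20)))
  thresholds <- sort(rnorm(5, 0, 400))
  masks <- lapply(thresholds, function(t) apply_threshold(rnd, t))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))  # raising t never adds voxels
  }
})

test_that("vessel removal strips a thin attached tube but keeps the nodule", {
  # sphere r = 0.5 mm with a r = 0.1 mm tube, filter radius 0.15 mm
  sp <- phantom_spec(
    noise_sd = 0,
    nodules = phantom_nodule(c(4, 4, 3.2), 0.5, placement = "vessel_attached"),
    vessels = tibble::tibble(x1 = 4.3, y1 = 4, z1 = 3.2,
                             x2 = 7.0, y2 = 4, z2 = 3.2,
                             radius = 0.1, density = 50))
  ph <- build_thorax_phantom(sp)
  ext <- extract_roi(ph$image, seed_stroke(c(3.5, 4, 3.2), c(4.5, 4, 3.2)), 5)
  mask <- apply_threshold(ext$roi, -175)
  mid <- round(world_to_index(ext$roi, c(4, 4, 3.2)))
  out <- remove_attached_vessels(mask, mid, 0.15, ext$roi$spacing)
  expect_true(all(out <= mask))  # output subset of input
  truth <- ph$truth$voxel_volumes
  got <- sum(out) * voxel_volume(ext$roi)
  expect_lt(abs(got - truth) / truth, 0.05)

  # radius 0: identity on the seed component
  out0 <- remove_attached_vessels(mask, mid, 0, ext$roi$spacing)
  labs <- murinod:::label_components(mask, 26)
  expect_identical(out0, labs == murinod:::component_at(labs, mid))

  # filter larger than the sphere erases the seed component
  expect_error(remove_attached_vessels(mask, mid, 0.7, ext$roi$spacing),
               class = "murinod_error_filter_too_large")
})

test_that("lung mask recovers the phantom cavity volume and flags solid volumes", {
  ph <- isolated_phantom()
  lm <- compute_lung_mask(ph$image)
  cavity <- ph$truth$lung_mask | ph$truth$nodule_masks[[1]]
  truth_vol <- sum(cavity) * voxel_volume(ph$image)
  expect_lt(abs(lm$volume_mm3 - truth_vol) / truth_vol, 0.02)
  expect_equal(lm$volume_mm3, sum(lm$mask) * voxel_volume(ph$image))

  solid <- vol_image(array(50, c(30, 30, 30)), rep(0.05, 3))
  expect_error(compute_lung_mask(solid), class = "murinod_error_lung_not_found")
})

test_that("juxtapleural classification separates isolated from wall-embedded nodules", {
  ph <- isolated_phantom()
  seg <- cached("seg_isolated",
                segment_nodule(ph$image, isolated_stroke()))
  expect_false(seg$juxtapleural)

  hseg <- cached("seg_hemisphere",
                 segment_nodule(hemisphere_phantom()$image, hemisphere_stroke()))
  expect_true(hseg$juxtapleural)

  # forcing juxtapleural = FALSE short-circuits classification
  expect_false(classify_juxtapleural(array(TRUE, c(3, 3, 3)),
                                     array(FALSE, c(3, 3, 3)),
                                     override = FALSE))
})

test_that("chest-wall separation recovers the hemisphere and is identity when misrouted", {
  ph <- hemisphere_phantom()
  seg <- cached("seg_hemisphere",
                segment_nodule(ph$image, hemisphere_stroke()))
  truth <- ph$truth$analytic_volumes  # spherical cap = half sphere
  expect_equal(truth, 0.5 * sphere_volume(0.75), tolerance = 1e-9)
  expect_lt(abs(seg$volume_mm3 - truth) / truth, 0.10)

  # non-attached input passes through unchanged: an isolated nodule is a
  # filled hole inside the lung region, so it has no wall territory
  m <- array(FALSE, c(30, 30, 30)); m[14:17, 14:17, 14:17] <- TRUE
  roi <- vol_image(array(-400, c(30, 30, 30)), rep(0.05, 3))
  lung <- array(TRUE, c(30, 30, 30))
  out <- separate_chest_wall(m, roi, lung, c(15, 15, 15), 0.4)
  expect_identical(out, m)
})

test_that("a nodule touching wall and diaphragm raises a multiple-attachment error", {
  ph <- two_attachment_phantom()
  expect_error(segment_nodule(ph$image, two_attachment_stroke()),
               class = "murinod_error_multiple_attachment")
})

test_that("full pipeline recovers isolated sphere volumes and is stroke-symmetric", {
  ph <- isolated_phantom()
  seg <- cached("seg_isolated", segment_nodule(ph$image, isolated_stroke()))
  truth <- ph$truth$voxel_volumes
  expect_lt(abs(seg$volume_mm3 - truth) / truth, 0.05)
  # threshold near the configured mode midpoint, as on repeat scans
  expect_gte(est <- seg$threshold$threshold, -190)
  expect_lte(est, -155)

  # swapped stroke endpoints give the identical mask
  s <- isolated_stroke()
  seg_rev <- segment_nodule(ph$image, seed_stroke(s$p2, s$p1))
  expect_identical(seg_rev$mask, seg$mask)

  # determinism: re-running is bit-identical
  seg2 <- segment_nodule(ph$image, s)
  expect_identical(seg2$mask, seg$mask)

  # every stage after thresholding shrinks or preserves the soft-tissue mask
  ext <- extract_roi(ph$image, s, 5)
  soft <- apply_threshold(resample_isotropic(ext$roi), seg$threshold$threshold)
  expect_true(all(seg$mask <= soft))
})

test_that("volume error stays small across sphere radii (5, 10, 20 voxels)", {
  errs <- vapply(c(0.25, 0.5, 1.0), function(r) {
    sp <- phantom_spec(nodules = phantom_nodule(c(4, 4, 3.2), r))
    ph <- build_thorax_phantom(sp)
    seg <- segment_nodule(ph$image,
                          seed_stroke(c(4 - r, 4, 3.2), c(4 + r, 4, 3.2)))
    abs(seg$volume_mm3 - ph$truth$voxel_volumes) / ph$truth$voxel_volumes
  }, double(1))
  expect_true(all(errs < 0.05))
  # no systematic worsening with radius (binary-density phantoms have no
  # partial-volume effect, so errors are discretisation jitter near zero)
  expect_lt(errs[3], errs[1] + 5e-3)
})

test_that("volume estimates are robust to scan noise between 30 and 90 HU", {
  vols <- vapply(c(30, 60, 90), function(ns) {
    ph <- build_thorax_phantom(phantom_spec(noise_sd = ns))
    segment_nodule(ph$image, isolated_stroke())$volume_mm3
  }, double(1))
  expect_lt(diff(range(vols)) / mean(vols), 0.05)
})

test_that("threshold override skips histogram analysis and is recorded", {
  ph <- isolated_phantom()
  params <- segmentation_params(threshold_override = -175)
  seg <- segment_nodule(ph$image, isolated_stroke(), params)
  expect_equal(seg$threshold$threshold, -175)
  truth <- ph$truth$voxel_volumes
  expect_lt(abs(seg$volume_mm3 - truth) / truth, 0.05)
})

test_that("pipeline errors carry the failing stage identity", {
  const_img <- vol_image(array(-300, c(120, 120, 120)), rep(0.05, 3))
  err <- tryCatch(
    segment_nodule(const_img, seed_stroke(c(2.5, 3, 3), c(3.5, 3, 3))),
    error = function(e) e)
  expect_s3_class(err, "murinod_error_bimodality")
  expect_equal(err$stage, "adaptive_threshold")
  expect_match(conditionMessage(err), "adaptive_threshold")
})
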