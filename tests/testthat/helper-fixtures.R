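# Shared fixtures: phantoms are built once per test run (cached), and DICOM
# test series are generated on the fly by an independent minimal writer so
# no binary fixtures ship with the package.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

isolated_phantom <- function() cached("isolated", {
  build_thorax_phantom(phantom_spec())  # defaults: r = 0.75 mm sphere, noise 60
})

isolated_stroke <- function() seed_stroke(c(3.25, 4, 3.2), c(4.75, 4, 3.2))

hemisphere_phantom <- function() cached("hemisphere", {
  build_thorax_phantom(phantom_spec(
    diaphragm_z = 2.0,
    nodules = phantom_nodule(c(4, 4, 2.0), 0.75, placement = "juxtapleural")))
})

hemisphere_stroke <- function() seed_stroke(c(3.25, 4, 2.3), c(4.75, 4, 2.3))

two_attachment_phantom <- function() cached("two_attach", {
  build_thorax_phantom(phantom_spec(
    diaphragm_z = 2.6,
    nodules = phantom_nodule(c(6.45, 4, 3.2), 0.75,
                             placement = "two_attachments")))
})

two_attachment_stroke <- function() seed_stroke(c(6.45, 3.25, 3.2), c(6.45, 4.75, 3.2))

# ---- minimal explicit-VR little-endian DICOM writer (test oracle only) ----

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_u16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))

# write one single-frame CT slice; `pixels` is an nx x ny integer matrix of
# raw (pre-rescale) values, x fastest as in the package's volume model
write_dicom_slice <- function(path, pixels, position, pixel_spacing_xy,
                              series_uid = "1.2.3.4", slope = 1,
                              intercept = -1000,
                              orientation = c(1, 0, 0, 0, 1, 0)) {
  px <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  body <- c(
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0032, "DS", paste(position, collapse = "\\")),
    dcm_str(0x0020, 0x0037, "DS", paste(orientation, collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(ncol(pixels))),  # Rows (y)
    dcm_element(0x0028, 0x0011, "US", dcm_u16(nrow(pixels))),  # Columns (x)
    dcm_str(0x0028, 0x0030, "DS",
            paste(c(pixel_spacing_xy[2], pixel_spacing_xy[1]), collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(1)),
    dcm_str(0x0028, 0x1052, "DS", format(intercept)),
    dcm_str(0x0028, 0x1053, "DS", format(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  meta <- dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# write a whole volume as a DICOM series; returns the directory
write_dicom_series <- function(img, dir, series_uid = "1.2.3.4", slope = 1,
                               intercept = -1000, filenames = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(img$data)[3]
  if (is.null(filenames)) filenames <- sprintf("slice_%03d.dcm", seq_len(nz))
  for (k in seq_len(nz)) {
    raw_vals <- round((img$data[, , k] - intercept) / slope)
    write_dicom_slice(
      file.path(dir, filenames[k]),
      matrix(as.integer(raw_vals), nrow = dim(img$data)[1]),
      position = img$origin + c(0, 0, (k - 1) * img$spacing[3]),
      pixel_spacing_xy = img$spacing[1:2],
      series_uid = series_uid, slope = slope, intercept = intercept)
  }
  invisible(dir)
}
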