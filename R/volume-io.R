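#' Read a volume from a NIfTI file
#'
#' NIfTI (`.nii` / `.nii.gz`) is the canonical on-disk format for volumes
#' and masks in this package.  Voxel spacing is taken from `pixdim` and the
#' origin from the qform/sform translation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [vol_image].
#' @seealso [write_volume()], [read_dicom_series()]
#' @export
read_volume <- function(path) {
  check_volume_ext(path)
  if (!file.exists(path))
    stop_murinod("file_not_found", paste0("File does not exist: ", path))
  nii <- RNifti::readNifti(path)
  dm <- dim(nii)
  if (length(dm) != 3L)
    stop_murinod("format", "Expected a 3D volume.")
  xf <- RNifti::xform(nii)
  vol_image(
    data = array(as.double(nii), dm),
    spacing = RNifti::pixdim(nii)[1:3],
    origin = as.double(xf[1:3, 4])
  )
}

#' Write a volume to a NIfTI file
#'
#' @param img A [vol_image] (or a logical/integer mask array wrapped by the
#'   caller into one; masks are written as 0/1 volumes).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "vol_image"))
  check_volume_ext(path)
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$spacing
  xf <- rbind(cbind(diag(img$spacing), img$origin), c(0, 0, 0, 1))
  RNifti::qform(nii) <- structure(xf, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

check_volume_ext <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop_murinod("format", paste0("Unrecognised volume extension: ", path,
                                  " (expected .nii or .nii.gz)"))
  invisible(path)
}

#' Read a single-frame DICOM CT series as a calibrated HU volume
#'
#' Reads every `.dcm` file in a directory (explicit VR little endian),
#' applies the rescale slope/intercept so voxel values are Hounsfield
#' units, sorts slices by physical position along the slice normal, and
#' infers the slice spacing from consecutive positions.
#'
#' @param directory_path Directory containing one single-frame CT series.
#' @param tol Relative tolerance on slice-gap uniformity (default 1%).
#' @return A [vol_image] in HU.
#' @export
read_dicom_series <- function(directory_path, tol = 0.01) {
  files <- list.files(directory_path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    stop_murinod("file_not_found",
                 paste0("No .dcm files in ", directory_path))
  slices <- lapply(files, read_dicom_slice)

  uids <- unique(vapply(slices, function(s) s$series_uid, character(1)))
  if (length(uids) > 1L)
    stop_murinod("mixed_series", sprintf(
      "Directory contains %d distinct series UIDs; expected one.", length(uids)))

  # physical position along the slice normal (cross product of the in-plane
  # direction cosines) defines the stacking order
  ori <- slices[[1]]$orientation
  normal <- c(
    ori[2] * ori[6] - ori[3] * ori[5],
    ori[3] * ori[4] - ori[1] * ori[6],
    ori[1] * ori[5] - ori[2] * ori[4]
  )
  zpos <- vapply(slices, function(s) sum(s$position * normal), double(1))
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]

  if (length(slices) > 1L) {
    gaps <- diff(zpos)
    if (any(gaps <= 0))
      stop_murinod("irregular_spacing", "Duplicate or non-increasing slice positions.")
    if ((max(gaps) - min(gaps)) / mean(gaps) > tol)
      stop_murinod("irregular_spacing", sprintf(
        "Non-uniform slice gap: %.4f..%.4f mm exceeds %.1f%% tolerance.",
        min(gaps), max(gaps), 100 * tol))
    dz <- mean(gaps)
  } else {
    dz <- slices[[1]]$pixel_spacing[1]
  }

  nx <- slices[[1]]$ncol
  ny <- slices[[1]]$nrow
  data <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (s$ncol != nx || s$nrow != ny)
      stop_murinod("mixed_series", "Slices disagree on matrix size.")
    data[, , k] <- s$slope * s$pixels + s$intercept
  }
  vol_image(
    data = data,
    # PixelSpacing is (row spacing = dy, column spacing = dx)
    spacing = c(slices[[1]]$pixel_spacing[2], slices[[1]]$pixel_spacing[1], dz),
    origin = slices[[1]]$position
  )
}

# Minimal explicit-VR little-endian single-frame CT parser: walks the data
# elements after the 128-byte preamble + "DICM" and keeps only the tags the
# volume model needs.  Long-form VRs (OB/OW/OF/SQ/UT/UN) carry 2 reserved
# bytes and a 32-bit length; all others a 16-bit length.
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop_murinod("format", paste0("Not a DICOM part-10 file: ", path))
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  out <- list(slope = 1, intercept = 0)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); body <- pos + 12L
    } else {
      len <- u16(pos + 6L); body <- pos + 8L
    }
    val_raw <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
    str_val <- function() trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
    ds_val <- function() as.double(strsplit(str_val(), "\\\\")[[1]])
    if (group == 0x0002L && elem == 0x0010L) {
      ts <- str_val()
      if (ts != "1.2.840.10008.1.2.1")
        stop_murinod("format", paste0("Unsupported transfer syntax: ", ts))
    } else if (group == 0x0020L && elem == 0x000EL) {
      out$series_uid <- str_val()
    } else if (group == 0x0020L && elem == 0x0032L) {
      out$position <- ds_val()
    } else if (group == 0x0020L && elem == 0x0037L) {
      out$orientation <- ds_val()
    } else if (group == 0x0028L && elem == 0x0010L) {
      out$nrow <- u16(body)
    } else if (group == 0x0028L && elem == 0x0011L) {
      out$ncol <- u16(body)
    } else if (group == 0x0028L && elem == 0x0030L) {
      out$pixel_spacing <- ds_val()
    } else if (group == 0x0028L && elem == 0x0100L) {
      out$bits <- u16(body)
    } else if (group == 0x0028L && elem == 0x0103L) {
      out$signed <- u16(body) == 1L
    } else if (group == 0x0028L && elem == 0x1052L) {
      out$intercept <- ds_val()
    } else if (group == 0x0028L && elem == 0x1053L) {
      out$slope <- ds_val()
    } else if (group == 0x7FE0L && elem == 0x0010L) {
      if (is.null(out$bits) || out$bits != 16L)
        stop_murinod("format", "Only 16-bit pixel data is supported.")
      n <- len %/% 2L
      px <- readBin(val_raw, "integer", n = n, size = 2, endian = "little",
                    signed = isTRUE(out$signed))
      # pixels run row by row, column index fastest -> (x, y) array
      out$pixels <- matrix(px, nrow = out$ncol, ncol = out$nrow)
    }
    pos <- body + len
  }
  needed <- c("series_uid", "position", "orientation", "nrow", "ncol",
              "pixel_spacing", "pixels")
  missing <- setdiff(needed, names(out))
  if (length(missing))
    stop_murinod("format", paste0("DICOM file ", path, " lacks required tags: ",
                                  paste(missing, collapse = ", ")))
  out
}

#' Density statistics over a region
#'
#' Mean and sample standard deviation (n - 1 denominator) of the voxel
#' densities under a mask — the quality-control computation used on
#' calibration phantoms of known density (air, water, bone rods scanned
#' alongside the animal).
#'
#' @param img A [vol_image].
#' @param region_mask Logical array with the same dimensions as `img`, or
#'   `NULL` for the whole volume.
#' @return A one-row tibble with columns `mean_hu`, `sd_hu`, `n`.
#' @examples
#' img <- vol_image(array(100, c(5, 5, 5)))
#' sample_density_stats(img)
#' @export
sample_density_stats <- function(img, region_mask = NULL) {
  vals <- masked_values(img, region_mask)
  tibble(
    mean_hu = mean(vals),
    sd_hu = if (length(vals) > 1L) sd(vals) else 0,
    n = length(vals)
  )
}

#' Density histogram over a region
#'
#' Histogram of masked voxel densities with bins of constant width aligned
#' to multiples of `bin_width` (so binning is independent of data order and
#' of the exact data range).  The density histogram of a thoracic region of
#' interest is the input to the adaptive bimodal threshold.
#'
#' @inheritParams sample_density_stats
#' @param bin_width Bin width in HU (default 10).
#' @return A tibble of class `density_histogram` with columns `bin_start`,
#'   `bin_end`, `bin_mid` (HU) and `count`; total count equals the number
#'   of masked voxels.
#' @export
density_histogram <- function(img, region_mask = NULL, bin_width = 10) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop_murinod("value", "`bin_width` must be a single positive number (HU).")
  vals <- masked_values(img, region_mask)
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  nb <- round((hi - lo) / bin_width)
  idx <- pmin(floor((vals - lo) / bin_width) + 1, nb)
  counts <- tabulate(idx, nbins = nb)
  out <- tibble(
    bin_start = lo + (seq_len(nb) - 1) * bin_width,
    bin_end = lo + seq_len(nb) * bin_width,
    bin_mid = lo + (seq_len(nb) - 0.5) * bin_width,
    count = counts
  )
  attr(out, "bin_width") <- bin_width
  class(out) <- c("density_histogram", class(out))
  out
}

masked_values <- function(img, region_mask) {
  stopifnot(inherits(img, "vol_image"))
  if (is.null(region_mask)) return(as.double(img$data))
  if (!identical(dim(region_mask), dim(img$data)))
    stop_murinod("value", "`region_mask` must match the image dimensions.")
  mask <- as.logical(region_mask)
  if (!any(mask))
    stop_murinod("empty_region", "The region mask selects no voxels.")
  as.double(img$data[mask])
}

#' @export
autoplot.density_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey40") +
    ggplot2::labs(x = "Density (HU)", y = "Voxel count") +
    ggplot2::theme_minimal()
}
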