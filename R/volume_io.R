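#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of Hounsfield-unit (HU) values indexed as
#' `(slice, row, col)` — the slice axis is the axial (z) direction — together
#' with the voxel spacing in millimetres, the physical origin, and scan
#' metadata. All thresholds in the pipeline (for example the −825 HU
#' air-density cutoff) are expressed in HU, so voxel values are stored as
#' floating point after any acquisition rescale and no display windowing is
#' ever applied at I/O time.
#'
#' @param voxels 3-D numeric array of HU values, dimension
#'   `(n_slice, n_row, n_col)`. At least 3 slices are required because the
#'   3-D mean CT value correlation feature needs slices `n - 1`, `n`, `n + 1`.
#' @param spacing_mm Numeric length-3: `(slice_increment, row, col)` spacing
#'   in mm, all strictly positive. Typical acquisition geometry is a 1.25 mm
#'   slice increment on a 512 × 512 matrix with 0.635–0.773 mm pixels.
#' @param origin_mm Physical origin of voxel `(1, 1, 1)`; default `c(0, 0, 0)`.
#' @param scan_id Identifier for the scan (e.g. `"scan1"` for admission).
#' @param acquisition_time Optional acquisition timestamp (kept verbatim).
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(-850, c(3, 4, 4)), spacing_mm = c(1.25, 0.7, 0.7))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                      scan_id = "scan", acquisition_time = NULL) {
  dm <- as_dim3(voxels)
  if (dm[1] < 3L) {
    stop("a ct_volume needs at least 3 slices (slice-neighbour features)",
         call. = FALSE)
  }
  if (!all(is.finite(voxels))) stop("voxels must be finite", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive numbers (slice, row, col)",
         call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), scan_id = scan_id,
         acquisition_time = acquisition_time),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  dm <- dim(x$voxels)
  cat(sprintf("<ct_volume '%s'> %d x %d x %d voxels (slice, row, col)\n",
              x$scan_id, dm[1], dm[2], dm[3]))
  cat(sprintf("  spacing %.3f x %.3f x %.3f mm; HU range [%.0f, %.0f]\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask aligned to a CT volume
#'
#' Masks carry a `role` naming their place in the pipeline: the grown lung
#' (`"lung"`), the raw neural-network output (`"injured_candidate"`), the
#' vesselness segmentation (`"vessel"`), or the post-processed injury map
#' (`"injured_final"`). After the pipeline completes, injured masks are always
#' subsets of the lung mask.
#'
#' @param bits Logical 3-D array, same shape as the source volume.
#' @param role One of `"lung"`, `"injured_candidate"`, `"vessel"`,
#'   `"injured_final"`.
#' @param spacing_mm Voxel spacing in mm, usually inherited from the volume.
#' @param source_scan_id Identifier of the scan the mask belongs to.
#' @return An object of class `pq_mask`.
#' @export
binary_mask <- function(bits, role = c("lung", "injured_candidate", "vessel",
                                       "injured_final"),
                        spacing_mm = NULL, source_scan_id = "scan") {
  role <- match.arg(role)
  dm <- as_dim3(bits)
  bits <- array(as.logical(bits), dim = dm)
  if (anyNA(bits)) stop("mask bits must not contain NA", call. = FALSE)
  structure(
    list(bits = bits, role = role, spacing_mm = spacing_mm,
         source_scan_id = source_scan_id),
    class = "pq_mask"
  )
}

#' @export
print.pq_mask <- function(x, ...) {
  dm <- dim(x$bits)
  cat(sprintf("<pq_mask role='%s'> %d x %d x %d, %d voxels set (%.1f%%)\n",
              x$role, dm[1], dm[2], dm[3], sum(x$bits),
              100 * mean(x$bits)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param spacing_mm Length-3 spacing in mm.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(spacing_mm) prod(as.numeric(spacing_mm))

#' Convert stored scanner values to Hounsfield units
#'
#' Applies the linear acquisition rescale `HU = slope * stored + intercept`
#' (the DICOM rescale contract; e.g. a stored value of 1024 with slope 1 and
#' intercept −1024 maps to 0 HU, water).
#'
#' @param stored Numeric stored values.
#' @param slope,intercept Rescale slope and intercept from the acquisition
#'   headers.
#' @return Numeric HU values.
#' @export
apply_rescale <- function(stored, slope, intercept) {
  if (!is.finite(slope) || !is.finite(intercept)) {
    stop("missing or non-finite rescale slope/intercept", call. = FALSE)
  }
  slope * stored + intercept
}

#' Stack individual axial slices into a CT volume
#'
#' Mirrors how an axial series is assembled from per-slice files: slices are
#' ordered by their physical position along the scan axis, stored values are
#' converted to HU through the rescale slope/intercept, and the slice spacing
#' must be uniform.
#'
#' @param slices List of 2-D matrices of stored values (equal dimensions).
#' @param positions_mm Numeric slice positions along the axial direction, one
#'   per slice; any order (slices are sorted by position).
#' @param pixel_spacing_mm Length-2 in-plane spacing `(row, col)` in mm.
#' @param slope,intercept Rescale parameters applied to every slice.
#' @param tol Relative tolerance on slice-spacing uniformity (default 1e-3).
#' @inheritParams ct_volume
#' @return A [ct_volume()].
#' @export
stack_slices <- function(slices, positions_mm, pixel_spacing_mm,
                         slope = 1, intercept = 0, tol = 1e-3,
                         scan_id = "scan") {
  if (length(slices) != length(positions_mm)) {
    stop("one position per slice required", call. = FALSE)
  }
  if (length(slices) < 3L) stop("need at least 3 slices", call. = FALSE)
  dims <- vapply(slices, function(s) dim(s), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed series: slice matrices differ in size", call. = FALSE)
  }
  ord <- order(positions_mm)
  gaps <- diff(positions_mm[ord])
  if (any(gaps <= 0)) stop("duplicate slice positions", call. = FALSE)
  if ((max(gaps) - min(gaps)) / mean(gaps) > tol) {
    stop(sprintf(
      "non-uniform slice spacing beyond tolerance: gaps range %.4g-%.4g mm",
      min(gaps), max(gaps)), call. = FALSE)
  }
  vox <- array(NA_real_, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (i in seq_along(ord)) {
    vox[i, , ] <- apply_rescale(slices[[ord[i]]], slope, intercept)
  }
  ct_volume(vox, spacing_mm = c(mean(gaps), pixel_spacing_mm),
            origin_mm = c(min(positions_mm), 0, 0), scan_id = scan_id)
}

#' Read a CT volume from disk
#'
#' Reads a volumetric NIfTI file (`.nii` / `.nii.gz`); any NIfTI intensity
#' scaling in the header is applied by the reader, so the returned voxels are
#' in HU. DICOM series directories are not supported in this implementation —
#' convert the series to NIfTI first (e.g. with `dcm2niix`); a directory
#' argument raises a descriptive error.
#'
#' Files written by [write_ct_volume()] store the array in `(x, y, z)` disk
#' order with matching pixdim, and reading restores the package's
#' `(slice, row, col)` convention.
#'
#' @param path Path to a NIfTI file.
#' @param scan_id Identifier attached to the returned volume.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, scan_id = NULL) {
  if (dir.exists(path)) {
    stop("'", path, "' is a directory: DICOM series input is not supported; ",
         "convert the series to a NIfTI volume first", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a single 3-D volume in ", path, call. = FALSE)
  }
  sp <- RNifti::pixdim(img)
  vox <- aperm(arr, c(3, 2, 1))
  attributes(vox) <- list(dim = dim(vox))
  ct_volume(vox, spacing_mm = rev(sp[1:3]),
            scan_id = scan_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write a CT volume to a NIfTI file
#'
#' @param volume A [ct_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as 0/1 NIfTI volumes with a JSON sidecar
#' (`<path>.json`) holding the mask role and source scan id, so the
#' round-trip is lossless for bits, shape, spacing and role.
#'
#' @param mask A [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param reference Optional [ct_volume()] whose shape the mask must match.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   [binary_mask()].
#' @export
write_mask <- function(mask, path, reference = NULL) {
  stopifnot(inherits(mask, "pq_mask"))
  if (!is.null(reference) &&
      !identical(dim(mask$bits), dim(reference$voxels))) {
    stop("mask shape does not match the reference volume", call. = FALSE)
  }
  arr <- aperm(array(as.integer(mask$bits), dim = dim(mask$bits)), c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  if (!is.null(mask$spacing_mm)) RNifti::pixdim(img) <- rev(mask$spacing_mm)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(role = mask$role, source_scan_id = mask$source_scan_id),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  arr <- aperm(as.array(img), c(3, 2, 1))
  attributes(arr) <- list(dim = dim(arr))
  meta <- list(role = "lung", source_scan_id = "scan")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  m <- binary_mask(arr != 0, role = meta$role,
                   spacing_mm = rev(RNifti::pixdim(img)[1:3]),
                   source_scan_id = meta$source_scan_id)
  if (!is.null(reference) &&
      !identical(dim(m$bits), dim(reference$voxels))) {
    stop("mask shape does not match the reference volume", call. = FALSE)
  }
  m
}
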