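#' 3-D scalar volume with voxel spacing
#'
#' `volume3d()` wraps a numeric 3-D array together with its voxel spacing in
#' millimetres and acquisition metadata (modality, echo time). It is the unit
#' consumed by every quantification stage: histogram thresholding, PET uptake
#' and registration. Voxel index `(i, j, k)` (1-based) has its centre at world
#' coordinate `(i - 0.5, j - 0.5, k - 0.5) * voxel_mm` (mm).
#'
#' @param data numeric 3-D array of intensities (finite).
#' @param voxel_mm positive numeric triple, voxel edge lengths in mm.
#' @param modality one of `"MRI"`, `"PET"`, `"CT"`.
#' @param echo_time_ms optional echo time in ms (e.g. 0.324 for the short and
#'   1.0 for the long UTE echo).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_mm, modality = c("MRI", "PET", "CT"),
                     echo_time_ms = NULL) {
  modality <- match.arg(modality)
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("volume3d requires a 3-D array, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data)))
    stop("volume intensities must be finite")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel_mm must be a positive triple")
  structure(data,
            voxel_mm = voxel_mm,
            modality = modality,
            echo_time_ms = echo_time_ms,
            class = c("volume3d", "array"))
}

#' Binary lung region-of-interest mask
#'
#' The lung ROI excludes the heart and great vessels; masks are inputs to the
#' pipeline (drawn upstream), and every histogram and uptake computation is
#' restricted to in-mask voxels.
#'
#' @param mask logical (or 0/1) 3-D array.
#' @param voxel_mm positive numeric triple (mm); must match the companion
#'   volume's spacing.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(mask, voxel_mm) {
  m <- unclass(mask)
  if (length(dim(m)) != 3L) stop("lung_mask requires a 3-D array")
  storage.mode(m) <- "logical"
  if (anyNA(m)) stop("mask must not contain NA")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be a positive triple")
  structure(m, voxel_mm = voxel_mm, class = c("lung_mask", "array"))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume3d> %s%s  %d x %d x %d voxels @ %s mm\n",
              attr(x, "modality"),
              if (!is.null(attr(x, "echo_time_ms")))
                sprintf(" (TE %.3g ms)", attr(x, "echo_time_ms")) else "",
              d[1], d[2], d[3],
              paste(signif(attr(x, "voxel_mm"), 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lung_mask> %d x %d x %d voxels @ %s mm, %d in-mask (%.1f%%)\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "voxel_mm"), 4), collapse = " x "),
              sum(x), 100 * mean(x)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param x a `volume3d` or `lung_mask`.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(x) prod(attr(x, "voxel_mm"))

#' Total mask volume in cubic millimetres
#' @param mask a `lung_mask`.
#' @return scalar mm^3.
#' @export
mask_volume_mm3 <- function(mask) sum(mask) * voxel_volume_mm3(mask)

check_congruent <- function(vol, mask) {
  if (!identical(dim(unclass(vol)), dim(unclass(mask))))
    stop("volume and mask grids are not congruent: ",
         paste(dim(vol), collapse = "x"), " vs ", paste(dim(mask), collapse = "x"))
  if (max(abs(attr(vol, "voxel_mm") - attr(mask, "voxel_mm"))) > 1e-9)
    stop("volume and mask voxel spacings differ")
  invisible(TRUE)
}

#' Read a single 3-D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` / `.nii.gz` file holding one scalar 3-D volume.
#' @param modality,echo_time_ms metadata attached to the returned volume (NIfTI
#'   itself does not carry them).
#' @return a [volume3d()].
#' @export
read_volume <- function(path, modality = "MRI", echo_time_ms = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a single 3-D volume, got ", length(d), "-D data in ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or invalid voxel spacing in ", path)
  volume3d(array(as.numeric(img), dim = d), voxel_mm = sp[1:3],
           modality = modality, echo_time_ms = echo_time_ms)
}

#' Write a volume (or mask) to a NIfTI-1 file
#'
#' The voxel spacing is stored in the NIfTI `pixdim`; a round trip through
#' [write_volume()] / [read_volume()] preserves grid, values and spacing.
#'
#' @param vol a `volume3d` or `lung_mask`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- unclass(vol)
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- attr(vol, "voxel_mm")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary lung mask from NIfTI
#' @param path NIfTI file with values 0/1.
#' @return a [lung_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  lung_mask(unclass(v) > 0.5, attr(v, "voxel_mm"))
}

#' Per-scan acquisition metadata
#'
#' Reads the cohort metadata CSV with columns exactly
#' `animal_id, group, day, dose_MBq, t_injection_iso8601, t_scan_iso8601`.
#'
#' @param path CSV path.
#' @return data.frame with parsed POSIXct injection/scan times.
#' @export
read_scan_meta <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "dose_MBq",
            "t_injection_iso8601", "t_scan_iso8601")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata CSV missing columns: ", paste(miss, collapse = ", "))
  m$t_injection <- as.POSIXct(m$t_injection_iso8601, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  m$t_scan <- as.POSIXct(m$t_scan_iso8601, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(m$t_injection) || anyNA(m$t_scan))
    stop("could not parse ISO8601 times in ", path)
  if (any(m$t_scan < m$t_injection)) stop("t_scan before t_injection in ", path)
  if (any(m$dose_MBq <= 0)) stop("non-positive dose_MBq in ", path)
  m
}
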