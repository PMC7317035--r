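# Vectorised 3-D interpolation on voxel-index coordinates (1-based, continuous;
# index i has its sample point at the voxel centre). Shared by isotropic
# resampling and rigid registration.

# arr: 3-D array; idx: n x 3 matrix of continuous 1-based indices.
# outside = "na": points beyond the grid return NA; "clamp": edge extension.
interp_trilinear <- function(arr, idx, outside = c("na", "clamp")) {
  outside <- match.arg(outside)
  d <- dim(arr)
  out_na <- NULL
  if (outside == "na") {
    out_na <- idx[, 1] < 1 | idx[, 1] > d[1] |
              idx[, 2] < 1 | idx[, 2] > d[2] |
              idx[, 3] < 1 | idx[, 3] > d[3]
  }
  x <- pmin(pmax(idx[, 1], 1), d[1])
  y <- pmin(pmax(idx[, 2], 1), d[2])
  z <- pmin(pmax(idx[, 3], 1), d[3])
  i0 <- pmin(floor(x), d[1] - 1L); fx <- x - i0
  j0 <- pmin(floor(y), d[2] - 1L); fy <- y - j0
  k0 <- pmin(floor(z), d[3] - 1L); fz <- z - k0
  if (d[1] == 1L) { i0 <- rep(1, length(x)); fx <- 0 }
  if (d[2] == 1L) { j0 <- rep(1, length(y)); fy <- 0 }
  if (d[3] == 1L) { k0 <- rep(1, length(z)); fz <- 0 }
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- (i0) + (j0 - 1) * s1 + (k0 - 1) * s2
  di <- min(1L, d[1] - 1L); dj <- min(1L, d[2] - 1L) * s1; dk <- min(1L, d[3] - 1L) * s2
  v <- arr[base]           * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[base + di]      * fx       * (1 - fy) * (1 - fz) +
       arr[base + dj]      * (1 - fx) * fy       * (1 - fz) +
       arr[base + di + dj] * fx       * fy       * (1 - fz) +
       arr[base + dk]      * (1 - fx) * (1 - fy) * fz +
       arr[base + di + dk] * fx       * (1 - fy) * fz +
       arr[base + dj + dk] * (1 - fx) * fy       * fz +
       arr[base + di + dj + dk] * fx  * fy       * fz
  if (!is.null(out_na)) v[out_na] <- NA_real_
  v
}

interp_nearest <- function(arr, idx, outside = c("na", "clamp")) {
  outside <- match.arg(outside)
  d <- dim(arr)
  out_na <- NULL
  if (outside == "na") {
    out_na <- idx[, 1] < 0.5 | idx[, 1] > d[1] + 0.5 |
              idx[, 2] < 0.5 | idx[, 2] > d[2] + 0.5 |
              idx[, 3] < 0.5 | idx[, 3] > d[3] + 0.5
  }
  i <- pmin(pmax(round(idx[, 1]), 1), d[1])
  j <- pmin(pmax(round(idx[, 2]), 1), d[2])
  k <- pmin(pmax(round(idx[, 3]), 1), d[3])
  v <- arr[i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]]
  if (!is.null(out_na)) v[out_na] <- NA
  v
}

# Voxel-centre world coordinates (mm) of a grid, as an n x 3 matrix in
# column-major voxel order.
grid_world_coords <- function(dims, voxel_mm, stride = 1L) {
  ax <- lapply(1:3, function(a) seq(1L, dims[a], by = stride))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  sweep(g - 0.5, 2, voxel_mm, `*`)
}

#' Resample a volume or mask to isotropic voxels
#'
#' Cross-modality work (PET onto MRI) requires a common isotropic grid; the
#' default target of 0.4 mm matches the PET reconstruction grid so PET is never
#' up-interpolated. The world-space extent of the grid is preserved to within
#' one voxel; output voxel `i` samples the input at the world coordinate of its
#' centre. Masks must use `order = "nearest"` so they stay binary.
#'
#' @param vol a `volume3d` or `lung_mask`.
#' @param target_mm positive scalar, isotropic voxel size of the output (mm).
#' @param order `"trilinear"` (intensities) or `"nearest"` (labels/masks);
#'   defaults to `"nearest"` for `lung_mask` input.
#' @return resampled object of the same class as `vol`.
#' @export
resample_isotropic <- function(vol, target_mm = 0.4,
                               order = c("trilinear", "nearest")) {
  if (length(target_mm) != 1L || !is.finite(target_mm) || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  is_mask <- inherits(vol, "lung_mask")
  if (is_mask && missing(order)) order <- "nearest"
  order <- match.arg(order)
  sp <- attr(vol, "voxel_mm")
  d <- dim(vol)
  extent <- d * sp
  nd <- pmax(1L, as.integer(round(extent / target_mm)))
  # world coords of output voxel centres -> continuous input indices
  coords <- grid_world_coords(nd, rep(target_mm, 3))
  idx <- sweep(coords, 2, sp, `/`) + 0.5
  arr <- unclass(vol)
  if (is_mask) storage.mode(arr) <- "double"
  vals <- if (order == "trilinear") interp_trilinear(arr, idx, outside = "clamp")
          else interp_nearest(arr, idx, outside = "clamp")
  out <- array(vals, dim = nd)
  if (is_mask)
    lung_mask(out > 0.5, rep(target_mm, 3))
  else
    volume3d(out, rep(target_mm, 3), modality = attr(vol, "modality"),
             echo_time_ms = attr(vol, "echo_time_ms"))
}
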