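# FDG-PET quantification: decay correction of the injected dose, rigid
# mutual-information registration of PET onto the MRI frame, and fractional
# uptake within the lung ROI (dose-fraction, not SUV).

#' Injected tracer dose record
#'
#' @param injected_MBq injected activity in MBq (> 0; study protocol
#'   30 +- 5 MBq).
#' @param t_injection,t_reference injection and reference (scan) clock times:
#'   `POSIXct`, or strings `"HH:MM:SS"` / ISO8601, or numeric minutes.
#' @param half_life_min isotope half-life in minutes; default 109.77 (18F).
#' @return object of class `tracer_dose`.
#' @export
tracer_dose <- function(injected_MBq, t_injection, t_reference,
                        half_life_min = 109.77) {
  if (!is.finite(injected_MBq) || injected_MBq <= 0)
    stop("injected_MBq must be positive")
  if (half_life_min <= 0) stop("half_life_min must be positive")
  dt <- minutes_between(t_injection, t_reference)
  if (dt < 0) stop("t_reference precedes t_injection")
  structure(list(injected_MBq = injected_MBq, t_injection = t_injection,
                 t_reference = t_reference, delta_min = dt,
                 half_life_min = half_life_min),
            class = "tracer_dose")
}

minutes_between <- function(t0, t1) {
  parse1 <- function(t) {
    if (inherits(t, "POSIXct")) return(as.numeric(t) / 60)
    if (is.numeric(t)) return(t)
    if (is.character(t)) {
      p <- if (grepl("T", t)) as.POSIXct(t, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
           else as.POSIXct(t, format = "%H:%M:%S", tz = "UTC")
      if (is.na(p)) stop("cannot parse clock time: ", t)
      return(as.numeric(p) / 60)
    }
    stop("unsupported time representation")
  }
  parse1(t1) - parse1(t0)
}

#' Decay-correct the injected dose to the scan time
#'
#' Radioactive decay between injection and the reference time reduces the
#' activity available: the corrected dose is
#' `injected_MBq * 2^(-dt / half_life)` with `dt` in minutes.
#'
#' @param dose a [tracer_dose()].
#' @return corrected activity in MBq.
#' @export
decay_correct <- function(dose) {
  stopifnot(inherits(dose, "tracer_dose"))
  dose$injected_MBq * 2^(-dose$delta_min / dose$half_life_min)
}

#' Rigid transform (3 rotations + 3 translations about a centre)
#'
#' Maps a point `p` in the fixed frame to `R (p - c) + c + t` in the moving
#' frame, with `R = Rz Ry Rx` built from the rotation angles in degrees. This
#' is the resampling convention: the transform tells each fixed-grid voxel
#' where to look in the moving image.
#'
#' @param rotations_deg numeric triple, rotations about x/y/z in degrees.
#' @param translations_mm numeric triple, mm.
#' @param center_mm rotation centre in world mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations_deg = c(0, 0, 0),
                            translations_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  structure(list(rotations_deg = as.numeric(rotations_deg),
                 translations_mm = as.numeric(translations_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

euler_from_matrix <- function(R) {
  # inverse of Rz(c) Ry(b) Rx(a)
  b <- asin(pmin(pmax(-R[3, 1], -1), 1))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c) * 180 / pi
}

apply_rigid <- function(tf, points) {
  R <- rotation_matrix(tf$rotations_deg)
  ctr <- matrix(tf$center_mm, nrow(points), 3, byrow = TRUE)
  sweep((points - ctr) %*% t(R), 2, tf$center_mm + tf$translations_mm, `+`)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform` (same centre).
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(tf$rotations_deg)
  rigid_transform(rotations_deg = euler_from_matrix(t(R)),
                  translations_mm = as.numeric(-t(R) %*% tf$translations_mm),
                  center_mm = tf$center_mm)
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform`s sharing a centre; returns the transform
#'   equivalent to applying `a` after mapping through `b` i.e. `x -> a(b(x))`.
#' @return a `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  stopifnot(max(abs(a$center_mm - b$center_mm)) < 1e-9)
  Ra <- rotation_matrix(a$rotations_deg)
  Rb <- rotation_matrix(b$rotations_deg)
  # a(b(x)) = Ra(Rb(x-c)+t_b) + c + t_a
  rigid_transform(rotations_deg = euler_from_matrix(Ra %*% Rb),
                  translations_mm = as.numeric(Ra %*% b$translations_mm) + a$translations_mm,
                  center_mm = a$center_mm)
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' For every voxel of `grid`, samples `vol` at the transformed world
#' coordinate (trilinear); points falling outside `vol` become `fill`.
#'
#' @param vol moving `volume3d`.
#' @param tf a [rigid_transform()] mapping grid (fixed) world coordinates into
#'   `vol` (moving) world coordinates.
#' @param grid `volume3d` (or `lung_mask`) defining the output grid; defaults
#'   to `vol`'s own grid.
#' @param fill value for out-of-volume samples.
#' @return `volume3d` on `grid`'s grid.
#' @export
transform_volume <- function(vol, tf, grid = vol, fill = 0) {
  dims <- dim(unclass(grid))
  sp_out <- attr(grid, "voxel_mm")
  sp_in <- attr(vol, "voxel_mm")
  pts <- grid_world_coords(dims, sp_out)
  q <- apply_rigid(tf, pts)
  idx <- sweep(q, 2, sp_in, `/`) + 0.5
  vals <- interp_trilinear(unclass(vol), idx, outside = "na")
  vals[is.na(vals)] <- fill
  volume3d(array(vals, dim = dims), sp_out, modality = attr(vol, "modality"),
           echo_time_ms = attr(vol, "echo_time_ms"))
}

#' Mutual information of two paired intensity samples
#'
#' Estimated from a `bins x bins` joint histogram of min-max scaled
#' intensities (natural log).
#'
#' @param a,b numeric vectors of equal length (NA pairs dropped).
#' @param bins histogram bins per axis (default 32).
#' @return MI in nats.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("too few overlapping samples for MI")
  scale01 <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) stop("no information: constant image")
    (x - r[1]) / (r[2] - r[1])
  }
  ia <- pmin(floor(scale01(a) * bins) + 1L, bins)
  ib <- pmin(floor(scale01(b) * bins) + 1L, bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Rigid mutual-information registration
#'
#' Finds the 6-parameter rigid transform (rotations in degrees, translations
#' in mm, centred on the fixed volume) that maximises the mutual information
#' between the fixed image and the transformed moving image. Optimisation is
#' derivative-free coordinate descent: each iteration is one cycle of
#' golden-section line searches over the six parameters with a shrinking
#' search bracket, capped at `max_iterations` cycles (the protocol cap of
#' 200). The MRI is the fixed image and PET (or CT) the moving image, so the
#' result resamples the moving data onto the MRI frame.
#'
#' @param moving,fixed isotropic `volume3d`s (resample first — see
#'   [resample_isotropic()]).
#' @param max_iterations cap on coordinate-descent cycles (default 200).
#' @param mi_bins joint-histogram bins per axis (default 32).
#' @param sample_stride evaluate MI on every `sample_stride`-th voxel of the
#'   fixed grid along each axis (2 keeps registration fast at phantom scale);
#'   multi-start exploration uses twice this stride before the winner is
#'   refined at `sample_stride`.
#' @param rot_bracket_deg,trans_bracket_mm initial half-widths of the line
#'   search brackets (also the span of the multi-start perturbations).
#' @param n_starts number of seeded starts (identity plus `n_starts - 1`
#'   random perturbations); MI is non-convex for nearly symmetric objects, so
#'   several basins are explored and the best final MI wins.
#' @param seed seed for the multi-start perturbations.
#' @param tol convergence: stop when no parameter moved more than this
#'   (deg/mm) in a full cycle.
#' @return a [rigid_transform()] with attributes `mi` (final value) and
#'   `iterations` (coordinate-descent cycles of the winning refinement).
#' @export
register_rigid_mi <- function(moving, fixed, max_iterations = 200L,
                              mi_bins = 32L, sample_stride = 2L,
                              rot_bracket_deg = 10, trans_bracket_mm = 5,
                              n_starts = 6L, seed = 0L,
                              tol = 0.01) {
  sp_f <- attr(fixed, "voxel_mm"); sp_m <- attr(moving, "voxel_mm")
  if (max(abs(sp_f - sp_f[1])) > 1e-6 || max(abs(sp_m - sp_m[1])) > 1e-6)
    stop("registration requires isotropic volumes; resample_isotropic() first")
  f_arr <- unclass(fixed); m_arr <- unclass(moving)
  if (max(f_arr) <= min(f_arr) || max(m_arr) <= min(m_arr))
    stop("no information: constant image cannot be registered")
  dims <- dim(f_arr)
  center <- dims * sp_f / 2
  make_objective <- function(stride) {
    pts <- grid_world_coords(dims, sp_f, stride = stride)
    ax <- lapply(1:3, function(a) seq(1L, dims[a], by = stride))
    f_vals <- f_arr[as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                                          KEEP.OUT.ATTRS = FALSE))]
    function(par) {
      tf <- rigid_transform(par[1:3], par[4:6], center)
      q <- apply_rigid(tf, pts)
      idx <- sweep(q, 2, sp_m, `/`) + 0.5
      mv <- interp_trilinear(m_arr, idx, outside = "na")
      keep <- !is.na(mv)
      # insufficient overlap: large finite penalty (keeps 1-D minimisers happy)
      if (sum(keep) < length(mv) / 4) return(1e6)
      -mutual_information(f_vals[keep], mv[keep], bins = mi_bins)
    }
  }
  brackets0 <- c(rep(rot_bracket_deg, 3), rep(trans_bracket_mm, 3))
  descend <- function(objective, par, brackets, max_cycles) {
    cur <- objective(par)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      moved <- 0
      for (p in 1:6) {
        f1 <- function(x) { pp <- par; pp[p] <- x; objective(pp) }
        # coarse scan guards against interpolation-induced wiggles in the MI
        # profile; then a bracketed golden-section refine at the best point
        xs <- seq(par[p] - brackets[p], par[p] + brackets[p], length.out = 13L)
        ys <- vapply(xs, f1, numeric(1))
        best <- which.min(ys)
        step <- brackets[p] / 6
        o <- stats::optimize(f1, interval = c(xs[best] - step, xs[best] + step),
                             tol = tol / 2)
        if (o$objective > ys[best]) o <- list(minimum = xs[best], objective = ys[best])
        if (o$objective < cur) {
          moved <- max(moved, abs(o$minimum - par[p]))
          par[p] <- o$minimum
          cur <- o$objective
        }
      }
      if (iter >= max_cycles) break
      if (moved <= tol) {
        # cycle stalled: zoom the line-search brackets in; converged once
        # they are already at their floor
        if (all(brackets <= 10 * tol)) break
        brackets <- pmax(brackets * 0.25, 10 * tol)
      }
    }
    list(par = par, value = cur, iterations = iter)
  }
  n_starts <- max(1L, as.integer(n_starts))
  starts <- matrix(0, n_starts, 6)
  if (n_starts > 1L) {
    starts[-1, ] <- with_seed(seed, matrix(stats::runif(6 * (n_starts - 1L), -1, 1),
                                           n_starts - 1L, 6))
    starts[-1, ] <- sweep(starts[-1, , drop = FALSE], 2, brackets0 / 2, `*`)
  }
  # exploration runs on a coarser sampling for speed, but never with so few
  # points that the 32^2-bin joint histogram becomes unstable
  explore_stride <- as.integer(sample_stride) * 2L
  while (explore_stride > 1L &&
         prod(ceiling(dims / explore_stride)) < 4096) {
    explore_stride <- explore_stride - 1L
  }
  explore <- make_objective(explore_stride)
  coarse <- lapply(seq_len(n_starts), function(i)
    descend(explore, starts[i, ], brackets0, max_cycles = min(8L, max_iterations)))
  ord <- order(vapply(coarse, `[[`, numeric(1), "value"))
  fine <- make_objective(as.integer(sample_stride))
  finalists <- lapply(coarse[ord[seq_len(min(2L, n_starts))]], function(c0)
    descend(fine, c0$par, pmax(brackets0 / 4, 20 * tol),
            max_cycles = max_iterations))
  res <- finalists[[which.min(vapply(finalists, `[[`, numeric(1), "value"))]]
  tf <- rigid_transform(res$par[1:3], res$par[4:6], center)
  attr(tf, "mi") <- -res$value
  attr(tf, "iterations") <- res$iterations
  tf
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%.3f, %.3f, %.3f) deg | trans (%.3f, %.3f, %.3f) mm\n",
              x$rotations_deg[1], x$rotations_deg[2], x$rotations_deg[3],
              x$translations_mm[1], x$translations_mm[2], x$translations_mm[3]))
  if (!is.null(attr(x, "mi")))
    cat(sprintf("  MI %.4f after %d iterations\n", attr(x, "mi"), attr(x, "iterations")))
  invisible(x)
}

#' Fractional FDG uptake within the lung ROI
#'
#' Sums the in-ROI PET activity (after optional rigid resampling onto the
#' mask grid), converts to MBq via `calibration`, and divides by the
#' decay-corrected injected dose: a dimensionless dose fraction, reported
#' both in total and per mm^3 of ROI.
#'
#' @param pet PET `volume3d`, already on the mask grid unless `transform`
#'   is given.
#' @param mask `lung_mask` on the reference (MRI) grid.
#' @param dose a [tracer_dose()].
#' @param calibration scanner calibration, MBq per PET intensity unit per
#'   voxel (phantoms use 1).
#' @param transform optional [rigid_transform()] from [register_rigid_mi()];
#'   when supplied the PET volume is resampled onto the mask grid first.
#' @return object of class `uptake_result`: `fractional_uptake_total`,
#'   `fractional_uptake_per_mm3`, `roi_volume_mm3`, `corrected_dose_MBq`,
#'   `registration`.
#' @export
fractional_uptake <- function(pet, mask, dose, calibration = 1,
                              transform = NULL) {
  if (!is.null(transform))
    pet <- transform_volume(pet, transform,
                            grid = volume3d(array(0, dim(unclass(mask))),
                                            attr(mask, "voxel_mm"), "PET"))
  check_congruent(pet, mask)
  d0 <- decay_correct(dose)
  if (d0 <= 0) stop("decay-corrected dose is zero")
  act <- sum(unclass(pet)[unclass(mask)]) * calibration
  roi <- mask_volume_mm3(mask)
  if (roi <= 0) stop("empty ROI")
  total <- act / d0
  structure(list(fractional_uptake_total = total,
                 fractional_uptake_per_mm3 = total / roi,
                 roi_volume_mm3 = roi,
                 corrected_dose_MBq = d0,
                 registration = transform),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat(sprintf("<uptake_result> total %.4g (dose fraction), %.4g /mm^3 over %.4g mm^3 ROI\n",
              x$fractional_uptake_total, x$fractional_uptake_per_mm3,
              x$roi_volume_mm3))
  invisible(x)
}
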