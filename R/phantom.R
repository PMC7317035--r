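# Synthetic dual-echo MR + PET phantom and longitudinal cohort generator.
#
# The generator is the statistical stand-in for the study's animals (imaging
# data unavailable): an ellipsoidal "lung" embedded in soft tissue, lesions as
# a union of random ellipsoidal blobs inside the lung, in-lung intensities
# drawn from a two-component Gaussian mixture (low-signal parenchyma,
# high-signal lesion), and a PET channel whose activity is elevated inside the
# lesion. Ground truth (masks, volumes, parameters) is returned alongside so
# every quantification stage can be validated against known answers.

#' Specification of a single lung phantom
#'
#' Defaults emulate the imaging geometry of a rat thorax study: a 64^3 grid of
#' 0.4 mm isotropic voxels (the PET reconstruction grid), a lung occupying 30%
#' of the field of view, and parenchyma/lesion intensity modes separated by
#' 10 parenchyma standard deviations — well-separated, as lesions appear
#' against the signal-poor lung on UTE MRI.
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_mm positive triple, voxel size in mm.
#' @param lung_fraction fraction of the grid volume occupied by the lung
#'   ellipsoid, in (0, 1).
#' @param lesion_fraction fraction of lung volume occupied by lesion, in
#'   [0, 0.8).
#' @param mu_low,sigma_low parenchyma intensity mean / sd (arbitrary units).
#' @param mu_high,sigma_high lesion intensity mean / sd; `mu_high > mu_low`.
#' @param pet_background,pet_lesion_gain PET activity per voxel outside /
#'   added inside the lesion (arbitrary calibration; phantoms use 1 unit =
#'   1 MBq-equivalent).
#' @param pet_noise_scale variance-to-mean ratio of the Gaussian PET noise
#'   (desk-scale proxy for Poisson counting noise).
#' @param n_lesion_blobs number of ellipsoidal lesion blobs (1-5).
#' @param fibrosis_component if `TRUE`, one lesion blob is "fibrosis-only":
#'   high-signal on the short echo but parenchyma-like on the long echo,
#'   emulating short-T2* tissue visible only at ultrashort TE. Off by default.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_mm = c(0.4, 0.4, 0.4),
                         lung_fraction = 0.3,
                         lesion_fraction = 0.1,
                         mu_low = 100, sigma_low = 20,
                         mu_high = 300, sigma_high = 25,
                         pet_background = 1, pet_lesion_gain = 4,
                         pet_noise_scale = 0.05,
                         n_lesion_blobs = 3L,
                         fibrosis_component = FALSE,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), voxel_mm = as.numeric(voxel_mm),
               lung_fraction = lung_fraction, lesion_fraction = lesion_fraction,
               mu_low = mu_low, sigma_low = sigma_low,
               mu_high = mu_high, sigma_high = sigma_high,
               pet_background = pet_background, pet_lesion_gain = pet_lesion_gain,
               pet_noise_scale = pet_noise_scale,
               n_lesion_blobs = as.integer(n_lesion_blobs),
               fibrosis_component = isTRUE(fibrosis_component),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 8L))
      stop("grid_shape must be a triple of at least 8 voxels per axis")
    if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
      stop("voxel_mm must be a positive triple")
    if (lung_fraction <= 0 || lung_fraction >= 1)
      stop("lung_fraction must lie in (0, 1)")
    if (lesion_fraction < 0 || lesion_fraction >= 1)
      stop("lesion_fraction must lie in [0, 1)")
    if (mu_high <= mu_low) stop("mu_high must exceed mu_low")
    if (sigma_low <= 0 || sigma_high <= 0) stop("sigmas must be positive")
    if (pet_background < 0 || pet_lesion_gain < 0 || pet_noise_scale < 0)
      stop("PET parameters must be nonnegative")
    if (n_lesion_blobs < 1L || n_lesion_blobs > 5L)
      stop("n_lesion_blobs must be between 1 and 5")
  })
  structure(spec, class = "phantom_spec")
}

# Normalised ellipsoid "radius" of every grid voxel for centre (voxel units)
# and semi-axes: 1 on the surface, < 1 inside.
ellipsoid_radius <- function(dims, center, semi_axes) {
  dx2 <- ((seq_len(dims[1]) - center[1]) / semi_axes[1])^2
  dy2 <- ((seq_len(dims[2]) - center[2]) / semi_axes[2])^2
  dz2 <- ((seq_len(dims[3]) - center[3]) / semi_axes[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

# Max lesion fraction of lung volume the blob construction supports (lesions
# are kept in the lung core so blobs stay clear of the pleural boundary).
.max_lesion_fraction <- 0.8

#' Generate one dual-echo MR + PET lung phantom
#'
#' Builds an ellipsoidal lung (fraction `lung_fraction` of the grid) inside a
#' soft-tissue background, places `n_lesion_blobs` ellipsoidal lesion blobs in
#' the lung core so that the lesion voxel count matches
#' `lesion_fraction * lung voxels` exactly, then draws intensities:
#' parenchyma ~ N(mu_low, sigma_low), lesion ~ N(mu_high, sigma_high), both
#' clamped at 0 (magnitude images are nonnegative); the short echo reuses the
#' same geometry with independent noise. The PET channel is
#' `pet_background + pet_lesion_gain * lesion` plus Gaussian noise with
#' variance proportional to the mean. Identical specs give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return list with class `lung_phantom`: `short`, `long`, `pet`
#'   (`volume3d`), `mask` (`lung_mask`), and `truth` (fields `lesion_mask`,
#'   `true_lesion_volume_mm3`, `true_lung_volume_mm3`,
#'   `true_lesion_volume_short_mm3`, `component_params`).
#' @export
make_lung_phantom <- function(spec = phantom_spec()) {
  spec <- validate_phantom_spec(spec)
  if (spec$lesion_fraction >= .max_lesion_fraction)
    stop(sprintf("lesion_fraction %.3g exceeds the achievable maximum %.2f of lung volume",
                 spec$lesion_fraction, .max_lesion_fraction))
  d <- spec$grid_shape
  vv <- prod(spec$voxel_mm)
  # lung ellipsoid with voxel-volume fraction lung_fraction of the grid:
  # (4/3) pi (r/2)^3 prod(d) = lung_fraction prod(d)  =>  r = (6 f / pi)^(1/3)
  r <- (6 * spec$lung_fraction / pi)^(1 / 3)
  lung_r <- ellipsoid_radius(d, center = (d + 1) / 2, semi_axes = r * d / 2)
  lung <- lung_r <= 1
  n_lung <- sum(lung)
  with_seed(spec$seed, {
    lesion <- array(FALSE, dim = d)
    fibrosis <- array(FALSE, dim = d)
    target <- round(spec$lesion_fraction * n_lung)
    if (target > 0) {
      # Blob centres in the lung core; per-voxel score = min over blobs of the
      # normalised ellipsoid distance; the `target` lowest-scoring lung voxels
      # form the lesion, so the voxel count is met exactly while the shape
      # stays a union of ellipsoidal blobs.
      k <- spec$n_lesion_blobs
      core <- which(lung_r <= 0.6)
      if (length(core) < k) stop("lung too small to place lesion blobs")
      centers <- arrayInd(sample(core, k), .dim = d)
      score <- array(Inf, dim = d)
      blob_id <- array(0L, dim = d)
      for (b in seq_len(k)) {
        ax <- stats::runif(3, 0.6, 1.4)
        ax <- ax / prod(ax)^(1 / 3) * mean(d) / 8   # unit-ish blobs, anisotropic
        sc <- ellipsoid_radius(d, centers[b, ], ax)
        upd <- sc < score
        score[upd] <- sc[upd]
        blob_id[upd] <- b
      }
      score[!lung] <- Inf
      ord <- order(score)[seq_len(target)]
      lesion[ord] <- TRUE
      if (spec$fibrosis_component && k >= 2L)
        fibrosis <- lesion & (blob_id == 1L)
    }
    draw_echo <- function(fib_visible) {
      arr <- array(0, dim = d)
      body <- !lung
      arr[body] <- stats::rnorm(sum(body), (spec$mu_low + spec$mu_high) / 2,
                                spec$sigma_low)
      high <- if (fib_visible) lesion else (lesion & !fibrosis)
      paren <- lung & !high
      arr[paren] <- stats::rnorm(sum(paren), spec$mu_low, spec$sigma_low)
      arr[high] <- stats::rnorm(sum(high), spec$mu_high, spec$sigma_high)
      pmax(arr, 0)
    }
    long_arr <- draw_echo(fib_visible = FALSE)
    short_arr <- draw_echo(fib_visible = TRUE)
    pet_mean <- spec$pet_background + spec$pet_lesion_gain * lesion
    pet_arr <- pet_mean + stats::rnorm(length(pet_mean),
                                       sd = sqrt(spec$pet_noise_scale * pet_mean))
    pet_arr <- array(pmax(pet_arr, 0), dim = d)
    structure(list(
      short = volume3d(short_arr, spec$voxel_mm, "MRI", echo_time_ms = 0.324),
      long = volume3d(long_arr, spec$voxel_mm, "MRI", echo_time_ms = 1.0),
      pet = volume3d(pet_arr, spec$voxel_mm, "PET"),
      mask = lung_mask(lung, spec$voxel_mm),
      truth = list(
        lesion_mask = lung_mask(lesion & !fibrosis, spec$voxel_mm),
        lesion_mask_short = lung_mask(lesion, spec$voxel_mm),
        true_lesion_volume_mm3 = sum(lesion & !fibrosis) * vv,
        true_lesion_volume_short_mm3 = sum(lesion) * vv,
        true_lung_volume_mm3 = n_lung * vv,
        component_params = spec
      )
    ), class = "lung_phantom")
  })
}

#' @export
print.lung_phantom <- function(x, ...) {
  cat(sprintf("<lung_phantom> lung %.4g mm^3, lesion %.4g mm^3 (%.1f%% of lung)\n",
              x$truth$true_lung_volume_mm3, x$truth$true_lesion_volume_mm3,
              100 * x$truth$true_lesion_volume_mm3 / x$truth$true_lung_volume_mm3))
  invisible(x)
}

#' Specification of a longitudinal synthetic cohort
#'
#' Arm sizes default to the study design this generator emulates: 4 saline
#' controls and 8 bleomycin-challenged animals that split into 4 low- and 4
#' high-responders, imaged at days 0/3/7/14/21/28. Control lung volume grows
#' linearly with age; both bleomycin arms share an inflammation bump peaking
#' at `inflammation_peak_day`; after day 14 the low arm resolves toward the
#' control trajectory (relative day-28 growth `low_final_gain`) while the high
#' arm progresses to `high_final_gain`.
#'
#' @param n_control,n_low,n_high arm sizes (`n_control >= 1`; bleomycin arms
#'   may be 0).
#' @param days strictly increasing integer vector containing 0.
#' @param growth_rate control lung-volume growth per day (fraction of
#'   baseline; default 0.0018/day, i.e. about +5% by day 28).
#' @param inflammation_peak_day day of peak oedema/lesion burden.
#' @param high_final_gain,low_final_gain V(final)/V(baseline) design targets
#'   for the two bleomycin arms; `high_final_gain > low_final_gain >= 1`.
#' @param inflammation_amplitude peak relative lung-volume elevation during
#'   inflammation (fraction of baseline).
#' @param peak_lesion_fraction lesion fraction of lung volume at the
#'   inflammation peak.
#' @param baseline_cv between-animal coefficient of variation of baseline
#'   lung size (cancels out of relative-growth statistics; default 0 so that
#'   `noise_cv = 0` is an exactly noiseless cohort).
#' @param noise_cv per-measurement multiplicative noise CV on every recorded
#'   quantity (scan-to-scan variability).
#' @param dose_MBq,dose_sd_MBq injected FDG dose mean / sd (30 +- 5 MBq).
#' @param uptake_time_min,uptake_time_sd_min tracer circulation time before
#'   the PET scan (60 +- 5 min).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 4L, n_low = 4L, n_high = 4L,
                        days = c(0L, 3L, 7L, 14L, 21L, 28L),
                        growth_rate = 0.0018,
                        inflammation_peak_day = 7L,
                        high_final_gain = 1.3, low_final_gain = 1.05,
                        inflammation_amplitude = 0.15,
                        peak_lesion_fraction = 0.1,
                        baseline_cv = 0,
                        noise_cv = 0.05,
                        dose_MBq = 30, dose_sd_MBq = 5,
                        uptake_time_min = 60, uptake_time_sd_min = 5,
                        seed = 1L) {
  spec <- list(n_control = as.integer(n_control), n_low = as.integer(n_low),
               n_high = as.integer(n_high), days = as.integer(days),
               growth_rate = growth_rate,
               inflammation_peak_day = as.integer(inflammation_peak_day),
               high_final_gain = high_final_gain, low_final_gain = low_final_gain,
               inflammation_amplitude = inflammation_amplitude,
               peak_lesion_fraction = peak_lesion_fraction,
               baseline_cv = baseline_cv, noise_cv = noise_cv,
               dose_MBq = dose_MBq, dose_sd_MBq = dose_sd_MBq,
               uptake_time_min = uptake_time_min,
               uptake_time_sd_min = uptake_time_sd_min,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_control < 1L) stop("need at least one control animal")
    if (n_low < 0L || n_high < 0L) stop("arm sizes must be nonnegative")
    if (is.unsorted(days, strictly = TRUE) || !(0L %in% days))
      stop("days must be strictly increasing and contain 0")
    if (!(high_final_gain > low_final_gain && low_final_gain >= 1))
      stop("need high_final_gain > low_final_gain >= 1")
    if (noise_cv < 0 || baseline_cv < 0) stop("CVs must be nonnegative")
    if (peak_lesion_fraction < 0 || peak_lesion_fraction >= .max_lesion_fraction)
      stop("peak_lesion_fraction out of range")
  })
  structure(spec, class = "cohort_spec")
}

# Inflammation bump shape: 0 at day 0, 1 at the peak day, decaying after
# (gamma-like b(t) = (t/p) exp(1 - t/p), squared to sharpen resolution).
inflammation_bump <- function(t, peak) {
  b <- (t / peak) * exp(1 - t / peak)
  b * b
}

# Design (noise-free) relative lung volume and lesion fraction per arm.
cohort_design <- function(spec, arm, t) {
  Tf <- max(spec$days)
  ctrl <- 1 + spec$growth_rate * t
  bump <- inflammation_bump(t, spec$inflammation_peak_day)
  prog <- t / Tf
  if (arm == "control") {
    list(rel_volume = ctrl, lesion_fraction = rep(0, length(t)))
  } else if (arm == "low") {
    cl <- spec$low_final_gain / (1 + spec$growth_rate * Tf) - 1 -
      spec$inflammation_amplitude * inflammation_bump(Tf, spec$inflammation_peak_day)
    list(rel_volume = ctrl * (1 + spec$inflammation_amplitude * bump + cl * prog),
         lesion_fraction = spec$peak_lesion_fraction * bump)
  } else {
    ch <- spec$high_final_gain / (1 + spec$growth_rate * Tf) - 1 -
      spec$inflammation_amplitude * inflammation_bump(Tf, spec$inflammation_peak_day)
    # persistent fibrotic burden: lesions do not resolve in the high arm
    list(rel_volume = ctrl * (1 + spec$inflammation_amplitude * bump + ch * prog),
         lesion_fraction = spec$peak_lesion_fraction * pmax(bump, 0.8 * prog))
  }
}

#' Generate a longitudinal synthetic cohort
#'
#' Produces one row per animal per imaging day with designed lung volume,
#' lesion (high-signal) volume, fractional FDG uptake and PET dose metadata,
#' each perturbed by multiplicative measurement noise of CV `noise_cv`. The
#' designed fractional uptake is the closed form the phantom PET channel
#' implies: `(background * lung voxels + gain * lesion voxels) /
#' decay-corrected dose`. Each row also carries `lung_fraction`,
#' `lesion_fraction` and `phantom_seed`, from which [cohort_phantom()]
#' materialises the corresponding image bundle on demand (volumes are not kept
#' in memory for a whole cohort).
#'
#' @param cspec a [cohort_spec()].
#' @param pspec a [phantom_spec()] providing grid geometry and intensity /
#'   PET parameters; its `lung_fraction` is the day-0 design value.
#' @return data.frame of class `cohort_timecourse` with columns `animal_id`,
#'   `arm` (generative label: control/low/high), `group` (saline/bleomycin),
#'   `day`, `lung_volume_mm3`, `lesion_volume_mm3`,
#'   `high_signal_volume_short_mm3`, `high_signal_volume_long_mm3`,
#'   `fractional_uptake_total`, `dose_MBq`, `uptake_time_min`,
#'   `lung_fraction`, `lesion_fraction`, `phantom_seed`.
#' @export
make_cohort <- function(cspec = cohort_spec(), pspec = phantom_spec()) {
  cspec <- validate_cohort_spec(cspec)
  pspec <- validate_phantom_spec(pspec)
  arms <- c(rep("control", cspec$n_control), rep("low", cspec$n_low),
            rep("high", cspec$n_high))
  n <- length(arms)
  ids <- sprintf("%s%02d", c(control = "C", low = "L", high = "H")[arms],
                 unlist(lapply(table(factor(arms, levels = c("control", "low", "high"))),
                               seq_len)))
  nd <- length(cspec$days)
  grid_vol <- prod(pspec$grid_shape) * prod(pspec$voxel_mm)
  v0_nominal <- pspec$lung_fraction * grid_vol
  with_seed(cspec$seed, {
    size <- 1 + cspec$baseline_cv * stats::rnorm(n)
    rows <- vector("list", n)
    for (a in seq_len(n)) {
      des <- cohort_design(cspec, arms[a], cspec$days)
      v_true <- v0_nominal * size[a] * des$rel_volume
      lf <- des$lesion_fraction
      lesion_true <- v_true * lf
      mnoise <- function() 1 + cspec$noise_cv * stats::rnorm(nd)
      dose <- pmax(stats::rnorm(nd, cspec$dose_MBq, cspec$dose_sd_MBq), 1)
      t_up <- pmax(stats::rnorm(nd, cspec$uptake_time_min, cspec$uptake_time_sd_min), 1)
      dose_corr <- dose * 2^(-t_up / 109.77)
      vvox <- prod(pspec$voxel_mm)
      n_lung <- v_true / vvox
      n_les <- lesion_true / vvox
      uptake_design <- (pspec$pet_background * n_lung +
                          pspec$pet_lesion_gain * n_les) / dose_corr
      rows[[a]] <- data.frame(
        animal_id = ids[a], arm = arms[a],
        group = if (arms[a] == "control") "saline" else "bleomycin",
        day = cspec$days,
        lung_volume_mm3 = v_true * mnoise(),
        lesion_volume_mm3 = lesion_true,
        high_signal_volume_short_mm3 = lesion_true * mnoise(),
        high_signal_volume_long_mm3 = lesion_true * mnoise(),
        fractional_uptake_total = uptake_design * mnoise(),
        dose_MBq = dose, uptake_time_min = t_up,
        lung_fraction = pspec$lung_fraction * size[a] * des$rel_volume,
        lesion_fraction = lf,
        phantom_seed = derive_seeds(cspec$seed + a, nd),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_timecourse", "data.frame")
    out
  })
}

#' Materialise the image bundle for one cohort row
#'
#' @param row one row of a [make_cohort()] data.frame.
#' @param pspec the [phantom_spec()] the cohort was generated with.
#' @return a `lung_phantom` whose lung and lesion fractions match that
#'   animal-day's design.
#' @export
cohort_phantom <- function(row, pspec = phantom_spec()) {
  stopifnot(nrow(row) == 1L)
  spec <- pspec
  spec$lung_fraction <- min(row$lung_fraction, 0.95)
  spec$lesion_fraction <- row$lesion_fraction
  spec$seed <- row$phantom_seed
  make_lung_phantom(validate_phantom_spec(spec))
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference genes have group-independent expected Ct; each target gene's Ct
#' is lowered by its log2 fold-change effect (in cycles) relative to the
#' time-matched control. A per-sample global shift (loading/efficiency)
#' affects all genes of a sample equally and cancels under reference
#' normalisation; Gaussian technical noise is added per well.
#'
#' @param genes character vector of all gene names.
#' @param ref_genes reference gene names (subset of `genes`; the study design
#'   uses five).
#' @param groups data.frame with columns `group`, `day`, `n` — one row per
#'   group x day stratum (a `control` group per day is expected downstream).
#' @param effects data.frame with columns `gene`, `group`, `day`, `log2fc`
#'   giving per-gene effects vs the time-matched control (`day = NA` applies
#'   to all days); genes/groups absent default to 0. Reference genes must not
#'   appear.
#' @param base_ct named numeric of per-gene baseline Cts; defaults to values
#'   drawn uniformly in [18, 28].
#' @param noise_sd technical noise sd in cycles (default 0.3).
#' @param sample_shift_sd sd of the per-sample global Ct shift.
#' @param seed integer RNG seed.
#' @return data.frame of class `ct_table`: `sample_id`, `group`, `day`, one
#'   column per gene.
#' @export
make_qpcr_table <- function(genes, ref_genes,
                            groups = data.frame(group = rep(c("control", "bleomycin"), 2),
                                                day = rep(c(7L, 28L), each = 2),
                                                n = 4L),
                            effects = NULL,
                            base_ct = NULL, noise_sd = 0.3,
                            sample_shift_sd = 0.2, seed = 1L) {
  if (length(ref_genes) < 1L) stop("need at least one reference gene")
  if (!all(ref_genes %in% genes)) stop("ref_genes must be a subset of genes")
  if (!is.null(effects)) {
    if (!all(c("gene", "group", "log2fc") %in% names(effects)))
      stop("effects needs columns gene, group, log2fc (day optional)")
    if (is.null(effects$day)) effects$day <- NA_integer_
    if (any(effects$gene %in% ref_genes))
      stop("effects must not target reference genes")
    if (!all(effects$gene %in% genes))
      stop("effects reference unknown genes")
  }
  with_seed(seed, {
    if (is.null(base_ct)) {
      base_ct <- stats::runif(length(genes), 18, 28)
      names(base_ct) <- genes
    }
    samp <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      data.frame(group = groups$group[i], day = groups$day[i],
                 rep = seq_len(groups$n[i]), stringsAsFactors = FALSE)
    }))
    samp$sample_id <- sprintf("%s_d%d_%02d", samp$group, samp$day, samp$rep)
    ns <- nrow(samp)
    shift <- stats::rnorm(ns, 0, sample_shift_sd)
    ct <- matrix(NA_real_, nrow = ns, ncol = length(genes),
                 dimnames = list(samp$sample_id, genes))
    for (g in genes) {
      eff <- numeric(ns)
      if (!is.null(effects)) {
        sel <- effects[effects$gene == g, , drop = FALSE]
        for (r in seq_len(nrow(sel))) {
          hit <- samp$group == sel$group[r] &
            (is.na(sel$day[r]) | samp$day == sel$day[r])
          eff[hit] <- eff[hit] + sel$log2fc[r]
        }
      }
      ct[, g] <- base_ct[[g]] - eff + shift +
        stats::rnorm(ns, 0, noise_sd)
    }
    out <- cbind(samp[c("sample_id", "group", "day")],
                 as.data.frame(ct, optional = TRUE))
    rownames(out) <- NULL
    class(out) <- c("ct_table", "data.frame")
    attr(out, "ref_genes") <- ref_genes
    out
  })
}
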