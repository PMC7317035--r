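# Histogram-based "high-signal" threshold segmentation.
#
# The lung-ROI intensity histogram of a UTE MR image has a dominant low-signal
# parenchyma mode; injured tissue (oedema, cellular infiltrate, fibrosis)
# appears as a high-signal component to its right. The automatic threshold is
# geometric: locate the first (lowest-intensity) histogram peak, find the point
# of sharpest decline on its right slope, draw the tangent line to the smoothed
# histogram there, and take its x-axis intercept. Everything above that
# intercept is "high-signal" volume.

#' Construct an intensity histogram
#'
#' Low-level constructor used by [build_histogram()] and by tests that build
#' histograms directly from counts. Smoothing is a centred moving average whose
#' window shrinks symmetrically at the edges.
#'
#' @param bin_edges ascending numeric vector of length `length(counts) + 1`;
#'   bins are half-open `[e_i, e_{i+1})`, the last bin closed.
#' @param counts nonnegative integer counts per bin.
#' @param source label for provenance (e.g. `"TE_long"`).
#' @param smooth_window odd integer width (bins) of the moving-average
#'   smoother applied before peak/slope analysis.
#' @return object of class `intensity_histogram` with fields `bin_edges`,
#'   `counts`, `smoothed_counts`, `bin_centers`, `bin_width`, `n_voxels`,
#'   `source`.
#' @export
intensity_histogram <- function(bin_edges, counts, source = "unknown",
                                smooth_window = 5L) {
  bin_edges <- as.numeric(bin_edges)
  counts <- as.numeric(counts)
  if (length(bin_edges) != length(counts) + 1L)
    stop("need length(bin_edges) == length(counts) + 1")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly ascending")
  if (any(counts < 0)) stop("counts must be nonnegative")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be a positive odd integer")
  structure(list(
    bin_edges = bin_edges,
    counts = counts,
    smoothed_counts = moving_average(counts, smooth_window),
    bin_centers = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    bin_width = diff(bin_edges),
    n_voxels = sum(counts),
    source = source,
    smooth_window = smooth_window
  ), class = "intensity_histogram")
}

# Centred moving average; the window is truncated symmetrically-enough at the
# edges (partial windows averaged over available bins) so no bin is lost.
moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %s: %d bins over [%.4g, %.4g], %d voxels\n",
              x$source, length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n_voxels))
  invisible(x)
}

#' Histogram of in-ROI voxel intensities
#'
#' Bins span `[0, r]` where `r` is the in-ROI intensity quantile given by
#' `range_policy` (robust to isolated hot voxels); values above `r` are clipped
#' into the last bin so every in-ROI voxel is counted exactly once.
#'
#' @param vol a `volume3d`.
#' @param mask a nonempty `lung_mask` congruent with `vol`.
#' @param n_bins number of bins (>= 16; default 256).
#' @param range_policy upper-edge rule: `"quantile"` (default, 99.5th
#'   percentile) or `"max"`.
#' @param range optional explicit numeric `c(lo, hi)` overriding
#'   `range_policy` (used e.g. to hold the binning grid fixed across scans).
#' @param smooth_window moving-average window (bins) for `smoothed_counts`.
#' @return an [intensity_histogram()].
#' @export
build_histogram <- function(vol, mask, n_bins = 256L,
                            range_policy = c("quantile", "max"),
                            range = NULL, smooth_window = 5L) {
  range_policy <- match.arg(range_policy)
  check_congruent(vol, mask)
  v <- unclass(vol)[unclass(mask)]
  if (length(v) == 0L) stop("empty mask: no in-ROI voxels to histogram")
  n_bins <- as.integer(n_bins)
  if (n_bins < 16L) stop("n_bins must be >= 16")
  if (is.null(range)) {
    lo <- min(0, min(v))
    hi <- if (range_policy == "quantile") stats::quantile(v, 0.995, names = FALSE)
          else max(v)
    if (hi <= lo) hi <- lo + max(abs(lo), 1) * 1e-6
  } else {
    lo <- range[1]; hi <- range[2]
    if (hi <= lo) stop("invalid explicit range")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bi <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bi, nbins = n_bins)
  src <- if (!is.null(attr(vol, "echo_time_ms")))
    sprintf("%s TE=%.3g ms", attr(vol, "modality"), attr(vol, "echo_time_ms"))
  else attr(vol, "modality")
  intensity_histogram(edges, counts, source = src, smooth_window = smooth_window)
}

# Local maxima of y: higher than the nearest distinct values on both sides,
# boundaries treated as -Inf (so bin 1 of a decreasing histogram qualifies).
# A plateau of equal values that is a maximum is reported once, at its first
# bin (symmetric histograms put a two-bin plateau at the mode).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 2L) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  starts[r$values > left & r$values > right]
}

# Topographic prominence of a local maximum at index i: height minus the
# higher of the two bases, where each side's base is the minimum of y between
# the peak and the nearest strictly higher sample; a side that runs to the
# signal edge without meeting a higher sample contributes no base.
peak_prominence <- function(y, i) {
  n <- length(y)
  h <- y[i]
  side_base <- function(step) {
    j <- i + step
    m <- Inf
    while (j >= 1L && j <= n && y[j] <= h) { m <- min(m, y[j]); j <- j + step }
    if (j < 1L || j > n) -Inf else m
  }
  base <- max(side_base(-1L), side_base(1L))
  if (!is.finite(base)) base <- min(y)   # global maximum: full height
  h - base
}

#' Locate the first histogram peak
#'
#' Returns the lowest-intensity local maximum of the smoothed counts whose
#' topographic prominence is at least `prominence_frac` of the global smoothed
#' maximum. In a lung ROI this is the normal-parenchyma mode (the mask contains
#' no air background, so no zero-intensity mode precedes it). Boundary bin 1 is
#' admitted as a peak.
#'
#' @param h an [intensity_histogram()].
#' @param prominence_frac minimum prominence as a fraction of
#'   `max(smoothed_counts)` (default 0.05).
#' @return integer bin index (1-based) of the first qualifying peak.
#' @export
find_first_peak <- function(h, prominence_frac = 0.05) {
  y <- h$smoothed_counts
  cand <- local_maxima(y)
  if (length(cand) == 0L) stop("degenerate histogram: no local maximum")
  ymax <- max(y)
  ok <- vapply(cand, function(i) peak_prominence(y, i) >= prominence_frac * ymax,
               logical(1))
  if (!any(ok)) stop("degenerate histogram: no peak with sufficient prominence")
  cand[which(ok)[1L]]
}

# Central-difference derivative per *bin*; one-sided at the two ends.
bin_derivative <- function(y) {
  n <- length(y)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- y[2] - y[1]
  d[n] <- y[n] - y[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  d
}

# First local minimum of y strictly right of `from` (<= both neighbours; the
# last bin counts as a minimum when it does not rise). Counting noise dimples
# the slope just right of the mode, so a minimum only qualifies once the curve
# has actually come down: y[j] must sit at least `depth_frac` of the
# peak-to-floor range below the peak value.
first_local_min_after <- function(y, from, depth_frac = 0.05) {
  n <- length(y)
  floor_y <- min(y)
  qualify <- y[from] - depth_frac * (y[from] - floor_y)
  j <- from + 1L
  while (j <= n) {
    left_ok <- y[j] <= y[j - 1]
    right_ok <- (j == n) || (y[j] <= y[j + 1])
    if (left_ok && right_ok && y[j] <= qualify) return(j)
    j <- j + 1L
  }
  NA_integer_
}

#' Find the point of sharpest decline right of the peak
#'
#' Scans bins strictly between the peak and the first subsequent local minimum
#' of the smoothed counts (inclusive) and returns the bin with the most
#' negative central-difference derivative; ties break toward the peak. A local
#' minimum qualifies as the end of the slope only once the smoothed counts
#' have descended at least `depth_frac` of the peak-to-floor range below the
#' peak, so shallow counting-noise dimples on the upper slope do not truncate
#' the search prematurely.
#'
#' @param h an [intensity_histogram()].
#' @param peak bin index returned by [find_first_peak()].
#' @param depth_frac required descent (fraction of the peak-to-minimum count
#'   range) before a local minimum ends the slope; default 0.05.
#' @return integer bin index of the sharpest decline.
#' @export
find_sharpest_decline <- function(h, peak, depth_frac = 0.05) {
  y <- h$smoothed_counts
  n <- length(y)
  if (peak < 1L || peak > n) stop("invalid peak index")
  stop_at <- first_local_min_after(y, peak, depth_frac)
  if (is.na(stop_at)) stop("no declining slope right of the peak")
  cand <- (peak + 1L):stop_at
  d <- bin_derivative(y)[cand]
  if (all(d >= 0)) stop("no declining slope right of the peak")
  cand[which.min(d)]
}

#' Tangent-line x-intercept threshold
#'
#' Draws the tangent to the smoothed histogram at the sharpest-decline bin —
#' the line through `(x0, v)` with the central-difference slope `s` (counts per
#' intensity unit) — and returns its x-axis intercept `x0 - v/s`.
#'
#' @param h an [intensity_histogram()].
#' @param decline bin index from [find_sharpest_decline()].
#' @return the threshold intensity (finite, `> x0` whenever `v > 0`).
#' @export
tangent_threshold <- function(h, decline) {
  y <- h$smoothed_counts
  n <- length(y)
  if (decline < 1L || decline > n) stop("invalid decline index")
  v <- y[decline]
  s <- bin_derivative(y)[decline] / h$bin_width[decline]
  if (!is.finite(s) || s >= 0)
    stop("slope at the decline point is not negative; no tangent intercept")
  h$bin_centers[decline] - v / s
}

#' High-signal volume above a threshold
#'
#' Counts in-ROI voxels with intensity strictly above `threshold` and converts
#' to mm^3. When the threshold provenance (`histogram`, `peak`, `decline`) is
#' supplied the result carries it along.
#'
#' @param vol a `volume3d`.
#' @param mask congruent `lung_mask`.
#' @param threshold finite intensity threshold.
#' @param histogram,peak,decline optional provenance from the threshold chain.
#' @param return_mask if `TRUE`, attach the binary high-signal mask as
#'   `$high_signal_mask`.
#' @return object of class `threshold_result` with `peak_bin_center`,
#'   `decline_bin_center`, `tangent_slope`, `tangent_value`, `threshold`,
#'   `high_signal_voxels`, `high_signal_volume_mm3`, `total_roi_volume_mm3`.
#' @export
high_signal_volume <- function(vol, mask, threshold, histogram = NULL,
                               peak = NULL, decline = NULL, return_mask = FALSE) {
  check_congruent(vol, mask)
  if (!is.finite(threshold)) stop("threshold must be finite")
  m <- unclass(mask)
  v <- unclass(vol)[m]
  vv <- voxel_volume_mm3(vol)
  hs <- sum(v > threshold)
  res <- list(
    peak_bin_center = if (!is.null(peak)) histogram$bin_centers[peak] else NA_real_,
    decline_bin_center = if (!is.null(decline)) histogram$bin_centers[decline] else NA_real_,
    tangent_slope = if (!is.null(decline))
      bin_derivative(histogram$smoothed_counts)[decline] / histogram$bin_width[decline]
      else NA_real_,
    tangent_value = if (!is.null(decline)) histogram$smoothed_counts[decline] else NA_real_,
    threshold = threshold,
    high_signal_voxels = hs,
    high_signal_volume_mm3 = hs * vv,
    total_roi_volume_mm3 = length(v) * vv,
    source = if (!is.null(histogram)) histogram$source else NA_character_
  )
  if (return_mask) {
    hm <- array(FALSE, dim = dim(m))
    hm[m] <- v > threshold
    res$high_signal_mask <- lung_mask(hm, attr(vol, "voxel_mm"))
  }
  structure(res, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(paste0("<threshold_result> %s\n",
                     "  peak %.4g | decline %.4g | threshold %.4g\n",
                     "  high-signal %d voxels = %.4g mm^3 of %.4g mm^3 ROI (%.1f%%)\n"),
              x$source, x$peak_bin_center, x$decline_bin_center, x$threshold,
              x$high_signal_voxels, x$high_signal_volume_mm3,
              x$total_roi_volume_mm3,
              100 * x$high_signal_volume_mm3 / x$total_roi_volume_mm3))
  invisible(x)
}

#' Run the full threshold chain on one volume
#'
#' Convenience wrapper: histogram, first peak, sharpest decline, tangent
#' intercept, high-signal volume.
#'
#' @inheritParams build_histogram
#' @inheritParams find_first_peak
#' @param return_mask attach the binary high-signal mask.
#' @return a `threshold_result`.
#' @export
threshold_scan <- function(vol, mask, n_bins = 256L, smooth_window = 5L,
                           prominence_frac = 0.05,
                           range_policy = "quantile", range = NULL,
                           return_mask = FALSE) {
  h <- build_histogram(vol, mask, n_bins = n_bins, range_policy = range_policy,
                       range = range, smooth_window = smooth_window)
  p <- find_first_peak(h, prominence_frac = prominence_frac)
  d <- find_sharpest_decline(h, p)
  thr <- tangent_threshold(h, d)
  high_signal_volume(vol, mask, thr, histogram = h, peak = p, decline = d,
                     return_mask = return_mask)
}

#' Quantify a dual-echo scan
#'
#' Runs the high-signal threshold chain independently on the short- and
#' long-echo volumes over the same lung ROI, and reports the total lung volume
#' (mask voxel count times voxel volume).
#'
#' @param short_echo,long_echo `volume3d` objects for the two echo times.
#' @param mask congruent `lung_mask`.
#' @param ... passed to [threshold_scan()] (bins, smoothing, prominence).
#' @return list with `short`, `long` (`threshold_result`s) and
#'   `total_lung_volume_mm3`.
#' @export
quantify_scan <- function(short_echo, long_echo, mask, ...) {
  res_short <- tryCatch(threshold_scan(short_echo, mask, ...),
                        error = function(e) stop("short echo: ", conditionMessage(e)))
  res_long <- tryCatch(threshold_scan(long_echo, mask, ...),
                       error = function(e) stop("long echo: ", conditionMessage(e)))
  list(short = res_short, long = res_long,
       total_lung_volume_mm3 = mask_volume_mm3(mask))
}
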