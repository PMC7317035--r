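# Independent brute-force oracles the implementation is checked against.
# These deliberately re-derive everything with plain loops from first
# principles and share no code with the package internals.

# --- histogram threshold chain ------------------------------------------------

# All local maxima of y by exhaustive scan (plateau reported at its first bin,
# boundaries count as lower).
oracle_local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  for (i in seq_len(n)) {
    # nearest distinct neighbour values
    l <- i - 1L
    while (l >= 1L && y[l] == y[i]) l <- l - 1L
    r <- i + 1L
    while (r <= n && y[r] == y[i]) r <- r + 1L
    left_lower <- l < 1L || y[l] < y[i]
    right_lower <- r > n || y[r] < y[i]
    first_of_plateau <- i == 1L || y[i - 1L] != y[i]
    if (left_lower && right_lower && first_of_plateau) out <- c(out, i)
  }
  out
}

oracle_prominence <- function(y, i) {
  n <- length(y)
  h <- y[i]
  walk <- function(step) {
    j <- i + step
    m <- Inf
    while (j >= 1L && j <= n && y[j] <= h) {
      m <- min(m, y[j])
      j <- j + step
    }
    if (j < 1L || j > n) -Inf else m
  }
  base <- max(walk(-1L), walk(1L))
  if (!is.finite(base)) base <- min(y)
  h - base
}

# Full chain: (first peak, sharpest decline, tangent threshold) or an error
# string, computed by exhaustive enumeration over all bins.
oracle_threshold_chain <- function(centers, widths, smoothed,
                                   prominence_frac = 0.05, depth_frac = 0.05) {
  y <- smoothed
  n <- length(y)
  peaks <- oracle_local_maxima(y)
  if (length(peaks) == 0L) return(list(error = "no peak"))
  ymax <- max(y)
  ok <- peaks[vapply(peaks, function(i) oracle_prominence(y, i) >= prominence_frac * ymax,
                     logical(1))]
  if (length(ok) == 0L) return(list(error = "no peak"))
  peak <- min(ok)
  # end of slope: first depth-qualified local minimum right of the peak
  qualify <- y[peak] - depth_frac * (y[peak] - min(y))
  stop_at <- NA_integer_
  for (j in (peak + 1L):n) {
    if (peak + 1L > n) break
    is_min <- y[j] <= y[max(j - 1L, 1L)] && (j == n || y[j] <= y[j + 1L])
    if (is_min && y[j] <= qualify) { stop_at <- j; break }
  }
  if (is.na(stop_at)) return(list(error = "no decline"))
  deriv <- function(j) {
    if (j == 1L) y[2] - y[1]
    else if (j == n) y[n] - y[n - 1]
    else (y[j + 1L] - y[j - 1L]) / 2
  }
  cand <- (peak + 1L):stop_at
  d <- vapply(cand, deriv, numeric(1))
  if (all(d >= 0)) return(list(error = "no decline"))
  decline <- cand[which.min(d)]
  s <- deriv(decline) / widths[decline]
  if (s >= 0) return(list(error = "no decline"))
  list(peak = peak, decline = decline,
       threshold = centers[decline] - y[decline] / s)
}

# Random multimodal test histogram: mixture of 1-3 Gaussian modes, counts
# multinomial-sampled, on 256 bins.
random_mixture_histogram <- function(n_bins = 256L, n_voxels = 5e4) {
  k <- sample(1:3, 1)
  mu <- sort(runif(k, 0.15, 0.85))
  sd_ <- runif(k, 0.02, 0.08)
  w <- runif(k, 0.3, 1); w <- w / sum(w)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  dens <- rowSums(vapply(seq_len(k), function(i) w[i] * dnorm(centers, mu[i], sd_[i]),
                         numeric(n_bins)))
  counts <- as.vector(rmultinom(1, n_voxels, prob = dens + 1e-12))
  intensity_histogram(edges, counts)
}

# --- Mann-Whitney exact enumeration ------------------------------------------

# Exact two-sided p for the rank-sum statistic by enumerating every
# assignment of the pooled values to the first group (no ties assumed).
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}

# --- Spearman hand formula ----------------------------------------------------

oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  1 - 6 * sum((rx - ry)^2) / (length(x) * (length(x)^2 - 1))
}

# --- misc ---------------------------------------------------------------------

make_uniform_volume <- function(value, dims = c(8, 8, 8), voxel = 0.4) {
  volume3d(array(value, dim = dims), rep(voxel, 3), "MRI")
}

make_full_mask <- function(dims = c(8, 8, 8), voxel = 0.4) {
  lung_mask(array(TRUE, dim = dims), rep(voxel, 3))
}
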