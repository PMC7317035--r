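# Longitudinal analysis: high-/low-responder stratification of lung-volume
# trajectories, group statistics and MRI-PET correlation.

#' Classify bleomycin animals into high- and low-responders
#'
#' Computes each animal's relative lung-volume growth
#' `g = V(final day) / V(baseline)` (relative, so animal size cancels). The
#' control arm defines normal growth (mean +- SD); a bleomycin animal is a
#' high-responder when its growth exceeds `mean_control + k * SD_control`
#' (progressive volume increase), otherwise a low-responder (volume returned
#' toward normal). Controls are never labelled high/low; animals missing the
#' baseline or final measurement are flagged `unclassifiable`.
#'
#' @param cohort data.frame with columns `animal_id`, `group`
#'   (`saline`/`control` vs anything else), `day`, `lung_volume_mm3` (e.g. a
#'   [make_cohort()] timecourse).
#' @param k control-referenced z-threshold (default 2).
#' @return data.frame of class `responder_labels`: `animal_id`, `group`,
#'   `label` in `{control, low, high, unclassifiable}`, `growth`; attributes
#'   `threshold`, `control_mean`, `control_sd`, `k`.
#' @export
classify_responders <- function(cohort, k = 2) {
  need <- c("animal_id", "group", "day", "lung_volume_mm3")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing columns: ", paste(miss, collapse = ", "))
  final_day <- max(cohort$day)
  per_animal <- function(df) {
    v0 <- df$lung_volume_mm3[df$day == 0]
    vf <- df$lung_volume_mm3[df$day == final_day]
    if (length(v0) != 1L || length(vf) != 1L || is.na(v0) || is.na(vf))
      return(NA_real_)
    vf / v0
  }
  ids <- unique(cohort$animal_id)
  growth <- vapply(ids, function(id)
    per_animal(cohort[cohort$animal_id == id, , drop = FALSE]), numeric(1))
  grp <- vapply(ids, function(id)
    cohort$group[cohort$animal_id == id][1], character(1))
  is_control <- grp %in% c("saline", "control")
  gc_ <- growth[is_control & !is.na(growth)]
  treated <- !is_control
  thr <- NA_real_
  if (any(treated)) {
    if (length(gc_) < 2L)
      stop("need at least 2 classifiable control animals to define normal growth")
    thr <- mean(gc_) + k * stats::sd(gc_)
  }
  label <- ifelse(is_control, "control",
                  ifelse(is.na(growth), "unclassifiable",
                         ifelse(growth > thr, "high", "low")))
  label[is_control & is.na(growth)] <- "unclassifiable"
  out <- data.frame(animal_id = ids, group = grp, label = label,
                    growth = growth, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "control_mean") <- if (length(gc_)) mean(gc_) else NA_real_
  attr(out, "control_sd") <- if (length(gc_) > 1) stats::sd(gc_) else NA_real_
  attr(out, "k") <- k
  class(out) <- c("responder_labels", "data.frame")
  out
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups differ in length")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ", paste(small, collapse = ", "))
  list(values = values, groups = groups)
}

#' Compare a measurement across groups
#'
#' Two procedures matching the study's reporting conventions:
#' `"anova_bonferroni"` — one-way ANOVA F test across all groups followed by
#' pairwise pooled-variance t tests with Bonferroni correction (raw p times
#' the number of comparisons, capped at 1); `"mann_whitney"` — two-tailed
#' pairwise Mann-Whitney (Wilcoxon rank-sum) tests, using the exact null
#' distribution when the combined sample is at most 20 with no ties and the
#' normal approximation with tie correction otherwise. Significance stars:
#' `*` p<0.05, `**` p<0.01, `***` p<0.001, `****` p<0.0001.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor), each group >= 2
#'   observations.
#' @param method `"anova_bonferroni"` or `"mann_whitney"`.
#' @return list with `method`, `overall` (for ANOVA: F, df, p) and
#'   `pairwise` data.frame (`group1`, `group2`, `statistic`, `p`, `p_adj`,
#'   `stars`).
#' @export
group_compare <- function(values, groups,
                          method = c("anova_bonferroni", "mann_whitney")) {
  method <- match.arg(method)
  g <- check_groups(values, groups)
  values <- g$values; groups <- g$groups
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  if (method == "anova_bonferroni") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    overall <- list(F = an$`F value`[1], df = unname(an$Df),
                    p = an$`Pr(>F)`[1])
    pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                 pool.sd = TRUE)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     statistic = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(m)) {
      p1 <- pairs[1, i]; p2 <- pairs[2, i]
      pv <- pt$p.value[p2, p1]
      if (is.na(pv)) pv <- pt$p.value[p1, p2]
      pw$p[i] <- pv
    }
  } else {
    overall <- NULL
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     statistic = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(m)) {
      x <- values[groups == pairs[1, i]]
      y <- values[groups == pairs[2, i]]
      use_exact <- (length(x) + length(y) <= 20) &&
        !anyDuplicated(c(x, y))
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE))
      pw$statistic[i] <- unname(wt$statistic)  # U for the first sample
      pw$p[i] <- wt$p.value
    }
  }
  pw$p_adj <- if (method == "anova_bonferroni") pmin(pw$p * m, 1) else pw$p
  pw$stars <- stars_for_p(pw$p_adj)
  list(method = method, overall = overall, pairwise = pw)
}

#' Correlate PET uptake with MRI high-signal volume
#'
#' Spearman rank correlation (average ranks for ties) between an MRI
#' high-signal volume column and a PET fractional-uptake column, with an
#' ordinary least-squares line and its R^2 for display — overall or per
#' subgroup (e.g. high-/low-responders).
#'
#' @param data data.frame of paired observations.
#' @param x,y column names (defaults: long-echo high-signal volume vs total
#'   fractional uptake).
#' @param subgroup optional column name; statistics are computed per level as
#'   well as overall.
#' @return data.frame with one row per stratum: `subgroup`, `n`,
#'   `spearman_rho`, `p`, `slope`, `intercept`, `r_squared`, `note` (set when
#'   rho is undefined, e.g. a constant variable).
#' @export
correlate_pet_mri <- function(data, x = "high_signal_volume_long_mm3",
                              y = "fractional_uptake_total",
                              subgroup = NULL) {
  if (!all(c(x, y) %in% names(data))) stop("columns not found: ", x, ", ", y)
  one <- function(df, label) {
    xs <- df[[x]]; ys <- df[[y]]
    keep <- !(is.na(xs) | is.na(ys))
    xs <- xs[keep]; ys <- ys[keep]
    n <- length(xs)
    if (n < 3L)
      return(data.frame(subgroup = label, n = n, spearman_rho = NA_real_,
                        p = NA_real_, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, note = "fewer than 3 pairs",
                        stringsAsFactors = FALSE))
    if (length(unique(xs)) < 2L || length(unique(ys)) < 2L)
      return(data.frame(subgroup = label, n = n, spearman_rho = NA_real_,
                        p = NA_real_, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_,
                        note = "constant variable: rho undefined",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(xs, ys, method = "spearman"))
    fit <- stats::lm(ys ~ xs)
    data.frame(subgroup = label, n = n,
               spearman_rho = unname(ct$estimate), p = ct$p.value,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared,
               note = NA_character_, stringsAsFactors = FALSE)
  }
  out <- one(data, "all")
  if (!is.null(subgroup)) {
    if (!subgroup %in% names(data)) stop("no such subgroup column: ", subgroup)
    for (lev in unique(data[[subgroup]]))
      out <- rbind(out, one(data[data[[subgroup]] == lev, , drop = FALSE], lev))
  }
  rownames(out) <- NULL
  out
}
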