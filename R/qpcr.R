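# Delta-delta-Ct relative gene-expression quantification.
#
# Ct is the PCR cycle at which a gene's amplification crosses threshold: one
# cycle corresponds to a factor of 2 in template abundance, so Ct is already
# a log2-scale quantity. Normalising expression to the geometric mean of the
# reference genes therefore corresponds, on the Ct scale, to subtracting the
# arithmetic mean of the reference Cts.

.default_ref_genes <- c("actb", "b2m", "hprt1", "ldha", "rplp1")

#' Per-sample reference Ct
#'
#' Arithmetic mean of the reference-gene Cts of each sample — the Ct-scale
#' equivalent of the geometric mean of the reference expression levels
#' (2^-Ct). The study design uses five reference genes (beta-actin,
#' beta-2-microglobulin, HPRT1, LDHA, RPLP1); missing reference wells are
#' dropped with a warning, a sample with none errors.
#'
#' @param ct a `ct_table` data.frame (columns `sample_id`, `group`, `day`,
#'   then one column per gene).
#' @param ref_genes reference gene column names.
#' @return named numeric vector, one reference Ct per sample.
#' @export
reference_ct <- function(ct, ref_genes = attr(ct, "ref_genes") %||% .default_ref_genes) {
  if (length(ref_genes) < 1L) stop("need at least one reference gene")
  miss <- setdiff(ref_genes, names(ct))
  if (length(miss)) stop("reference genes absent from table: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(ct[, ref_genes, drop = FALSE])
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok == 0L))
    stop("all reference genes missing for sample(s): ",
         paste(ct$sample_id[n_ok == 0L], collapse = ", "))
  if (any(n_ok < length(ref_genes)))
    warning("missing reference Cts in ", sum(n_ok < length(ref_genes)),
            " sample(s); averaging the remaining reference genes")
  out <- rowMeans(m, na.rm = TRUE)
  names(out) <- ct$sample_id
  out
}

#' Delta-delta-Ct fold changes
#'
#' For each sample and target gene: `dCt = Ct_target - reference Ct`;
#' `ddCt = dCt - mean(dCt of control samples at the same day)`;
#' `fold_change = 2^(-ddCt)` (amplification efficiency fixed at 2, the
#' standard ddCt assumption). Normalisation is stratified by day — each
#' stratum must contain at least one control sample. Missing target Cts
#' propagate to missing fold changes; they are never imputed.
#'
#' @param ct a `ct_table` data.frame.
#' @param ref_genes reference gene columns (default: the table's
#'   `ref_genes` attribute, else the five-gene panel).
#' @param target_genes target gene columns; default all gene columns that are
#'   not reference genes.
#' @param control_group label of the control group (default `"control"`;
#'   `"saline"` is accepted as a synonym).
#' @return list of class `fold_change_table`: `per_sample` (long data.frame
#'   `sample_id`, `group`, `day`, `gene`, `dct`, `ddct`, `fold_change`) and
#'   `summary` (`gene`, `group`, `day`, `n`, `mean_fold`, `sem_fold`,
#'   `mean_log2_fold`).
#' @export
delta_delta_ct <- function(ct, ref_genes = attr(ct, "ref_genes") %||% .default_ref_genes,
                           target_genes = NULL, control_group = "control") {
  meta_cols <- c("sample_id", "group", "day")
  miss <- setdiff(meta_cols, names(ct))
  if (length(miss)) stop("ct table missing columns: ", paste(miss, collapse = ", "))
  gene_cols <- setdiff(names(ct), meta_cols)
  if (is.null(target_genes)) target_genes <- setdiff(gene_cols, ref_genes)
  if (!length(target_genes)) stop("no target genes")
  ref <- reference_ct(ct, ref_genes)
  is_ctrl <- ct$group %in% c(control_group, "saline")
  days <- unique(ct$day)
  no_ctrl <- days[!vapply(days, function(d) any(is_ctrl & ct$day == d), logical(1))]
  if (length(no_ctrl))
    stop("day stratum without control samples: ", paste(no_ctrl, collapse = ", "))
  per <- do.call(rbind, lapply(target_genes, function(g) {
    dct <- ct[[g]] - ref
    ctrl_mean <- vapply(ct$day, function(d)
      mean(dct[is_ctrl & ct$day == d], na.rm = TRUE), numeric(1))
    ddct <- dct - ctrl_mean
    data.frame(sample_id = ct$sample_id, group = ct$group, day = ct$day,
               gene = g, dct = dct, ddct = ddct, fold_change = 2^(-ddct),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  key <- interaction(per$gene, per$group, per$day, drop = TRUE)
  summ <- do.call(rbind, lapply(split(per, key), function(df) {
    fc <- df$fold_change[!is.na(df$fold_change)]
    data.frame(gene = df$gene[1], group = df$group[1], day = df$day[1],
               n = length(fc),
               mean_fold = mean(fc),
               sem_fold = if (length(fc) > 1) stats::sd(fc) / sqrt(length(fc)) else NA_real_,
               mean_log2_fold = mean(log2(fc)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_sample = per, summary = summ), class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("<fold_change_table> %d genes x %d samples\n",
              length(unique(x$per_sample$gene)),
              length(unique(x$per_sample$sample_id))))
  print(utils::head(x$summary, 10))
  invisible(x)
}
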