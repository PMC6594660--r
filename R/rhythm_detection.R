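# Per-condition rhythm detection: gene pre-filter, template scan over all
# genes, family-wise Bonferroni cycling calls, phase/amplitude estimation.

#' Pre-filter lowly expressed genes
#'
#' A gene is kept iff its total TPM across *all* samples (both conditions
#' jointly) is at least `min_total_tpm` and its fraction of zero datapoints
#' is below `max_zero_fraction`.
#'
#' @param x a [diel_exprs()] matrix spanning both conditions.
#' @param min_total_tpm minimum total TPM (default 5; genes with total < 5
#'   are removed).
#' @param max_zero_fraction maximum allowed fraction of zero cells
#'   (default 0.25, i.e. a gene with >= 25% zeros is removed).
#' @return list with `kept` (a `diel_exprs`) and `removed` (gene ids).
#' @export
filter_genes <- function(x, min_total_tpm = 5, max_zero_fraction = 0.25) {
  stopifnot(inherits(x, "diel_exprs"), min_total_tpm >= 0,
            max_zero_fraction >= 0)
  if (nrow(x$tpm) == 0L) stop("empty expression matrix")
  total <- rowSums(x$tpm)
  zfrac <- rowMeans(x$tpm == 0)
  keep <- total >= min_total_tpm & zfrac < max_zero_fraction
  log_msg("filter_genes: kept %d of %d genes (total TPM >= %g, zero fraction < %g)",
          sum(keep), length(keep), min_total_tpm, max_zero_fraction)
  list(kept = subset_exprs(x, genes = which(keep)),
       removed = rownames(x$tpm)[!keep])
}

#' Family-wise Bonferroni cycling calls
#'
#' @param calls data.frame of per-gene scan results for one condition (as
#'   from [detect_rhythms()] pre-adjustment, with a `p_value` column).
#' @param alpha significance level; a gene is cycling iff the Bonferroni
#'   adjusted p-value is strictly below `alpha`.
#' @return `calls` with `adj_p` (`min(1, p * n_genes)`) and logical
#'   `cycling` columns added.
#' @export
call_cycling <- function(calls, alpha = 0.05) {
  stopifnot(is.data.frame(calls), "p_value" %in% names(calls))
  calls$adj_p <- pmin(1, calls$p_value * nrow(calls))
  calls$cycling <- calls$adj_p < alpha
  calls
}

#' Detect rhythmic genes in one condition
#'
#' Runs the exact-null Kendall-S template scan on every gene's
#' replicate-expanded series (replicates are matched against a
#' replicate-expanded template, not pre-averaged, unless
#' `average_replicates = TRUE`), applies the family-wise Bonferroni cycling
#' call, and estimates a least-squares cosinor amplitude at each gene's best
#' template lag. The reported `phase` is defined only for cycling genes.
#'
#' @param x a [diel_exprs()] matrix (typically the filtered matrix).
#' @param condition condition label to analyse (e.g. `"WW"`).
#' @param periods candidate periods (hours); default 24.
#' @param alpha family-wise significance level (default 0.05).
#' @param pre_average pre-average replicates before scanning?
#' @param bonferroni_templates within-gene correction over distinct
#'   templates (default TRUE).
#' @return data.frame (one row per gene): `gene_id`, `condition`,
#'   `p_value`, `adj_p`, `cycling`, `period`, `phase` (ZT h; NA unless
#'   cycling), `lag` (best-template lag regardless of significance),
#'   `amplitude` (TPM), `tau`.
#' @export
detect_rhythms <- function(x, condition, periods = 24, alpha = 0.05,
                           pre_average = FALSE,
                           bonferroni_templates = TRUE) {
  stopifnot(inherits(x, "diel_exprs"))
  sel <- x$keys$condition == condition
  if (!any(sel)) stop("condition not present: ", condition)
  xs <- subset_exprs(x, samples = which(sel))
  if (pre_average) xs <- average_replicates(xs)
  ord <- order(xs$keys$zt, xs$keys$replicate)
  xs <- subset_exprs(xs, samples = ord)
  times <- xs$keys$zt
  if (length(unique(times)) < 4L) stop("fewer than 4 distinct timepoints")
  scan <- jtk_scan_matrix(xs$tpm, times, periods = periods,
                          bonferroni_templates = bonferroni_templates)
  scan <- call_cycling(scan, alpha = alpha)
  amp <- numeric(nrow(scan))
  for (P in unique(scan$period)) {
    idx <- which(scan$period == P)
    amp[idx] <- amplitude_matrix(xs$tpm[idx, , drop = FALSE], times, P,
                                 scan$lag[idx])
  }
  log_msg("detect_rhythms[%s]: %d / %d genes cycling (alpha = %g)",
          condition, sum(scan$cycling), nrow(scan), alpha)
  data.frame(gene_id = scan$gene_id,
             condition = condition,
             p_value = scan$p_value,
             adj_p = scan$adj_p,
             cycling = scan$cycling,
             period = scan$period,
             phase = ifelse(scan$cycling, scan$lag, NA_real_),
             lag = scan$lag,
             amplitude = amp,
             tau = scan$tau,
             stringsAsFactors = FALSE)
}

#' Write rhythm calls to TSV
#' @param calls data.frame from [detect_rhythms()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rhythm_calls <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}
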