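# Cross-condition rhythm-change classification, circular phase shifts,
# category tabulation and phase-specific enrichment.

RHYTHM_CATEGORIES <- c("WW_only", "DR_only", "both_equal",
                       "both_WW_gt_DR", "both_DR_gt_WW", "arrhythmic")
TOP_CATEGORIES <- c("WW_only", "DR_only", "both", "arrhythmic")

#' Circular phase difference on a 24-h clock
#'
#' @param a,b phases in hours.
#' @param period clock period (default 24).
#' @return minimal circular distance in `[0, period/2]`.
#' @export
circular_phase_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Classify each gene's rhythm change between conditions
#'
#' Genes cycling in one condition only are `WW_only` / `DR_only`; genes
#' cycling in neither are `arrhythmic`. Genes cycling in both are split by
#' the amplitude difference `amp_diff = amplitude_WW - amplitude_DR`:
#' `both_equal` when `|amp_diff|` is below `amp_threshold` (no material
#' amplitude change), otherwise `both_WW_gt_DR` or `both_DR_gt_WW` by sign.
#' The circular phase shift and a `phase_changed` flag (shift >=
#' `phase_threshold`) are reported for genes cycling in both conditions.
#'
#' @param calls_ww,calls_dr rhythm-call data.frames from [detect_rhythms()]
#'   over the same gene universe.
#' @param amp_threshold TPM amplitude-difference threshold (default 3).
#' @param phase_threshold hours; smallest shift counted as a phase change
#'   (default 2 h, one sampling interval).
#' @return data.frame: `gene_id`, `category`, `amp_diff`, `phase_shift`,
#'   `phase_changed`.
#' @export
classify_rhythm_change <- function(calls_ww, calls_dr, amp_threshold = 3,
                                   phase_threshold = 2) {
  if (!setequal(calls_ww$gene_id, calls_dr$gene_id)) {
    stop("call sets cover different gene universes")
  }
  calls_dr <- calls_dr[match(calls_ww$gene_id, calls_dr$gene_id), ]
  both <- calls_ww$cycling & calls_dr$cycling
  amp_diff <- ifelse(both, calls_ww$amplitude - calls_dr$amplitude, NA_real_)
  category <- ifelse(calls_ww$cycling & !calls_dr$cycling, "WW_only",
              ifelse(!calls_ww$cycling & calls_dr$cycling, "DR_only",
              ifelse(!calls_ww$cycling & !calls_dr$cycling, "arrhythmic",
              ifelse(abs(amp_diff) < amp_threshold, "both_equal",
              ifelse(amp_diff > 0, "both_WW_gt_DR", "both_DR_gt_WW")))))
  phase_shift <- ifelse(both,
                        circular_phase_diff(calls_ww$phase, calls_dr$phase),
                        NA_real_)
  out <- data.frame(gene_id = calls_ww$gene_id,
                    category = factor(category, levels = RHYTHM_CATEGORIES),
                    amp_diff = amp_diff,
                    phase_shift = phase_shift,
                    phase_changed = ifelse(both, phase_shift >= phase_threshold,
                                           NA),
                    stringsAsFactors = FALSE)
  counts <- table(out$category)
  log_msg("classify_rhythm_change: %s",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  out
}

# count -> percentage summary shared by tabulate_categories and the
# consistency checks run on externally supplied count tables
category_summary <- function(counts) {
  need <- RHYTHM_CATEGORIES
  counts <- counts[need]
  counts[is.na(counts)] <- 0
  names(counts) <- need
  both <- sum(counts[c("both_equal", "both_WW_gt_DR", "both_DR_gt_WW")])
  top <- c(counts["WW_only"], counts["DR_only"], both = both,
           counts["arrhythmic"])
  names(top) <- TOP_CATEGORIES
  total <- sum(top)
  data.frame(category = c(TOP_CATEGORIES,
                          "both_equal", "both_WW_gt_DR", "both_DR_gt_WW",
                          "total"),
             count = as.numeric(c(top, counts["both_equal"],
                                  counts["both_WW_gt_DR"],
                                  counts["both_DR_gt_WW"], total)),
             percent = round(100 * c(top, counts["both_equal"],
                                     counts["both_WW_gt_DR"],
                                     counts["both_DR_gt_WW"], total) / total,
                             1),
             stringsAsFactors = FALSE)
}

#' Tabulate rhythm-change categories with percentages
#'
#' Produces the summary-table layout of the study: the four mutually
#' exclusive top-level categories (rhythmic in WW only, in DR only, in both,
#' arrhythmic) plus the three amplitude subcategories of "both", with
#' percentages of the gene universe to one decimal.
#'
#' @param records data.frame from [classify_rhythm_change()], or a named
#'   count vector over the six fine categories.
#' @return data.frame with `category`, `count`, `percent` rows (top-level
#'   categories sum to `total`).
#' @export
tabulate_categories <- function(records) {
  counts <- if (is.data.frame(records)) {
    tab <- table(factor(records$category, levels = RHYTHM_CATEGORIES))
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    records
  }
  category_summary(counts)
}

#' Phase-specific enrichment of a gene group
#'
#' For each integer phase bin 0-23, tests over-representation of the group's
#' cycling genes at that phase against the background with a one-sided
#' hypergeometric test; Bonferroni correction over the 24 bins. Bins never
#' populated on a 2-hourly grid simply return p = 1.
#'
#' @param phases named numeric vector: gene id -> phase (ZT h); genes without
#'   a phase (non-cycling) must be excluded beforehand.
#' @param group character vector of gene ids (subset of `background`).
#' @param background character vector of gene ids; defaults to all phased
#'   genes.
#' @return data.frame (24 rows): `phase`, `group_at_phase`, `group_total`,
#'   `bg_at_phase`, `bg_total`, `p_value`, `adj_p`, `enriched`
#'   (`adj_p <= 0.05`).
#' @export
phase_enrichment <- function(phases, group, background = names(phases)) {
  if (length(group) == 0L) stop("empty gene group")
  stopifnot(!is.null(names(phases)), all(group %in% background))
  background <- intersect(background, names(phases))
  group <- intersect(group, background)
  if (length(group) == 0L) stop("no group gene has a phase")
  ph <- round(phases) %% 24
  bins <- 0:23
  N <- length(background)
  n <- length(group)
  res <- lapply(bins, function(h) {
    K <- sum(ph[background] == h)
    k <- sum(ph[group] == h)
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(phase = h, group_at_phase = k, group_total = n,
               bg_at_phase = K, bg_total = N, p_value = p)
  })
  out <- do.call(rbind, res)
  out$adj_p <- pmin(1, out$p_value * 24)
  out$enriched <- out$adj_p <= 0.05
  out
}
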