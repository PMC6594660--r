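# Small closed-form metrics: orthogroup family dynamics, titratable acidity,
# stomatal aperture, and Ks-based divergence time.

#' Classify orthogroup expansion/contraction for a focal species
#'
#' Gene counts are first normalised by each species' genome-wide gene total
#' (accounting for ploidy and annotation depth). A family is *contracted*
#' when the focal species' normalised count is less than `contract_ratio`
#' times that of every other species carrying the family, and *expanded*
#' when it exceeds `expand_ratio` times every other species' value
#' (uniquely-changed semantics; set `mode = "any"` to require only one
#' comparator species). Species with a zero count for a family are excluded
#' from that family's ratio test.
#'
#' @param counts matrix or data.frame, families x species, of gene counts.
#' @param totals named numeric vector of genome-wide gene totals per species.
#' @param focal focal species name.
#' @param contract_ratio contraction threshold (default 0.2).
#' @param expand_ratio expansion threshold (default 3).
#' @param mode `"every"` (default) or `"any"` comparator species.
#' @return data.frame: `family`, `status` in
#'   {`contracted`, `expanded`, `neither`}, `min_ratio`, `max_ratio`,
#'   `n_comparators`.
#' @export
classify_family_dynamics <- function(counts, totals, focal,
                                     contract_ratio = 0.2, expand_ratio = 3,
                                     mode = c("every", "any")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  stopifnot(focal %in% colnames(counts), all(colnames(counts) %in% names(totals)),
            all(totals[colnames(counts)] > 0), all(counts >= 0))
  norm <- sweep(counts, 2L, totals[colnames(counts)], "/")
  others <- setdiff(colnames(counts), focal)
  out <- lapply(rownames(counts), function(fam) {
    if (all(counts[fam, ] == 0)) stop("family absent in all species: ", fam)
    vf <- norm[fam, focal]
    vs <- norm[fam, others]
    vs <- vs[vs > 0]
    if (length(vs) == 0L) {
      return(data.frame(family = fam, status = "neither",
                        min_ratio = NA_real_, max_ratio = NA_real_,
                        n_comparators = 0L, stringsAsFactors = FALSE))
    }
    ratio <- vf / vs
    contracted <- if (mode == "every") all(ratio < contract_ratio)
                  else any(ratio < contract_ratio)
    expanded <- if (mode == "every") all(ratio > expand_ratio)
                else any(ratio > expand_ratio)
    status <- if (contracted) "contracted" else if (expanded) "expanded"
              else "neither"
    data.frame(family = fam, status = status,
               min_ratio = min(ratio), max_ratio = max(ratio),
               n_comparators = length(vs), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Titratable acidity in micro-equivalents per gram fresh weight
#'
#' `volume(0.1N NaOH, mL) * 0.1 * 1000 / fresh weight (g)` - the titration
#' endpoint formula for nocturnal malic-acid accumulation assays.
#'
#' @param naoh_volume_ml titrated volume of 0.1 N NaOH (mL), >= 0.
#' @param fresh_weight_g tissue fresh weight (g), > 0.
#' @return acidity in uEq per g fresh weight.
#' @export
titratable_acid <- function(naoh_volume_ml, fresh_weight_g) {
  if (any(fresh_weight_g <= 0)) stop("fresh weight must be positive")
  if (any(naoh_volume_ml < 0)) stop("NaOH volume must be non-negative")
  naoh_volume_ml * 0.1 * 1000 / fresh_weight_g
}

#' Stomatal aperture ratio
#'
#' Width divided by length (dimensionless; 0 = closed, 1 = circular pore).
#'
#' @param width,length stoma dimensions in the same units; `length > 0`.
#' @return aperture ratio.
#' @export
stomatal_aperture <- function(width, length) {
  if (any(length <= 0)) stop("stoma length must be positive")
  width / length
}

#' Compare aperture ratios between two condition groups
#'
#' Welch two-sample t-test (unequal variances) on aperture ratios.
#'
#' @param group1,group2 numeric aperture vectors.
#' @return `htest` object from [stats::t.test()].
#' @export
aperture_t_test <- function(group1, group2) {
  stats::t.test(group1, group2, var.equal = FALSE)
}

#' Divergence time from synonymous substitution rate
#'
#' `t = Ks / (2 * rate)` years for a pairwise synonymous divergence `Ks`
#' under a per-lineage substitution rate (substitutions/site/year). The rate
#' is a required parameter - no default is assumed.
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param rate substitution rate per site per year (> 0).
#' @return divergence time in years.
#' @export
ks_to_time <- function(ks, rate) {
  if (any(rate <= 0)) stop("substitution rate must be positive")
  if (any(ks < 0)) stop("Ks must be non-negative")
  ks / (2 * rate)
}
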