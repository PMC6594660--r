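# Exact-null Kendall-S template matching ("JTK-style" rhythm detection).
#
# A gene's timecourse is compared against cosine reference templates at every
# grid lag; the statistic is Kendall's S restricted to template-untied pairs.
# Under the null (exchangeable continuous observations) the concordance count
# J = (S + M)/2 is distributed as a Jonckheere-Terpstra statistic whose pmf
# factorises into independent Mann-Whitney components, one per template tie
# group: the generating function of each component is a Gaussian binomial
# coefficient. We build each component exactly (integer counts stay below
# 2^53 for the series lengths this design produces), normalise, and convolve.

# coefficient vector of the Gaussian binomial [m+n choose m]_q =
# prod_{j=1..m} (1 - q^{n+j}) / (1 - q^j); exact in doubles
gaussian_binomial <- function(m, n) {
  poly <- 1
  for (j in seq_len(m)) {
    # multiply by (1 - q^{n+j})
    d <- n + j
    p2 <- c(poly, numeric(d)) - c(numeric(d), poly)
    # divide by (1 - q^j): s_k = p_k + s_{k-j}
    s <- p2[seq_len(length(p2) - j)]
    for (k in seq_along(s)) if (k > j) s[k] <- s[k] + s[k - j]
    poly <- s
  }
  poly
}

# cache of null distributions keyed by the template's tie-group sizes
.null_cache <- new.env(parent = emptyenv())

#' Exact null distribution of Kendall's S against a tied template
#'
#' Given the tie-group sizes of a reference template, returns the exact null
#' pmf of S (over random orderings of continuous observations) computed by
#' dynamic-programming convolution of Mann-Whitney components.
#'
#' @param group_sizes integer sizes of the template's tie groups (order
#'   irrelevant; their sum is the series length).
#' @return list with `M` (number of template-untied pairs), `S` (support,
#'   `2*(0:M) - M`), and `pmf` (probabilities summing to 1).
#' @export
kendall_s_null <- function(group_sizes) {
  group_sizes <- sort(as.integer(group_sizes))
  stopifnot(all(group_sizes >= 1), sum(group_sizes) >= 2)
  key <- paste(group_sizes, collapse = ",")
  hit <- .null_cache[[key]]
  if (!is.null(hit)) return(hit)
  pmf <- 1
  acc <- group_sizes[1L]
  for (i in seq_along(group_sizes)[-1L]) {
    m <- group_sizes[i]
    comp <- gaussian_binomial(m, acc)
    comp <- comp / sum(comp)
    # direct polynomial convolution (supports are small)
    new <- numeric(length(pmf) + length(comp) - 1L)
    for (k in seq_along(comp)) {
      idx <- seq_along(pmf) + k - 1L
      new[idx] <- new[idx] + pmf * comp[k]
    }
    pmf <- new
    acc <- acc + m
  }
  n <- sum(group_sizes)
  M <- (n^2 - sum(group_sizes^2)) / 2
  out <- list(M = M, S = 2 * (seq_along(pmf) - 1L) - M, pmf = pmf)
  assign(key, out, envir = .null_cache)
  out
}

# two-sided exact tail P(|S_null| >= |s|) for a vector of observed S
null_two_sided_p <- function(null, s_obs) {
  absS <- abs(null$S)
  ord <- order(absS)
  sorted <- absS[ord]
  suffix <- rev(cumsum(rev(null$pmf[ord])))
  # first index with sorted >= |s|; findInterval gives last index <= q
  q <- abs(s_obs) - 1e-9
  idx <- findInterval(q, sorted) + 1L
  p <- ifelse(idx > length(sorted), 0, suffix[pmin(idx, length(sorted))])
  pmin(1, p)
}

# cosine reference templates at every grid lag for each period
jtk_templates <- function(times, periods, lags = NULL) {
  out <- list()
  for (P in periods) {
    lag_set <- if (is.null(lags)) sort(unique(times %% P)) else lags
    for (lag in lag_set) {
      out[[length(out) + 1L]] <- list(period = P, lag = lag,
                                      ref = cos(2 * pi * (times - lag) / P))
    }
  }
  out
}

# Matrix engine: scan all genes against all templates at once.
# X: genes x samples; times: per-column hours. Returns one row per gene with
# the template minimising the two-sided exact p (ties broken by largest S,
# then smallest lag), tau = S / M, and the within-gene Bonferroni-adjusted p.
jtk_scan_matrix <- function(X, times, periods = 24, lags = NULL,
                            bonferroni_templates = TRUE) {
  stopifnot(is.matrix(X), ncol(X) == length(times))
  if (length(unique(times)) < 4L) stop("fewer than 4 distinct timepoints")
  if (any(!is.finite(X))) stop("non-finite value in series")
  tmpl <- jtk_templates(times, periods, lags)
  n <- ncol(X)
  pr <- t(utils::combn(n, 2L))
  sd_obs <- sign(X[, pr[, 2L], drop = FALSE] - X[, pr[, 1L], drop = FALSE])
  tsign <- matrix(0, length(tmpl), nrow(pr))
  groups <- vector("list", length(tmpl))
  for (k in seq_along(tmpl)) {
    ref <- round(tmpl[[k]]$ref, 9)
    tsign[k, ] <- sign(ref[pr[, 2L]] - ref[pr[, 1L]])
    groups[[k]] <- as.integer(table(ref))
  }
  S <- sd_obs %*% t(tsign)                      # genes x templates
  P <- matrix(1, nrow(X), length(tmpl))
  for (k in seq_along(tmpl)) {
    null <- kendall_s_null(groups[[k]])
    P[, k] <- null_two_sided_p(null, S[, k])
  }
  # distinct templates (as reference vectors) for the within-gene correction
  refmat <- t(vapply(tmpl, function(t) round(t$ref, 9), numeric(n)))
  n_templates <- nrow(unique(refmat))
  best <- integer(nrow(X))
  for (g in seq_len(nrow(X))) {
    cand <- which(P[g, ] == min(P[g, ]))
    cand <- cand[S[g, cand] == max(S[g, cand])]
    best[g] <- cand[1L]
  }
  ib <- cbind(seq_len(nrow(X)), best)
  M <- vapply(groups, function(gs) (sum(gs)^2 - sum(gs^2)) / 2, 0)
  zerovar <- apply(sd_obs == 0, 1L, all)
  p_min <- P[ib]
  tau <- S[ib] / M[best]
  p_min[zerovar] <- 1
  tau[zerovar] <- 0
  p_adj <- if (bonferroni_templates) pmin(1, p_min * n_templates) else p_min
  p_adj[zerovar] <- 1
  data.frame(
    gene_id = rownames(X) %||% sprintf("g%d", seq_len(nrow(X))),
    p_value = p_adj,
    p_min = p_min,
    period = vapply(tmpl, `[[`, 0, "period")[best],
    lag = vapply(tmpl, `[[`, 0, "lag")[best],
    tau = tau,
    S = S[ib],
    n_templates = n_templates,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan a single timecourse for rhythmicity
#'
#' Kendall-S template matching of one replicate-expanded series against
#' cosine references at every grid lag, with exact two-sided p-values from
#' the dynamic-programming null and a within-gene Bonferroni correction over
#' the distinct templates tested.
#'
#' @param values numeric series (replicate-expanded observations).
#' @param times hours for each observation (>= 4 distinct timepoints).
#' @param periods candidate periods in hours; default single 24 h cycle (a
#'   one-day design cannot separate nearby periods).
#' @param lags reference lags; default every distinct timepoint on the grid.
#' @param bonferroni_templates multiply the minimal p by the number of
#'   distinct templates (capped at 1)? Default TRUE.
#' @return one-row data.frame: `p_value` (template-corrected), `p_min`
#'   (uncorrected minimum), `period`, `lag` (best-template phase, ZT hours),
#'   `tau` (S / max |S| given template ties), `S`, `n_templates`.
#' @export
jtk_scan <- function(values, times, periods = 24, lags = NULL,
                     bonferroni_templates = TRUE) {
  X <- matrix(as.numeric(values), nrow = 1L,
              dimnames = list("series", NULL))
  jtk_scan_matrix(X, times, periods, lags, bonferroni_templates)
}

#' Least-squares cosinor phase/amplitude at a fixed lag
#'
#' Fits `x(t) = m + A cos(2 pi (t - lag)/period)` by least squares with the
#' amplitude constrained to be non-negative; the phase is the (grid) lag
#' selected by the template scan, so amplitude is a per-condition scalar in
#' the units of the data (TPM), comparable across conditions.
#'
#' @param values numeric series.
#' @param times observation hours.
#' @param period period (hours).
#' @param lag phase of the fitted cosine (ZT hours).
#' @return list with `phase`, `amplitude`, `mesor`.
#' @export
estimate_phase_amplitude <- function(values, times, period = 24, lag = 0) {
  ref <- cos(2 * pi * (times - lag) / period)
  cc <- ref - mean(ref)
  denom <- sum(cc^2)
  A <- if (denom < 1e-12) 0 else sum(cc * (values - mean(values))) / denom
  A <- max(0, A)
  list(phase = lag, amplitude = A,
       mesor = mean(values) - A * mean(ref))
}

# vectorised amplitude estimation: genes grouped by their selected lag
amplitude_matrix <- function(X, times, period, lags) {
  amp <- numeric(nrow(X))
  for (lag in unique(lags)) {
    idx <- which(lags == lag)
    ref <- cos(2 * pi * (times - lag) / period)
    cc <- ref - mean(ref)
    denom <- sum(cc^2)
    if (denom < 1e-12) { amp[idx] <- 0; next }
    xc <- X[idx, , drop = FALSE] - rowMeans(X[idx, , drop = FALSE])
    amp[idx] <- pmax(0, as.numeric(xc %*% cc) / denom)
  }
  amp
}
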