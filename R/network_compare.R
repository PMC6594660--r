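# Signed weighted co-expression modules (bicor + signed TOM), module overlap
# testing, mutual-information interaction networks with DPI pruning, and
# condition-specific activator/suppressor classification.

#' Biweight midcorrelation
#'
#' Robust correlation used for co-expression adjacency: observations are
#' weighted by `(1 - u^2)^2` with `u = (x - median) / (9 * mad)` and weight 0
#' beyond `|u| >= 1`. Columns with zero median absolute deviation fall back
#' to Pearson centring (standard practice for degenerate profiles).
#'
#' @param x numeric matrix, columns = variables (genes), rows = samples.
#' @param y optional second matrix; default `x`.
#' @return correlation matrix in `[-1, 1]`.
#' @export
bicor_matrix <- function(x, y = x) {
  w <- function(m) {
    apply(m, 2L, function(v) {
      med <- stats::median(v)
      s <- stats::mad(v, constant = 1)
      if (s < 1e-12) { # degenerate: fall back to mean-centred (Pearson)
        c <- v - mean(v)
        nm <- sqrt(sum(c^2))
        return(if (nm < 1e-12) rep(0, length(v)) else c / nm)
      }
      u <- (v - med) / (9 * s)
      wt <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      c <- (v - med) * wt
      nm <- sqrt(sum(c^2))
      if (nm < 1e-12) rep(0, length(v)) else c / nm
    })
  }
  out <- crossprod(w(x), w(y))
  pmin(pmax(out, -1), 1)
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`: anticorrelated genes get adjacency near
#' 0 (a signed network separates them); the soft power beta sharpens strong
#' positive correlations.
#'
#' @param x samples x genes matrix (gene profiles in columns).
#' @param beta soft-threshold power (>= 1).
#' @param cor_fun correlation function on the matrix (default
#'   [bicor_matrix()]).
#' @return genes x genes adjacency with unit diagonal.
#' @export
signed_adjacency <- function(x, beta = 7, cor_fun = bicor_matrix) {
  stopifnot(beta >= 1)
  ((1 + cor_fun(x)) / 2)^beta
}

#' Topological overlap similarity
#'
#' Standard TOM on an adjacency A (diagonal ignored):
#' `TOM_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' `TOM_ii = 1`. Bounded in `[0, 1]` and symmetric.
#'
#' @param A adjacency matrix with entries in `[0, 1]`.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(A) {
  stopifnot(isSymmetric(unname(A)))
  diag(A) <- 0
  L <- A %*% A
  k <- colSums(A)
  mink <- outer(k, k, pmin)
  tom <- (L + A) / (mink + 1 - A)
  diag(tom) <- 1
  tom
}

module_eigengene <- function(profiles) {
  # first principal component of the standardised member profiles,
  # sign-anchored to the mean profile
  z <- scale(t(profiles)) # samples x genes
  z[is.na(z)] <- 0
  e <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1L]
  if (stats::cor(e, rowMeans(z)) < 0) e <- -e
  e
}

#' Build signed co-expression modules for one condition
#'
#' Pipeline: signed bicor adjacency at power `beta`, signed TOM,
#' average-linkage hierarchical clustering of `1 - TOM`, a fixed-height cut,
#' removal of modules below `min_module_size` (label 0 = unassigned), and
#' iterative merging of modules whose eigengenes (first principal components)
#' correlate above `1 - merge_height`. Constant gene profiles are assigned
#' label 0 with a warning. Labels are contiguous integers, ordered by
#' decreasing module size.
#'
#' @param x a [diel_exprs()] (replicate-averaged, one condition) or a plain
#'   genes x samples matrix.
#' @param beta soft power (study defaults: 7 for WW, 10 for DR).
#' @param cut_height dendrogram cut height on the `1 - TOM` scale
#'   (default 0.85).
#' @param min_module_size smallest retained module (default 10).
#' @param merge_height eigengene merge height: modules with eigengene
#'   correlation > `1 - merge_height` are merged (study defaults: 0.01 WW,
#'   0.15 DR).
#' @return named integer vector: gene -> module label (0 = unassigned).
#' @export
build_coexpression_modules <- function(x, beta = 7, cut_height = 0.85,
                                       min_module_size = 10,
                                       merge_height = 0.01) {
  tpm <- if (inherits(x, "diel_exprs")) x$tpm else x
  stopifnot(is.matrix(tpm))
  if (ncol(tpm) < 8L) stop("need >= 8 samples to build a network")
  const <- apply(tpm, 1L, function(v) stats::sd(v) < 1e-12)
  if (any(const)) {
    warning(sum(const), " constant gene profile(s) assigned to label 0")
  }
  labels <- stats::setNames(integer(nrow(tpm)), rownames(tpm))
  work <- tpm[!const, , drop = FALSE]
  if (nrow(work) < 2L) return(labels)
  A <- signed_adjacency(t(work), beta)
  tom <- tom_similarity(A)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  cl[!(cl %in% as.integer(keep))] <- 0L
  # eigengene merging
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2L) break
    eig <- sapply(mods, function(m) module_eigengene(work[cl == m, , drop = FALSE]))
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (max(cc) <= 1 - merge_height) break
    cl[cl == mods[top[2L]]] <- mods[top[1L]]
  }
  mods <- setdiff(unique(cl), 0L)
  ord <- mods[order(-as.integer(table(factor(cl, levels = mods))))]
  relab <- stats::setNames(seq_along(ord), ord)
  out <- ifelse(cl == 0L, 0L, relab[as.character(cl)])
  labels[rownames(work)] <- as.integer(out)
  log_msg("build_coexpression_modules: %d modules over %d genes (beta = %g)",
          length(ord), nrow(tpm), beta)
  labels
}

#' Cross-condition module overlap matrix
#'
#' For every (module in partition A) x (module in partition B) pair over the
#' shared gene universe: shared gene count, percentage of the smaller
#' module, and a one-sided Fisher exact (hypergeometric tail) p-value for
#' over-representation.
#'
#' @param partition_ww,partition_dr named integer vectors from
#'   [build_coexpression_modules()] over the same gene universe.
#' @return data.frame: `module_ww`, `module_dr`, `shared`, `size_ww`,
#'   `size_dr`, `percent_shared`, `p_value`.
#' @export
module_overlap_matrix <- function(partition_ww, partition_dr) {
  genes <- intersect(names(partition_ww), names(partition_dr))
  if (length(genes) == 0L ||
      !setequal(names(partition_ww), names(partition_dr))) {
    stop("partitions cover different gene universes")
  }
  pw <- partition_ww[genes]; pd <- partition_dr[genes]
  N <- length(genes)
  res <- list()
  for (a in setdiff(sort(unique(pw)), 0L)) {
    for (b in setdiff(sort(unique(pd)), 0L)) {
      K <- sum(pw == a); n <- sum(pd == b)
      k <- sum(pw == a & pd == b)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        module_ww = a, module_dr = b, shared = k,
        size_ww = K, size_dr = n,
        percent_shared = round(100 * k / min(K, n), 1),
        p_value = p)
    }
  }
  do.call(rbind, res)
}

# equal-frequency binning into ceiling(sqrt(n)) bins
ef_bin <- function(v, bins) {
  ceiling(rank(v, ties.method = "first") * bins / length(v))
}

# normalized mutual information of two pre-binned vectors
nmi_binned <- function(bx, by, bins) {
  tab <- table(factor(bx, levels = seq_len(bins)),
               factor(by, levels = seq_len(bins)))
  pj <- tab / sum(tab)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx < 1e-12 || hy < 1e-12) return(NA_real_)
  max(0, min(1, mi / sqrt(hx * hy)))
}

#' Infer an interaction network from expression profiles
#'
#' A documented stand-in for part-mutual-information network inference:
#' pairwise dependency is scored by normalized mutual information
#' (equal-frequency binning into `ceiling(sqrt(n))` bins, MI normalised by
#' `sqrt(Hx * Hy)` into `[0, 1]`), edges below `threshold` are dropped, and
#' the surviving graph is pruned with a data-processing-inequality step:
#' edge (i, j) is removed when some gene k satisfies
#' `min(score(i,k), score(k,j)) > score(i,j) * (1 + dpi_tolerance)`,
#' suppressing indirect interactions. Constant genes are excluded with a
#' warning. The score scale is this estimator's own; the study thresholds
#' (0.47 WW, 0.52 DR) are exposed as configuration on that scale.
#'
#' @param x a [diel_exprs()] (one condition, replicate-averaged) or a plain
#'   genes x samples matrix with >= 10 samples.
#' @param threshold minimum retained score.
#' @param dpi_tolerance DPI slack (default 0.1).
#' @return object of class `interaction_network`: list with `edges`
#'   (data.frame `a`, `b`, `score`), `genes`, `threshold`.
#' @export
infer_interaction_network <- function(x, threshold = 0.47,
                                      dpi_tolerance = 0.1) {
  tpm <- if (inherits(x, "diel_exprs")) x$tpm else x
  stopifnot(is.matrix(tpm))
  n <- ncol(tpm)
  if (n < 10L) stop("need >= 10 samples to estimate interactions")
  const <- apply(tpm, 1L, function(v) stats::sd(v) < 1e-12)
  if (any(const)) {
    warning(sum(const), " constant gene(s) excluded from the network")
    tpm <- tpm[!const, , drop = FALSE]
  }
  genes <- rownames(tpm)
  bins <- ceiling(sqrt(n))
  bx <- t(apply(tpm, 1L, ef_bin, bins = bins))
  p <- nrow(tpm)
  score <- matrix(0, p, p, dimnames = list(genes, genes))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      s <- nmi_binned(bx[i, ], bx[j, ], bins)
      score[i, j] <- score[j, i] <- if (is.na(s)) 0 else s
    }
  }
  keep <- score >= threshold
  diag(keep) <- FALSE
  # DPI pruning on the thresholded graph
  sc <- score * keep
  drop <- matrix(FALSE, p, p)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    via <- pmin(sc[i, ], sc[, j])
    via[c(i, j)] <- 0
    if (any(via > sc[i, j] * (1 + dpi_tolerance))) {
      drop[i, j] <- drop[j, i] <- TRUE
    }
  }
  keep <- keep & !drop
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(a = genes[idx[, 1L]], b = genes[idx[, 2L]],
                      score = score[idx], stringsAsFactors = FALSE)
  log_msg("infer_interaction_network: %d edges over %d genes (threshold %g)",
          nrow(edges), p, threshold)
  structure(list(edges = edges, genes = genes, threshold = threshold),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d genes, %d edges (threshold %g)\n",
              length(x$genes), nrow(x$edges), x$threshold))
  invisible(x)
}

net_neighbors <- function(net, gene) {
  e <- net$edges
  unique(c(e$b[e$a == gene], e$a[e$b == gene]))
}

#' Classify condition-specific interactors of target genes
#'
#' For each target, interaction partners present only in the drought (DR)
#' network are called activators and partners present only in the
#' well-watered (WW) network are called suppressors (the study's
#' "repressor"); shared partners are reported separately.
#'
#' @param net_ww,net_dr `interaction_network` objects.
#' @param targets character vector of target gene ids.
#' @return list with `table` (per-target counts) and `partners` (per-target
#'   lists `activators`, `suppressors`, `shared`).
#' @export
classify_regulators <- function(net_ww, net_dr, targets) {
  partners <- list()
  rows <- list()
  for (t in targets) {
    in_ww <- t %in% net_ww$genes
    in_dr <- t %in% net_dr$genes
    if (!in_ww && !in_dr) {
      warning("target ", t, " absent from both networks")
    }
    nb_ww <- if (in_ww) net_neighbors(net_ww, t) else character(0)
    nb_dr <- if (in_dr) net_neighbors(net_dr, t) else character(0)
    act <- setdiff(nb_dr, nb_ww)
    sup <- setdiff(nb_ww, nb_dr)
    shared <- intersect(nb_ww, nb_dr)
    partners[[t]] <- list(activators = act, suppressors = sup,
                          shared = shared)
    rows[[t]] <- data.frame(gene_id = t,
                            activators = length(act),
                            suppressors = length(sup),
                            shared = length(shared),
                            stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       partners = partners)
}

#' Write an interaction network edge list to TSV
#' @param net `interaction_network` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  data.table::fwrite(net$edges, path, sep = "\t")
  invisible(path)
}

#' Write a module partition to TSV
#' @param partition named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(partition, path) {
  data.table::fwrite(data.frame(gene_id = names(partition),
                                module = as.integer(partition)),
                     path, sep = "\t")
  invisible(path)
}
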