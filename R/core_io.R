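#' @import data.table
#' @importFrom stats median mad sd cor prcomp quantile phyper fisher.test
#'   t.test setNames complete.cases hclust cutree as.dist p.adjust rnorm runif
#' @importFrom utils head tail
NULL

# timestamped log line on stderr; all pipeline stages report through this
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Format a sample key as a column label
#'
#' The canonical label dialect is `<COND>_ZT<two-digit hour>_r<replicate>`,
#' e.g. `WW_ZT06_r2`. Replicate-averaged matrices drop the `_r<k>` suffix.
#'
#' @param condition character vector, e.g. `"WW"` or `"DR"`.
#' @param zt integer zeitgeber hours (hours since lights-on).
#' @param replicate integer replicate numbers, or `NA` for averaged columns.
#' @return character vector of labels.
#' @export
format_sample_key <- function(condition, zt, replicate = NA_integer_) {
  base <- sprintf("%s_ZT%02d", condition, as.integer(zt))
  ifelse(is.na(replicate), base, sprintf("%s_r%d", base, as.integer(replicate)))
}

#' Parse sample column labels into condition, ZT and replicate
#'
#' @param labels character vector of column labels.
#' @param pattern regex with three capture groups (condition, zt, replicate);
#'   the replicate group may match an empty string for averaged matrices.
#' @return data.frame with columns `condition`, `zt`, `replicate`.
#' @export
parse_sample_keys <- function(labels,
                              pattern = "^([A-Za-z]+)_ZT([0-9]{1,2})(?:_r([0-9]+))?$") {
  m <- regmatches(labels, regexec(pattern, labels))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable sample label: ", paste(labels[bad], collapse = ", "))
  }
  cond <- vapply(m, `[`, "", 2L)
  zt <- as.integer(vapply(m, `[`, "", 3L))
  rep_chr <- vapply(m, function(g) if (length(g) >= 4L) g[4L] else "", "")
  repl <- suppressWarnings(as.integer(rep_chr))
  data.frame(condition = cond, zt = zt, replicate = repl,
             stringsAsFactors = FALSE)
}

#' Construct a diel expression matrix object
#'
#' A light container bundling a genes x samples TPM matrix with parsed sample
#' keys, the universal input of the pipeline.
#'
#' @param tpm numeric matrix, rows = genes (rownames required, unique),
#'   columns = samples.
#' @param keys data.frame as returned by [parse_sample_keys()]; defaults to
#'   parsing `colnames(tpm)`.
#' @return object of class `diel_exprs` with elements `$tpm` and `$keys`.
#' @export
diel_exprs <- function(tpm, keys = parse_sample_keys(colnames(tpm))) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (is.null(rownames(tpm))) stop("gene ids (rownames) are required")
  if (anyDuplicated(rownames(tpm))) {
    stop("duplicate gene id: ",
         paste(unique(rownames(tpm)[duplicated(rownames(tpm))]), collapse = ", "))
  }
  if (nrow(keys) != ncol(tpm)) stop("keys do not match matrix columns")
  lab <- format_sample_key(keys$condition, keys$zt, keys$replicate)
  if (anyDuplicated(lab)) {
    stop("duplicate sample key: ", paste(lab[duplicated(lab)], collapse = ", "))
  }
  if (any(!is.finite(tpm))) {
    bad <- which(!is.finite(tpm), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric/non-finite cell at gene '%s', sample '%s'",
                 rownames(tpm)[bad[1L]], colnames(tpm)[bad[2L]]))
  }
  if (any(tpm < 0)) stop("negative TPM values are not allowed")
  structure(list(tpm = tpm, keys = keys), class = "diel_exprs")
}

#' @export
print.diel_exprs <- function(x, ...) {
  cat(sprintf("diel_exprs: %d genes x %d samples\n", nrow(x$tpm), ncol(x$tpm)))
  for (cond in unique(x$keys$condition)) {
    k <- x$keys[x$keys$condition == cond, ]
    cat(sprintf("  %s: %d timepoints (ZT %s), %s\n", cond,
                length(unique(k$zt)), paste(range(k$zt), collapse = "-"),
                if (all(is.na(k$replicate))) "replicate-averaged"
                else sprintf("%d columns", nrow(k))))
  }
  invisible(x)
}

#' @export
dim.diel_exprs <- function(x) dim(x$tpm)

#' Subset a diel expression matrix
#'
#' @param x a `diel_exprs` object.
#' @param genes gene ids or row indices (default all).
#' @param samples logical/integer index over columns (default all).
#' @return a `diel_exprs` object.
#' @export
subset_exprs <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "diel_exprs"))
  tpm <- x$tpm
  keys <- x$keys
  if (!is.null(genes)) tpm <- tpm[genes, , drop = FALSE]
  if (!is.null(samples)) {
    tpm <- tpm[, samples, drop = FALSE]
    keys <- keys[samples, , drop = FALSE]
  }
  diel_exprs(tpm, keys)
}

#' Read a TPM expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples labelled per the
#' configured dialect. Row and column order are preserved.
#'
#' @param path TSV file path.
#' @param key_pattern regex passed to [parse_sample_keys()].
#' @return a [diel_exprs()] object.
#' @export
read_expression_matrix <- function(path,
                                   key_pattern = "^([A-Za-z]+)_ZT([0-9]{1,2})(?:_r([0-9]+))?$") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("expression TSV needs a gene id column plus samples")
  ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                   ids[bad], colnames(vals)[j]))
    }
  }
  tpm <- as.matrix(vals)
  rownames(tpm) <- ids
  keys <- parse_sample_keys(colnames(tpm), key_pattern)
  x <- diel_exprs(tpm, keys)
  log_msg("read %d genes x %d samples from %s", nrow(tpm), ncol(tpm), path)
  x
}

#' Write an expression matrix to TSV
#'
#' @param x a `diel_exprs` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "diel_exprs"))
  dt <- data.table::data.table(gene_id = rownames(x$tpm))
  lab <- format_sample_key(x$keys$condition, x$keys$zt, x$keys$replicate)
  for (j in seq_len(ncol(x$tpm))) dt[[lab[j]]] <- x$tpm[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Average biological replicates per (condition, ZT)
#'
#' Each cell of the result is the arithmetic mean of the available replicates
#' (missing replicates are simply excluded from the denominator, matching a
#' design with occasional lost samples). Idempotent on an already-averaged
#' matrix.
#'
#' @param x a `diel_exprs` object.
#' @return a `diel_exprs` object with one column per (condition, ZT) and
#'   `replicate = NA` keys.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "diel_exprs"))
  cell <- paste(x$keys$condition, x$keys$zt, sep = "@")
  cells <- unique(cell)
  out <- matrix(0, nrow(x$tpm), length(cells),
                dimnames = list(rownames(x$tpm), NULL))
  cond <- character(length(cells)); zt <- integer(length(cells))
  for (i in seq_along(cells)) {
    idx <- which(cell == cells[i])
    if (length(idx) == 0L) stop("empty (condition, ZT) cell: ", cells[i])
    out[, i] <- rowMeans(x$tpm[, idx, drop = FALSE])
    cond[i] <- x$keys$condition[idx[1L]]
    zt[i] <- x$keys$zt[idx[1L]]
  }
  keys <- data.frame(condition = cond, zt = zt, replicate = NA_integer_,
                     stringsAsFactors = FALSE)
  ord <- order(keys$condition, keys$zt)
  colnames(out) <- format_sample_key(keys$condition, keys$zt, keys$replicate)
  diel_exprs(out[, ord, drop = FALSE], keys[ord, , drop = FALSE])
}

#' Read a gene list (one id per line)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Write a gene list (one id per line)
#' @param ids character vector.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
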