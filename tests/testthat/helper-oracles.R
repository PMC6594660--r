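# Shared fixtures and independent oracles, built in code at test time.

# all permutations of 1..n as a matrix (rows), built level by level
perm_mat <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perm_mat(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# exhaustive-permutation null pmf of Kendall's S against a fixed reference:
# the independent oracle for the dynamic-programming null
perm_null_pmf <- function(ref) {
  n <- length(ref)
  pr <- t(combn(n, 2L))
  tsign <- sign(ref[pr[, 2L]] - ref[pr[, 1L]])
  P <- perm_mat(n)
  S <- integer(nrow(P))
  for (r in seq_len(nrow(pr))) {
    S <- S + sign(P[, pr[r, 2L]] - P[, pr[r, 1L]]) * tsign[r]
  }
  tab <- table(S)
  list(S = as.integer(names(tab)), pmf = as.numeric(tab) / nrow(P))
}

# two-sided tail of an enumerated pmf
perm_two_sided_p <- function(null, s_obs) {
  sum(null$pmf[abs(null$S) >= abs(s_obs) - 1e-9])
}

# direct-summation hypergeometric upper tail P[X >= k]
hyper_tail <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  sum(dhyper(k:min(K, n), K, N - K, n))
}

# edge list of a complete clique over gene ids
clique_edges <- function(genes, rho = 0.9) {
  n <- length(genes)
  do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    data.frame(a = genes[i], b = genes[(i + 1L):n], rho = rho,
               stringsAsFactors = FALSE)
  }))
}

# minimal hand-built rhythm-call table
toy_calls <- function(gene_id, cycling, amplitude = 0, phase = NA_real_,
                      condition = "WW") {
  data.frame(gene_id = gene_id, condition = condition,
             p_value = ifelse(cycling, 1e-6, 0.5),
             adj_p = ifelse(cycling, 1e-4, 1),
             cycling = cycling, period = 24,
             phase = ifelse(cycling, phase, NA_real_),
             lag = ifelse(is.na(phase), 0, phase),
             amplitude = amplitude, tau = ifelse(cycling, 0.9, 0),
             stringsAsFactors = FALSE)
}
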