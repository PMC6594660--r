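test_that("the DP null equals exhaustive permutation enumeration (n <= 8)", {
  refs <- list(
    distinct = c(3, 1, 4, 2, 6, 5),                 # no template ties
    paired = c(1, 1, 2, 2, 3, 3),                   # replicate-style ties
    cosine = round(cos(2 * pi * (seq(0, 20, 4) - 4) / 24), 9))
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    oracle <- perm_null_pmf(ref)
    null <- kendall_s_null(as.integer(table(ref)))
    got <- data.frame(S = null$S, p = null$pmf)
    got <- got[got$p > 0, ]
    expect_equal(got$S, oracle$S, info = nm)
    expect_equal(got$p, oracle$pmf, tolerance = 1e-12, info = nm)
  }
  # every n <= 8 with random tie structures
  set.seed(11)
  for (n in 3:8) {
    ref <- sample(1:max(2, n - 2), n, replace = TRUE)
    oracle <- perm_null_pmf(ref)
    null <- kendall_s_null(as.integer(table(ref)))
    keep <- null$pmf > 0
    expect_equal(null$S[keep], oracle$S)
    expect_equal(null$pmf[keep], oracle$pmf, tolerance = 1e-12)
  }
})

test_that("jtk_scan p-values match the permutation oracle on observed data", {
  set.seed(21)
  # n = 5 against a strictly monotone reference: exhaustive 120 permutations
  x <- rnorm(5)
  ref <- 1:5
  pr <- t(combn(5, 2))
  s_obs <- sum(sign(x[pr[, 2]] - x[pr[, 1]]) * sign(ref[pr[, 2]] - ref[pr[, 1]]))
  oracle <- perm_two_sided_p(perm_null_pmf(ref), s_obs)
  null <- kendall_s_null(rep(1L, 5))
  expect_equal(dielshift:::null_two_sided_p(null, s_obs), oracle,
               tolerance = 1e-12)

  # noiseless cosine at ZT4, 12 timepoints x 1 replicate
  times <- seq(0, 22, 2)
  series <- 10 + 3 * cos(2 * pi * (times - 4) / 24)
  scan <- jtk_scan(series, times)
  expect_equal(scan$lag, 4)
  ref <- round(cos(2 * pi * (times - 4) / 24), 9)
  # un-adjusted min-p equals the two-sided tail at the maximal concordant S
  pr <- t(combn(12, 2))
  tsign <- sign(ref[pr[, 2]] - ref[pr[, 1]])
  s_max <- sum(abs(tsign))
  null <- kendall_s_null(as.integer(table(ref)))
  expect_equal(scan$p_min, dielshift:::null_two_sided_p(null, s_max),
               tolerance = 1e-12)
  expect_equal(scan$S, s_max)

  # constant series: p = 1, tau = 0
  flat <- jtk_scan(rep(3, 12), times)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$tau, 0)
  expect_error(jtk_scan(rnorm(3), c(0, 8, 16)), "fewer than 4")
  expect_error(jtk_scan(c(1, NA, 2, 3), c(0, 6, 12, 18)), "non-finite")
})

test_that("scan is scale-invariant and phase-equivariant on the grid", {
  times <- seq(0, 22, 2)
  set.seed(31)
  x <- 20 + 8 * cos(2 * pi * (times - 6) / 24) + rnorm(12, 0, 2)
  base <- jtk_scan(x, times)
  for (c in c(0.1, 3, 117)) {
    scaled <- jtk_scan(c * x, times)
    expect_equal(scaled$p_value, base$p_value)
    expect_equal(scaled$tau, base$tau)
    expect_equal(scaled$lag, base$lag)
    amp <- estimate_phase_amplitude(c * x, times, 24, scaled$lag)$amplitude
    expect_equal(amp, c * estimate_phase_amplitude(x, times, 24, base$lag)$amplitude)
  }
  for (shift_steps in 1:11) {
    rot <- c(tail(x, shift_steps), head(x, 12 - shift_steps))
    # rot[i] = x at time (t_i - 2*shift): the waveform moved later by 2*shift
    got <- jtk_scan(rot, times)
    expect_equal(got$lag, (base$lag + 2 * shift_steps) %% 24)
    expect_equal(got$p_value, base$p_value)
  }
})

test_that("cosinor amplitude estimation is exact on noiseless data and unbiased", {
  times <- seq(0, 22, 2)
  fit <- estimate_phase_amplitude(10 + 3 * cos(2 * pi * (times - 6) / 24),
                                  times, 24, 6)
  expect_equal(fit$phase, 6)
  expect_equal(fit$amplitude, 3)
  expect_equal(fit$mesor, 10)
  expect_equal(estimate_phase_amplitude(rep(4, 12), times, 24, 0)$amplitude, 0)
  # Monte Carlo unbiasedness: A = 5, sd 1, 100 draws
  set.seed(41)
  est <- replicate(100, {
    y <- 12 + 5 * cos(2 * pi * (times - 8) / 24) + rnorm(12)
    estimate_phase_amplitude(y, times, 24, 8)$amplitude
  })
  expect_lt(abs(mean(est) - 5), 0.5)
})

test_that("detection power is monotone in amplitude at fixed noise", {
  times <- seq(0, 22, 2)
  n_genes <- 150
  rate <- vapply(c(1, 4, 8), function(A) {
    X <- dielshift:::with_seed(51 + A, {
      t(replicate(n_genes,
                  20 + A * cos(2 * pi * (times - 10) / 24) + rnorm(12, 0, 2)))
    })
    rownames(X) <- sprintf("g%d", seq_len(n_genes))
    calls <- call_cycling(dielshift:::jtk_scan_matrix(X, times))
    mean(calls$cycling)
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3], rate[1])
})

test_that("filter_genes applies both rules jointly over all samples", {
  # 10 genes: 3 fail the total-TPM rule, 3 fail the zero-fraction rule,
  # one of each overlap -> 5 removed, 5 kept
  keys <- expand.grid(replicate = 1, zt = seq(0, 22, 2),
                      condition = c("WW", "DR"), stringsAsFactors = FALSE)
  n <- nrow(keys)                                       # 24 samples
  tpm <- rbind(
    lowA = rep(4.9 / n, n),                             # total 4.9, no zeros
    lowB = rep(0.1, n),                                 # total 2.4
    low_and_zero = c(rep(0, 12), rep(0.3, 12)),         # fails both rules
    zeroA = c(rep(0, 6), rep(10, 18)),                  # 25% zeros (boundary)
    zeroB = c(rep(0, 7), rep(10, 17)),                  # > 25% zeros
    keepA = rep(5 / n, n),                              # total exactly 5
    keepB = rep(1, n),
    keepC = c(rep(0, 5), rep(10, 19)),                  # 21% zeros, high TPM
    keepD = 1 + seq_len(n),
    keepE = rep(100, n))
  colnames(tpm) <- format_sample_key(keys$condition, keys$zt, keys$replicate)
  x <- diel_exprs(tpm)
  res <- suppressMessages(filter_genes(x))
  expect_setequal(res$removed, c("lowA", "lowB", "low_and_zero", "zeroA", "zeroB"))
  expect_equal(nrow(res$kept$tpm), 5L)
  expect_setequal(c(rownames(res$kept$tpm), res$removed), rownames(tpm))
  allzero <- diel_exprs(rbind(tpm, gone = rep(0, n)))
  expect_true("gone" %in% suppressMessages(filter_genes(allzero))$removed)
})

test_that("call_cycling applies a strict Bonferroni boundary", {
  n <- 40L
  calls <- data.frame(gene_id = sprintf("g%d", 1:n),
                      p_value = c(0.05 / n, 0.049 / n, rep(0.5, n - 2L)))
  out <- call_cycling(calls, alpha = 0.05)
  expect_equal(out$adj_p[1], 0.05)
  expect_false(out$cycling[1])                     # boundary: strict <
  expect_true(out$cycling[2])
  expect_true(all(out$adj_p >= out$p_value))
  one <- call_cycling(data.frame(gene_id = "g", p_value = 0.2))
  expect_equal(one$adj_p, 0.2)                     # n = 1: identity
})

test_that("noiseless truths are fully recovered downstream", {
  truths <- simulate_truths(n = c(WW_only = 6, DR_only = 6, both = 6,
                                  arrhythmic = 6),
                            n_shifted = 3, noise_sd = 0, seed = 61)
  x <- generate_expression(diel_design(), truths, seed = 62)
  cw <- suppressMessages(detect_rhythms(x, "WW"))
  cd <- suppressMessages(detect_rhythms(x, "DR"))
  expect_equal(cw$cycling, truths$amplitude_ww > 0)
  expect_equal(cd$cycling, truths$amplitude_dr > 0)
  expect_equal(cw$phase[cw$cycling],
               truths$phase_ww[truths$amplitude_ww > 0])
  expect_true(all(is.na(cw$phase[!cw$cycling])))
})
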