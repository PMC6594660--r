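# Synthetic two-condition diel timecourses with known ground truth.
# The default design mirrors the study layout: 12 timepoints every 2 h over
# 24 h, 12:12 photoperiod, 3 biological replicates, conditions WW and DR.

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Describe a diel sampling design
#'
#' @param timepoints strictly increasing ZT hours in `[0, 24)`.
#' @param photoperiod_hours light-phase length (h); default 12:12.
#' @param replicates biological replicates per (condition, timepoint).
#' @param conditions condition labels; default well-watered vs drought.
#' @param missing optional data.frame with columns `condition`, `zt`,
#'   `replicate` listing whole replicates dropped from the design.
#' @return object of class `diel_design`.
#' @export
diel_design <- function(timepoints = seq(0, 22, by = 2),
                        photoperiod_hours = 12,
                        replicates = 3,
                        conditions = c("WW", "DR"),
                        missing = NULL) {
  stopifnot(all(diff(timepoints) > 0), all(timepoints >= 0), all(timepoints < 24),
            replicates >= 1, length(conditions) >= 1)
  if (!is.null(missing)) {
    stopifnot(all(c("condition", "zt", "replicate") %in% names(missing)))
    for (i in seq_len(nrow(missing))) {
      cell_left <- replicates - sum(missing$condition == missing$condition[i] &
                                      missing$zt == missing$zt[i])
      if (cell_left < 1L) {
        stop("dropping these replicates would empty a (condition, ZT) cell")
      }
    }
  }
  structure(list(timepoints = as.numeric(timepoints),
                 photoperiod_hours = photoperiod_hours,
                 replicates = as.integer(replicates),
                 conditions = conditions,
                 missing = missing),
            class = "diel_design")
}

#' The study's missing replicates
#'
#' The source design lost one replicate at WW ZT22 (two remain) and two at
#' DR ZT0 (one remains).
#'
#' @return data.frame usable as the `missing` argument of [diel_design()].
#' @export
sedum_missing <- function() {
  data.frame(condition = c("WW", "DR", "DR"),
             zt = c(22L, 0L, 0L),
             replicate = c(3L, 2L, 3L),
             stringsAsFactors = FALSE)
}

design_keys <- function(design) {
  keys <- expand.grid(replicate = seq_len(design$replicates),
                      zt = design$timepoints,
                      condition = design$conditions,
                      stringsAsFactors = FALSE)[, c("condition", "zt", "replicate")]
  keys$condition <- as.character(keys$condition)
  if (!is.null(design$missing)) {
    drop <- paste(design$missing$condition, design$missing$zt,
                  design$missing$replicate)
    keys <- keys[!(paste(keys$condition, keys$zt, keys$replicate) %in% drop), ]
  }
  rownames(keys) <- NULL
  keys
}

#' Simulate per-gene rhythm ground truth
#'
#' Builds the truth table for the standard recovery benchmark: genes rhythmic
#' in one condition only, in both (a subset carrying a 2-4 h phase shift in
#' DR), or arrhythmic. Defaults give the 1,000-gene benchmark layout
#' (200/200/300/300 with 150 shifted) at noise_sd = amplitude/3.
#'
#' @param n named integer vector with entries `WW_only`, `DR_only`, `both`,
#'   `arrhythmic`.
#' @param n_shifted number of `both` genes whose DR phase is shifted by
#'   2-4 h (grid-resolved) relative to WW.
#' @param baseline mean TPM level of every gene.
#' @param amplitude cosine amplitude (TPM) of rhythmic condition(s).
#' @param noise_sd additive Gaussian noise sd (TPM); default amplitude/3.
#' @param timepoints sampling grid used to draw phases.
#' @param seed RNG seed.
#' @return data.frame of class `gene_truth` (one row per gene).
#' @export
simulate_truths <- function(n = c(WW_only = 200, DR_only = 200,
                                  both = 300, arrhythmic = 300),
                            n_shifted = 150,
                            baseline = 20, amplitude = 10,
                            noise_sd = amplitude / 3,
                            timepoints = seq(0, 22, by = 2),
                            seed = 1) {
  stopifnot(all(c("WW_only", "DR_only", "both", "arrhythmic") %in% names(n)),
            n_shifted <= n[["both"]])
  with_seed(seed, {
    total <- sum(n)
    cls <- rep(names(n), times = n)
    gene_id <- sprintf("g%04d", seq_len(total))
    phase_ww <- sample(timepoints, total, replace = TRUE)
    phase_dr <- phase_ww
    shift_idx <- which(cls == "both")[seq_len(n_shifted)]
    phase_dr[shift_idx] <- (phase_ww[shift_idx] +
                              sample(c(-4, -2, 2, 4), n_shifted, replace = TRUE)) %% 24
    amp_ww <- ifelse(cls %in% c("WW_only", "both"), amplitude, 0)
    amp_dr <- ifelse(cls %in% c("DR_only", "both"), amplitude, 0)
    truths <- data.frame(
      gene_id = gene_id, class = cls,
      baseline_ww = baseline, baseline_dr = baseline,
      amplitude_ww = amp_ww, amplitude_dr = amp_dr,
      phase_ww = ifelse(amp_ww > 0, phase_ww, NA_real_),
      phase_dr = ifelse(amp_dr > 0, phase_dr, NA_real_),
      noise_sd = noise_sd,
      stringsAsFactors = FALSE)
    class(truths) <- c("gene_truth", "data.frame")
    truths
  })
}

validate_truths <- function(truths) {
  need <- c("gene_id", "class", "baseline_ww", "baseline_dr", "amplitude_ww",
            "amplitude_dr", "phase_ww", "phase_dr", "noise_sd")
  stopifnot(is.data.frame(truths), all(need %in% names(truths)),
            nrow(truths) > 0)
  if (anyDuplicated(truths$gene_id)) stop("duplicate gene_ids in truths")
  if (any(truths$amplitude_ww < 0 | truths$amplitude_dr < 0) ||
      any(truths$baseline_ww < 0 | truths$baseline_dr < 0)) {
    stop("negative amplitude/baseline in truths")
  }
  arr_ww <- truths$class %in% c("DR_only", "arrhythmic")
  arr_dr <- truths$class %in% c("WW_only", "arrhythmic")
  if (any(truths$amplitude_ww[arr_ww] != 0) ||
      any(truths$amplitude_dr[arr_dr] != 0)) {
    stop("truth class says arrhythmic but amplitude > 0")
  }
  invisible(truths)
}

#' Generate a synthetic expression matrix from a design and truth table
#'
#' Signal model: `max(0, baseline + amplitude * cos(2*pi*(t - phase)/24) + e)`
#' with `e ~ N(0, noise_sd^2)` drawn independently per replicate (additive
#' Gaussian on the TPM scale, truncated at zero). `noise_model = "lognormal"`
#' instead multiplies the noiseless signal by `exp(N(0, noise_sd^2))`
#' (noise_sd then acts on the log scale) for heavier tails.
#'
#' @param design a [diel_design()].
#' @param truths a truth table as from [simulate_truths()].
#' @param seed RNG seed; outputs are byte-identical for identical inputs.
#' @param noise_model `"gaussian"` (default) or `"lognormal"`.
#' @return a [diel_exprs()] matrix whose columns exactly match the design
#'   minus its `missing` entries.
#' @export
generate_expression <- function(design, truths, seed,
                                noise_model = c("gaussian", "lognormal")) {
  stopifnot(inherits(design, "diel_design"))
  noise_model <- match.arg(noise_model)
  validate_truths(truths)
  keys <- design_keys(design)
  with_seed(seed, {
    tpm <- matrix(0, nrow(truths), nrow(keys),
                  dimnames = list(truths$gene_id, NULL))
    for (j in seq_len(nrow(keys))) {
      ww <- keys$condition[j] == design$conditions[1L]
      base <- if (ww) truths$baseline_ww else truths$baseline_dr
      amp <- if (ww) truths$amplitude_ww else truths$amplitude_dr
      phase <- if (ww) truths$phase_ww else truths$phase_dr
      signal <- base + ifelse(amp > 0,
                              amp * cos(2 * pi * (keys$zt[j] - phase) / 24), 0)
      tpm[, j] <- switch(noise_model,
        gaussian = pmax(0, signal + rnorm(nrow(truths), 0, truths$noise_sd)),
        lognormal = signal * exp(rnorm(nrow(truths), 0, truths$noise_sd)))
    }
    colnames(tpm) <- format_sample_key(keys$condition, keys$zt, keys$replicate)
    diel_exprs(tpm, keys)
  })
}

#' Write / read a truth table (lossless TSV round trip)
#' @param truths truth data.frame.
#' @param path TSV path.
#' @return `path` invisibly (write); the truth data.frame (read).
#' @export
write_truths <- function(truths, path) {
  data.table::fwrite(truths, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truths
#' @export
read_truths <- function(path) {
  truths <- data.table::fread(path, sep = "\t", data.table = FALSE,
                              na.strings = "")
  class(truths) <- c("gene_truth", "data.frame")
  truths
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate promoter sequences with planted motifs
#'
#' Background bases are i.i.d. with the given GC content; planted motifs
#' overwrite the background at their stated 0-based offsets
#' (reverse-complemented first when strand is `-`). Overlapping plants with
#' conflicting bases are rejected.
#'
#' @param truths data.frame with columns `gene_id`, `motif`, `offset`
#'   (0-based), `strand` (`+`/`-`); rows with `NA`/empty motif contribute the
#'   gene with a pure-background promoter.
#' @param length promoter length (bp); must fit the longest planted motif.
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return named [Biostrings::DNAStringSet] of promoters.
#' @export
generate_promoters <- function(truths, length = 2000, gc = 0.5, seed = 1) {
  stopifnot(gc > 0, gc < 1, all(c("gene_id", "motif") %in% names(truths)))
  planted <- truths[!is.na(truths$motif) & nzchar(truths$motif), , drop = FALSE]
  if (nrow(planted) > 0) {
    stopifnot(all(c("offset", "strand") %in% names(truths)))
    if (any(nchar(planted$motif) > length)) {
      stop("promoter length shorter than a planted motif")
    }
    if (!all(strsplit(paste(planted$motif, collapse = ""), "")[[1]] %in%
             c("A", "C", "G", "T"))) {
      stop("planted motifs must be over {A,C,G,T}")
    }
    if (any(planted$offset < 0 | planted$offset + nchar(planted$motif) > length)) {
      stop("planted motif offset outside promoter")
    }
  }
  genes <- unique(truths$gene_id)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(genes, function(g) {
      chars <- sample(names(probs), length, replace = TRUE, prob = probs)
      rows <- planted[planted$gene_id == g, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        motif <- rows$motif[i]
        if (identical(rows$strand[i], "-")) motif <- revcomp_chr(motif)
        pos <- rows$offset[i] + seq_len(nchar(motif))
        new <- strsplit(motif, "")[[1]]
        old <- chars[pos]
        prev <- attr(chars, "planted_at")
        clash <- pos %in% prev & old != new
        if (any(clash)) stop("overlapping planted motifs with conflicting bases")
        chars[pos] <- new
        attr(chars, "planted_at") <- c(prev, pos)
      }
      paste(chars, collapse = "")
    }, "")
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- genes
    out
  })
}

#' Generate correlation-structured sample data for network benchmarks
#'
#' Genes are standard-normal "profiles" across `n_samples` samples with
#' planted pairwise structure. Connected components of the planted edge list
#' are materialised as: a single latent factor when the component is a
#' complete clique (every pair correlated at `rho`), or a Markov chain along
#' the component's spanning tree otherwise (adjacent pairs at `rho`,
#' correlation decaying with tree distance - the layout needed to exercise
#' data-processing-inequality pruning on chains).
#'
#' @param n_genes total genes; ids `g1..gN`, unplanted genes independent.
#' @param planted_edges data.frame with columns `a`, `b` (gene ids) and
#'   optionally `rho` (default 0.9); must form a simple graph.
#' @param n_samples number of samples (>= 5).
#' @param seed RNG seed.
#' @return numeric matrix genes x samples.
#' @export
generate_network_data <- function(n_genes, planted_edges = NULL,
                                  n_samples = 100, seed = 1) {
  if (n_samples < 5) stop("n_samples < 5: too few samples for estimation")
  genes <- sprintf("g%d", seq_len(n_genes))
  edges <- planted_edges
  if (!is.null(edges) && nrow(edges) > 0) {
    stopifnot(all(c("a", "b") %in% names(edges)))
    if (is.null(edges$rho)) edges$rho <- 0.9
    stopifnot(all(edges$a %in% genes), all(edges$b %in% genes),
              all(edges$a != edges$b), all(abs(edges$rho) <= 1))
    key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    if (anyDuplicated(key)) stop("planted edges must form a simple graph")
  }
  with_seed(seed, {
    x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(genes, sprintf("S%d", seq_len(n_samples))))
    if (!is.null(edges) && nrow(edges) > 0) {
      adj <- lapply(setNames(vector("list", n_genes), genes), function(.) NULL)
      for (i in seq_len(nrow(edges))) {
        adj[[edges$a[i]]] <- rbind(adj[[edges$a[i]]], edges[i, ])
        adj[[edges$b[i]]] <- rbind(adj[[edges$b[i]]], edges[i, ])
      }
      seen <- character(0)
      comp_of <- function(start) { # BFS over the planted graph
        comp <- start; queue <- start
        while (length(queue)) {
          g <- queue[1]; queue <- queue[-1]
          nb <- adj[[g]]
          if (is.null(nb)) next
          nbrs <- setdiff(unique(c(nb$a, nb$b)), comp)
          comp <- c(comp, nbrs); queue <- c(queue, nbrs)
        }
        comp
      }
      edge_rho <- function(g1, g2) {
        hit <- (edges$a == g1 & edges$b == g2) | (edges$a == g2 & edges$b == g1)
        if (any(hit)) edges$rho[which(hit)[1]] else NA_real_
      }
      for (g in unique(c(edges$a, edges$b))) {
        if (g %in% seen) next
        comp <- comp_of(g)
        seen <- c(seen, comp)
        m <- length(comp)
        n_within <- sum(edges$a %in% comp)
        if (m > 2 && n_within == m * (m - 1) / 2) {
          # complete clique: exchangeable correlation via one latent factor
          rho <- edges$rho[edges$a %in% comp][1]
          f <- rnorm(n_samples)
          for (gg in comp) {
            x[gg, ] <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samples)
          }
        } else {
          # spanning tree, Markov propagation from the BFS root
          if (n_within > m - 1) {
            warning("planted component has cycles; using a spanning tree")
          }
          done <- g # root keeps its iid draw
          queue <- g
          while (length(queue)) {
            cur <- queue[1]; queue <- queue[-1]
            nb <- adj[[cur]]
            nbrs <- setdiff(unique(c(nb$a, nb$b)), c(done, cur))
            for (gg in nbrs) {
              rho <- edge_rho(cur, gg)
              if (abs(rho) >= 1) {
                x[gg, ] <- sign(rho) * x[cur, ]
              } else {
                x[gg, ] <- rho * x[cur, ] + sqrt(1 - rho^2) * rnorm(n_samples)
              }
              done <- c(done, gg); queue <- c(queue, gg)
            }
          }
        }
      }
    }
    x
  })
}
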