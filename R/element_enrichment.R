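# Promoter extraction, IUPAC motif scanning and exhaustive 3-8-mer
# overrepresentation tests (presence/absence hypergeometric, ELEMENT-style).

#' Catalog of known diel / stress cis-elements
#'
#' Time-of-day modules (morning: ME, G-box; evening: EE, GATA; midnight:
#' TBX, SBX, PBX), the ABA-responsive ABRE / ABRE-like elements, the MYB
#' binding site, and MYC2 (no published consensus here; the G-box is shipped
#' as its default binding pattern and can be overridden).
#'
#' @param MYC2 IUPAC pattern to use for MYC2 (default G-box `CACGTG`).
#' @return named character vector of IUPAC patterns.
#' @export
motif_catalog <- function(MYC2 = "CACGTG") {
  c(ME = "CCACAC", Gbox = "CACGTG",
    EE = "AATATCT", GATA = "GGATA",
    TBX = "AAACCCT", SBX = "AAGCCC", PBX = "ATGGGCC",
    ABRE = "YACGTGGC", ABRE_like = "BACGTGKM",
    MYB = "MACCWAMC", MYC2 = MYC2)
}

check_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% names(IUPAC_MAP))) {
    stop("invalid IUPAC symbol in pattern: ", pattern)
  }
  toupper(pattern)
}

#' Extract promoter sequences from a genome and gene models
#'
#' For a + strand gene the promoter is the `length` bases immediately 5' of
#' the annotated start; for a - strand gene, the reverse complement of the
#' `length` bases immediately 3' of the annotated end. Promoters are
#' truncated at contig edges (logged); zero-length promoters are skipped
#' with a warning.
#'
#' @param genome a named [Biostrings::DNAStringSet] or FASTA path.
#' @param models a [GenomicRanges::GRanges] of gene spans, or a GFF3/BED
#'   path (GFF3 `gene` features are used when present).
#' @param length promoter length in bp (the study used 500, 1000, 2000).
#' @return named [Biostrings::DNAStringSet] of promoters.
#' @export
extract_promoters <- function(genome, models, length = 2000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(models)) {
    models <- rtracklayer::import(models)
    if ("type" %in% names(S4Vectors::mcols(models)) &&
        any(models$type == "gene")) {
      models <- models[models$type == "gene"]
    }
  }
  ids <- if (!is.null(names(models)) && all(nzchar(names(models)))) {
    names(models)
  } else {
    mc <- S4Vectors::mcols(models)
    if ("ID" %in% names(mc)) as.character(mc$ID)
    else if ("name" %in% names(mc)) as.character(mc$name)
    else if ("Name" %in% names(mc)) as.character(mc$Name)
    else stop("gene models carry no usable identifiers")
  }
  chrs <- as.character(GenomicRanges::seqnames(models))
  if (!all(chrs %in% names(genome))) {
    stop("contig absent from genome: ",
         paste(setdiff(chrs, names(genome)), collapse = ", "))
  }
  strands <- as.character(GenomicRanges::strand(models))
  starts <- GenomicRanges::start(models)
  ends <- GenomicRanges::end(models)
  seqs <- character(0)
  kept <- character(0)
  for (i in seq_along(models)) {
    clen <- Biostrings::width(genome[chrs[i]])
    if (strands[i] == "-") {
      from <- ends[i] + 1L
      to <- min(ends[i] + length, clen)
    } else {
      from <- max(1L, starts[i] - length)
      to <- starts[i] - 1L
    }
    if (to < from) {
      warning("zero-length promoter for gene ", ids[i], "; skipped")
      next
    }
    if (to - from + 1L < length) {
      log_msg("promoter for %s truncated to %d bp at contig edge",
              ids[i], to - from + 1L)
    }
    s <- Biostrings::subseq(genome[[chrs[i]]], from, to)
    if (strands[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
    kept <- c(kept, ids[i])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- kept
  out
}

#' Scan promoters for an IUPAC motif
#'
#' Counts exact (possibly overlapping) occurrences of a degenerate pattern.
#' In both-strand mode (default) the reverse-complement pattern is scanned
#' too and sites are deduplicated by start position, so a palindromic site
#' counts once.
#'
#' @param promoters named [Biostrings::DNAStringSet].
#' @param pattern IUPAC pattern string.
#' @param both_strands scan the reverse complement as well (default TRUE).
#' @return data.frame: `gene_id`, `hits`, `present`.
#' @export
scan_motif <- function(promoters, pattern, both_strands = TRUE) {
  pattern <- check_iupac(pattern)
  fwd <- Biostrings::vmatchPattern(pattern, promoters, fixed = FALSE)
  starts <- lapply(fwd, IRanges::start)
  if (both_strands) {
    rcpat <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    rev <- Biostrings::vmatchPattern(rcpat, promoters, fixed = FALSE)
    starts <- Map(function(a, b) unique(c(a, b)), starts,
                  lapply(rev, IRanges::start))
  }
  hits <- vapply(starts, length, 1L)
  data.frame(gene_id = names(promoters), hits = hits, present = hits >= 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

# canonical form of each k-mer column: lexicographic min of (kmer, revcomp)
canonical_map <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

# per-gene presence counts of every canonical k-mer, accumulated in chunks
# to bound memory (k = 8 has 65,536 raw columns)
kmer_presence_counts <- function(promoters, k, gene_sets, chunk = 100L) {
  counts <- NULL
  idx <- seq_along(promoters)
  for (chunk_idx in split(idx, ceiling(idx / chunk))) {
    m <- Biostrings::oligonucleotideFrequency(promoters[chunk_idx], width = k)
    if (is.null(counts)) {
      canon <- canonical_map(colnames(m))
      keep <- !duplicated(canon)
      canon_cols <- colnames(m)[keep]
      rc_cols <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(canon_cols)))
      counts <- lapply(gene_sets, function(.) numeric(sum(keep)))
    }
    pres <- (m[, canon_cols, drop = FALSE] +
               m[, rc_cols, drop = FALSE]) > 0
    ids <- names(promoters)[chunk_idx]
    for (s in names(gene_sets)) {
      sel <- ids %in% gene_sets[[s]]
      if (any(sel)) {
        counts[[s]] <- counts[[s]] + colSums(pres[sel, , drop = FALSE])
      }
    }
  }
  lapply(counts, stats::setNames, canon_cols)
}

#' Exhaustive k-mer overrepresentation between gene sets
#'
#' Tests every canonical k-mer (a k-mer and its reverse complement collapsed
#' to the lexicographically smaller string) for over-representation among
#' foreground promoters versus background, on gene *presence* (does the
#' promoter contain the element at least once, on either strand), with a
#' one-sided hypergeometric test. Elements absent from every promoter are
#' excluded. The study applies a raw p < `alpha` cutoff; Benjamini-Hochberg
#' q-values over the full tested family are reported as an extra column.
#'
#' @param fg foreground gene ids (subset of `bg`).
#' @param bg background gene ids (all must have promoters).
#' @param promoters named [Biostrings::DNAStringSet] covering `bg`.
#' @param kmin,kmax k-mer range (default 3..8).
#' @param alpha raw p-value cutoff for the `enriched` flag (default 0.05).
#' @param allow_any_k permit k outside 3..8 (default FALSE).
#' @return data.frame sorted by p: `element`, `k`, `fg_hits`, `fg_total`,
#'   `bg_hits`, `bg_total`, `p_value`, `q_value`, `enriched`.
#' @export
kmer_enrichment <- function(fg, bg, promoters, kmin = 3, kmax = 8,
                            alpha = 0.05, allow_any_k = FALSE) {
  if (!allow_any_k && (kmin < 3 || kmax > 8)) {
    stop("k outside 3..8; set allow_any_k = TRUE to override")
  }
  stopifnot(all(fg %in% bg), kmin <= kmax)
  if (!all(bg %in% names(promoters))) stop("promoters do not cover background")
  promoters <- promoters[bg]
  res <- vector("list", kmax - kmin + 1L)
  for (k in kmin:kmax) {
    cts <- kmer_presence_counts(promoters, k,
                                list(fg = fg, bg = bg))
    keep <- cts$bg > 0
    fg_hits <- cts$fg[keep]
    bg_hits <- cts$bg[keep]
    p <- stats::phyper(fg_hits - 1, bg_hits, length(bg) - bg_hits,
                       length(fg), lower.tail = FALSE)
    res[[k - kmin + 1L]] <- data.frame(
      element = names(fg_hits), k = k,
      fg_hits = as.integer(fg_hits), fg_total = length(fg),
      bg_hits = as.integer(bg_hits), bg_total = length(bg),
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$p_value < alpha
  out <- out[order(out$p_value, out$element), ]
  rownames(out) <- NULL
  out
}

#' Catalog-motif enrichment between gene sets
#'
#' Presence-based hypergeometric over-representation of each catalog IUPAC
#' motif in `fg` versus `bg` promoters.
#'
#' @inheritParams kmer_enrichment
#' @param catalog named IUPAC patterns (default [motif_catalog()]).
#' @return data.frame: `element`, `pattern`, counts, `p_value`, `enriched`.
#' @export
catalog_enrichment <- function(fg, bg, promoters, catalog = motif_catalog(),
                               alpha = 0.05) {
  stopifnot(all(fg %in% bg), all(bg %in% names(promoters)))
  res <- lapply(names(catalog), function(nm) {
    hit <- scan_motif(promoters[bg], catalog[[nm]])
    present <- hit$gene_id[hit$present]
    K <- length(present)
    k <- length(intersect(fg, present))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, length(bg) - K,
                                          length(fg), lower.tail = FALSE)
    data.frame(element = nm, pattern = catalog[[nm]],
               fg_hits = k, fg_total = length(fg),
               bg_hits = K, bg_total = length(bg),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$enriched <- out$p_value < alpha
  out
}

#' Per-category cis-element profiles
#'
#' Runs the exhaustive k-mer test and the catalog scan for every
#' rhythm-change category (foreground = genes of the category, background =
#' every classified gene with a promoter), and, when phases are supplied, a
#' phase x element matrix of -log10 p for the catalog motifs.
#'
#' @param records data.frame from [classify_rhythm_change()].
#' @param promoters named [Biostrings::DNAStringSet].
#' @param phases optional named numeric vector gene -> phase (ZT h) used for
#'   the phase-profile matrix.
#' @param catalog named IUPAC patterns.
#' @param kmin,kmax,alpha forwarded to [kmer_enrichment()].
#' @return list with `kmer` and `catalog` (named lists of per-category
#'   tables) and `phase_profile` (matrix or NULL).
#' @export
category_element_profile <- function(records, promoters, phases = NULL,
                                     catalog = motif_catalog(),
                                     kmin = 3, kmax = 8, alpha = 0.05) {
  bg <- intersect(records$gene_id, names(promoters))
  cats <- unique(as.character(records$category))
  kmer <- list(); catal <- list()
  for (cc in cats) {
    fg <- intersect(records$gene_id[records$category == cc], bg)
    if (length(fg) == 0L) next
    if (length(fg) < 10L) {
      warning("category ", cc, " has < 10 genes; enrichment is underpowered")
    }
    kmer[[cc]] <- kmer_enrichment(fg, bg, promoters, kmin, kmax, alpha)
    catal[[cc]] <- catalog_enrichment(fg, bg, promoters, catalog, alpha)
  }
  phase_profile <- NULL
  if (!is.null(phases)) {
    ph <- round(phases[intersect(names(phases), bg)]) %% 24
    phase_profile <- matrix(0, 24, length(catalog),
                            dimnames = list(0:23, names(catalog)))
    for (h in 0:23) {
      fg <- names(ph)[ph == h]
      if (length(fg) == 0L) next
      tab <- catalog_enrichment(fg, bg, promoters, catalog, alpha)
      phase_profile[as.character(h), tab$element] <- -log10(pmax(tab$p_value,
                                                                 1e-300))
    }
  }
  list(kmer = kmer, catalog = catal, phase_profile = phase_profile)
}
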