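test_that("extract_promoters matches hand-computed fixture strings", {
  genome <- system.file("extdata", "toy_genome.fa", package = "dielshift")
  models <- system.file("extdata", "toy_models.gff3", package = "dielshift")
  # contig (60 bp): ACGTACGTACGTTTAAACCCAAAGGGTTTCCCGGGAAATTTGCATGCATGCCCGGGTTTA
  pro <- suppressWarnings(suppressMessages(
    extract_promoters(genome, models, length = 10)))
  expect_equal(as.character(pro[["geneA"]]), "GTTTAAACCC")   # [11, 20] on +
  expect_equal(as.character(pro[["geneB"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("CCCGGGTTTA"))))      # [51, 60] on -
  expect_equal(as.character(pro[["geneC"]]), "ACGTA")        # clipped to 5 bp
  # minus-strand gene ending at the contig edge is truncated and logged
  gr <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(30, 55), strand = "-")
  names(gr) <- "geneD"
  proD <- extract_promoters(Biostrings::readDNAStringSet(genome), gr, 500)
  expect_equal(unname(Biostrings::width(proD["geneD"])), 5L) # [56, 60] only
  bad <- GenomicRanges::GRanges("nope", IRanges::IRanges(5, 10), strand = "+")
  names(bad) <- "geneX"
  expect_error(extract_promoters(Biostrings::readDNAStringSet(genome), bad, 10),
               "contig absent")
})

test_that("IUPAC motif scanning expands degenerate codes and handles strands", {
  pro <- Biostrings::DNAStringSet(c(gA = "TTTTACGTGGCTTT",  # ABRE via Y = T
                                    gB = "TTTCACGTGGCTTT",  # ABRE via Y = C
                                    gC = "TTTAACGTGGCTTT",  # A not in Y
                                    gD = "TTTTTTTTTTTTTT"))
  hit <- scan_motif(pro, "YACGTGGC", both_strands = FALSE)
  expect_equal(hit$present, c(TRUE, TRUE, FALSE, FALSE))
  # palindrome: both-strand mode deduplicates the site
  pal <- Biostrings::DNAStringSet(c(g = "CACGTGTG"))
  expect_equal(scan_motif(pal, "CACGTG", both_strands = TRUE)$hits, 1L)
  # non-palindromic motif is found on the reverse strand
  rc <- Biostrings::DNAStringSet(c(g = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("TTAATATCTTT")))))
  expect_true(scan_motif(rc, "AATATCT")$present)
  expect_false(scan_motif(rc, "AATATCT", both_strands = FALSE)$present)
  # overlapping occurrences are all counted
  ov <- Biostrings::DNAStringSet(c(g = "AAAAAA"))
  expect_equal(scan_motif(ov, "AAAA", both_strands = FALSE)$hits, 3L)
  expect_error(scan_motif(pro, "ACGTQ"), "invalid IUPAC")
})

test_that("planted motifs are recovered exactly at their offsets", {
  set.seed(91)
  planted <- data.frame(gene_id = sprintf("g%d", 1:8),
                        motif = "AATATCT",
                        offset = c(0L, 10L, 25L, 40L, 55L, 70L, 85L, 93L),
                        strand = rep(c("+", "-"), 4))
  pro <- generate_promoters(planted, length = 100, gc = 0.5, seed = 92)
  for (i in seq_len(8)) {
    s <- pro[[planted$gene_id[i]]]
    found <- c(IRanges::start(Biostrings::matchPattern("AATATCT", s)),
               IRanges::start(Biostrings::matchPattern(
                 Biostrings::reverseComplement(Biostrings::DNAString("AATATCT")), s)))
    expect_true((planted$offset[i] + 1L) %in% found)
  }
})

test_that("kmer enrichment p-values equal the hypergeometric oracle and obey laws", {
  planted <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    motif = c(rep("GATCGAT", 16), rep(NA, 24)),
    offset = 20L, strand = "+")
  pro <- generate_promoters(planted, length = 120, gc = 0.5, seed = 93)
  fg <- sprintf("g%02d", 1:20)                       # 16 of 20 carry the motif
  bg <- names(pro)
  res <- kmer_enrichment(fg, bg, pro, kmin = 6, kmax = 7)
  canon <- pmin("GATCGAT", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GATCGAT"))))
  row <- res[res$element == canon, ][1, ]
  expect_gte(row$fg_hits, 16L)
  expect_equal(row$p_value,
               hyper_tail(row$fg_hits, row$bg_hits, row$bg_total, row$fg_total),
               tolerance = 1e-12)
  expect_equal(row$p_value, min(res$p_value))        # smallest p of the family
  # fg == bg: nothing enriched
  same <- kmer_enrichment(bg, bg, pro, kmin = 3, kmax = 3)
  expect_true(all(same$p_value == 1))
  expect_false(any(same$enriched))
  # absent elements are excluded from output
  expect_false(any(grepl("N", res$element)))
  expect_true(all(res$bg_hits > 0))
  expect_error(kmer_enrichment(fg, bg, pro, kmin = 2, kmax = 3), "3..8")

  # strand involution: reverse-complementing every promoter changes nothing
  rcpro <- Biostrings::reverseComplement(pro)
  names(rcpro) <- names(pro)
  res_rc <- kmer_enrichment(fg, bg, rcpro, kmin = 6, kmax = 7)
  expect_equal(res_rc[order(res_rc$element), c("element", "fg_hits", "p_value")],
               res[order(res$element), c("element", "fg_hits", "p_value")])

  # monotonicity: adding a carrier foreground gene cannot increase the p-value
  extra <- generate_promoters(data.frame(gene_id = "g41", motif = "GATCGAT",
                                         offset = 5L, strand = "+"),
                              length = 120, gc = 0.5, seed = 94)
  pro2 <- c(pro, extra)
  res2 <- kmer_enrichment(c(fg, "g41"), c(bg, "g41"), pro2, kmin = 7, kmax = 7)
  expect_lte(res2$p_value[res2$element == canon],
             res$p_value[res$element == canon])
})

test_that("category profiles localise planted elements to their category", {
  genes <- sprintf("g%03d", 1:60)
  cat_of <- rep(c("DR_only", "WW_only", "arrhythmic"), each = 20)
  planted <- data.frame(gene_id = genes,
                        motif = ifelse(cat_of == "DR_only", "TACGTGGC", NA),
                        offset = 50L, strand = "+")
  pro <- generate_promoters(planted, length = 300, gc = 0.5, seed = 95)
  records <- data.frame(gene_id = genes, category = cat_of)
  prof <- suppressWarnings(category_element_profile(
    records, pro, kmin = 3, kmax = 4))
  abre_dr <- prof$catalog$DR_only
  abre_ww <- prof$catalog$WW_only
  expect_true(abre_dr$enriched[abre_dr$element == "ABRE"])
  expect_false(abre_ww$enriched[abre_ww$element == "ABRE"])
  # identical promoters across categories: no category-specific enrichment
  flat <- generate_promoters(data.frame(gene_id = genes, motif = NA,
                                        offset = NA, strand = NA),
                             length = 100, gc = 0.5, seed = 1)
  uni <- Biostrings::DNAStringSet(rep(as.character(flat[[1]]), 60))
  names(uni) <- genes
  prof2 <- suppressWarnings(category_element_profile(records, uni,
                                                     kmin = 3, kmax = 3))
  expect_true(all(prof2$kmer$DR_only$p_value == 1))
})
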