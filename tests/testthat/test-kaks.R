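# Interallelic Ka/Ks: haplotype CDS reconstruction and the Nei-Gojobori
# pathway-counting estimator against a brute-force oracle.

.codons <- function() {
  bases <- c("A", "C", "G", "T")
  all3 <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
  apply(all3, 1, paste, collapse = "")
}

test_that("identical haplotypes give Ka = Ks = 0", {
  cds <- haplotype_cds("g", "ATGAAATTTGGG", "ATGAAATTTGGG")
  res <- nei_gojobori(cds)
  expect_equal(res$Ka, 0); expect_equal(res$Ks, 0)
  expect_equal(res$Nd, 0); expect_equal(res$Sd, 0)
  expect_true(is.na(res$ratio))
})

test_that("a single synonymous difference counts as Sd = 1", {
  cds <- haplotype_cds("g", "TTT", "TTC")  # Phe -> Phe
  res <- nei_gojobori(cds)
  expect_equal(res$Sd, 1); expect_equal(res$Nd, 0)
  expect_equal(res$Ka, 0)
  # pS = 3 on a single codon is outside the Jukes-Cantor domain: flagged
  expect_true(is.na(res$Ks))
  # on a longer gene the corrected Ks is positive
  res_l <- nei_gojobori(haplotype_cds("g", "TTTAAAGGGCCCTTTAAAGGGCCC",
                                      "TTCAAAGGGCCCTTTAAAGGGCCC"))
  expect_equal(res_l$Sd, 1)
  expect_gt(res_l$Ks, 0)
  expect_equal(res_l$Ka, 0)
  # and a single nonsynonymous one as Nd = 1, with ratio = Inf
  cds2 <- haplotype_cds("g", "TTT", "GTT")  # Phe -> Val
  res2 <- nei_gojobori(cds2)
  expect_equal(res2$Nd, 1); expect_equal(res2$Sd, 0)
  expect_equal(res2$ratio, Inf)
})

test_that("per-codon site fractions sum to 3", {
  tab <- introscan:::.codon_table()
  sense <- Filter(function(cdn) tab[cdn] != "*", .codons())
  for (cdn in sample(sense, 20)) {
    st <- introscan:::.codon_sites(cdn, tab)
    expect_equal(unname(st["S"] + st["N"]), 3)
  }
})

test_that("all 1- and 2-difference codon pairs match the pathway oracle", {
  skip_if_not_installed("seqinr")
  tab <- introscan:::.codon_table()
  sense <- Filter(function(cdn) tab[cdn] != "*", .codons())
  set.seed(6)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (c1 in sense) {
    x <- strsplit(c1, "")[[1]]
    # all single-position changes
    for (p in 1:3) for (b in setdiff(bases, x[p])) {
      y <- x; y[p] <- b
      c2 <- paste(y, collapse = "")
      if (tab[c2] == "*") next
      got <- introscan:::.codon_diffs(c1, c2, tab)
      orc <- ng_codon_oracle(c1, c2)
      expect_equal(unname(got["Sd"]), unname(orc["Sd"]))
      expect_equal(unname(got["Nd"]), unname(orc["Nd"]))
      n_checked <- n_checked + 1
    }
  }
  # two-position changes: sampled exhaustively over a random subset
  for (c1 in sample(sense, 20)) {
    x <- strsplit(c1, "")[[1]]
    for (pp in list(c(1, 2), c(1, 3), c(2, 3))) {
      y <- x
      y[pp[1]] <- sample(setdiff(bases, x[pp[1]]), 1)
      y[pp[2]] <- sample(setdiff(bases, x[pp[2]]), 1)
      c2 <- paste(y, collapse = "")
      if (tab[c2] == "*") next
      got <- introscan:::.codon_diffs(c1, c2, tab)
      orc <- ng_codon_oracle(c1, c2)
      expect_equal(unname(got["Sd"]), unname(orc["Sd"]))
      expect_equal(unname(got["Nd"]), unname(orc["Nd"]))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 500)
})

test_that("a 30-codon gene matches the full brute-force oracle", {
  skip_if_not_installed("seqinr")
  tab <- introscan:::.codon_table()
  sense <- Filter(function(cdn) tab[cdn] != "*", .codons())
  set.seed(13)
  c1 <- sample(sense, 30, replace = TRUE)
  c2 <- c1
  # plant 6 mutated codons with 1-3 differences each
  for (i in sample(30, 6)) {
    repeat {
      y <- strsplit(c1[i], "")[[1]]
      for (p in sample(1:3, sample(1:3, 1)))
        y[p] <- sample(c("A", "C", "G", "T"), 1)
      cand <- paste(y, collapse = "")
      if (tab[cand] != "*") { c2[i] <- cand; break }
    }
  }
  cds <- haplotype_cds("toy", paste(c1, collapse = ""),
                       paste(c2, collapse = ""))
  res <- nei_gojobori(cds)
  orc_S <- sum(vapply(c1, function(cdn)
    introscan:::.codon_sites(cdn, tab)["S"], numeric(1)))
  orc_d <- rowSums(vapply(seq_len(30), function(i)
    ng_codon_oracle(c1[i], c2[i]), numeric(2)))
  expect_equal(res$S, orc_S)
  expect_equal(res$N, 90 - orc_S)
  expect_equal(res$Sd, unname(orc_d["Sd"]))
  expect_equal(res$Nd, unname(orc_d["Nd"]))
})

test_that("difference counts are invariant to swapping the haplotypes", {
  cds <- haplotype_cds("g", "ATGAAATTTGGGCCA", "ATGAGATTCGGGCCG")
  a <- nei_gojobori(cds)
  b <- nei_gojobori(haplotype_cds("g", cds$hap2, cds$hap1))
  expect_equal(a$Nd, b$Nd); expect_equal(a$Sd, b$Sd)
  # with symmetric site counting every output matches
  a2 <- nei_gojobori(cds, site_counting = "average")
  b2 <- nei_gojobori(haplotype_cds("g", cds$hap2, cds$hap1),
                     site_counting = "average")
  expect_equal(a2[c("N", "S", "Nd", "Sd", "Ka", "Ks")],
               b2[c("N", "S", "Nd", "Sd", "Ka", "Ks")])
})

test_that("CDS reconstruction applies phased variants, masks indels, and
           demands phase in multi-het codons", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "NNNN", "ATGAAATTTGGGCCATAA", "NNNN")))
  cds <- data.frame(chrom = "chr1", start = 5L, end = 22L, strand = "+")
  mk_panel <- function(pos, ref_a, alt_a, g1, g2, phased = TRUE) {
    haplotype_panel(
      data.frame(id = "F1", population = "focal"),
      data.frame(chrom = rep("chr1", length(pos)), pos = pos, ref = ref_a,
                 alt = alt_a, stringsAsFactors = FALSE),
      matrix(g1, length(pos), 1), matrix(g2, length(pos), 1),
      matrix(phased, length(pos), 1),
      matrix(60L, length(pos), 1))
  }
  # no variants: both haplotypes equal the reference CDS
  p0 <- mk_panel(integer(0), character(0), character(0), integer(0),
                 integer(0))
  h0 <- reconstruct_haplotype_cds(ref, cds, p0, "F1")
  expect_equal(h0$hap1, "ATGAAATTTGGGCCATAA")
  expect_equal(h0$hap1, h0$hap2)
  # one het SNP changes exactly one codon on one haplotype
  p1 <- mk_panel(8L, "A", "G", 0L, 1L)
  h1 <- reconstruct_haplotype_cds(ref, cds, p1, "F1")
  expect_equal(h1$hap1, "ATGAAATTTGGGCCATAA")
  expect_equal(h1$hap2, "ATGGAATTTGGGCCATAA")
  # cis vs trans phase of two het SNPs in one codon differ in outcome
  cis <- mk_panel(c(8L, 9L), c("A", "A"), c("G", "C"), c(0L, 0L), c(1L, 1L))
  trans <- mk_panel(c(8L, 9L), c("A", "A"), c("G", "C"), c(0L, 1L),
                    c(1L, 0L))
  hc <- reconstruct_haplotype_cds(ref, cds, cis, "F1")
  ht <- reconstruct_haplotype_cds(ref, cds, trans, "F1")
  expect_equal(substr(hc$hap2, 4, 6), "GCA")
  expect_equal(substr(ht$hap1, 4, 6), "ACA")
  expect_equal(substr(ht$hap2, 4, 6), "GAA")
  # unphased multi-het genotypes are refused
  unph <- mk_panel(c(8L, 9L), c("A", "A"), c("G", "C"), c(0L, 0L),
                   c(1L, 1L), phased = FALSE)
  expect_error(reconstruct_haplotype_cds(ref, cds, unph, "F1"), "phase")
  # a deletion masks its codon
  pdel <- mk_panel(8L, "AT", "A", 0L, 1L)
  hd <- reconstruct_haplotype_cds(ref, cds, pdel, "F1")
  expect_equal(hd$masked_codons, 2L)
  # site totals: 6 codons minus the masked one minus the terminal stop
  res <- nei_gojobori(hd)
  expect_equal(res$N + res$S, 3 * (6 - 2))
})

test_that("minus-strand CDS are reconstructed in reading frame", {
  # plus-strand gene ATGAAATAA lives reverse-complemented in the genome
  gene <- "ATGAAATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0("CCCC", rc, "CCCC")))
  cds <- data.frame(chrom = "chr1", start = 5L, end = 13L, strand = "-")
  panel <- haplotype_panel(
    data.frame(id = "F1", population = "focal"),
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0)),
    matrix(integer(0), 0, 1), matrix(integer(0), 0, 1),
    matrix(logical(0), 0, 1), matrix(integer(0), 0, 1))
  h <- reconstruct_haplotype_cds(ref, cds, panel, "F1")
  expect_equal(h$hap1, gene)
})

test_that("the ratio test behaves at its analytic anchor points", {
  cds0 <- haplotype_cds("g", "ATGAAA", "ATGAAA")
  expect_equal(kaks_ratio_test(nei_gojobori(cds0)), 1)
  # pN = pS exactly: one-sided p = 0.5 by symmetry
  res <- nei_gojobori(haplotype_cds("g", "TTTAAA", "TTCAGA"))
  fake <- res; fake$pN <- 0.1; fake$pS <- 0.1; fake$Nd <- 1; fake$Sd <- 1
  expect_equal(kaks_ratio_test(fake), 0.5)
  # strong nonsynonymous excess is significant
  set.seed(3)
  tab <- introscan:::.codon_table()
  c1 <- rep("TTT", 60)
  c2 <- rep("GTT", 60)  # every codon nonsynonymously changed
  resx <- nei_gojobori(haplotype_cds("g", paste(c1, collapse = ""),
                                     paste(c2, collapse = "")))
  expect_lt(kaks_ratio_test(resx), 0.05)
})
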