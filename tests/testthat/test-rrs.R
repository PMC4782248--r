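# In silico RAD / ddRAD: conserved-site discovery, capture-interval
# geometry, fragment size selection, and agreement with a brute-force
# position-by-position oracle.

.rand_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive string-scan oracle for recognition-site starts
.scan_oracle <- function(seq_chr, site) {
  w <- nchar(site)
  hits <- integer(0)
  for (p in seq_len(nchar(seq_chr) - w + 1L))
    if (substr(seq_chr, p, p + w - 1L) == site) hits <- c(hits, p)
  hits
}

test_that("conserved-site discovery honors fixed-difference exclusion", {
  s <- paste0(strrep("A", 100), "CCTGCAGG", strrep("A", 100))
  ref <- Biostrings::DNAStringSet(c(chr1 = s))
  enz <- default_enzymes()$SbfI
  expect_equal(find_conserved_sites(ref, "chr1", integer(0), enz), 101L)
  # a fixed difference anywhere inside the 8-mer disqualifies the site
  for (off in 0:7)
    expect_equal(length(find_conserved_sites(ref, "chr1", 101L + off, enz)), 0)
  # a difference adjacent to the footprint does not
  expect_equal(find_conserved_sites(ref, "chr1", c(100L, 109L), enz), 101L)
})

test_that("site scanning equals the naive string-scan oracle", {
  s <- .rand_seq(100000, seed = 7)
  ref <- Biostrings::DNAStringSet(c(chr1 = s))
  for (enz in default_enzymes()[c("MspI", "EcoRI")]) {
    got <- find_conserved_sites(ref, "chr1", integer(0), enz)
    expect_equal(got, .scan_oracle(s, enz$site))
  }
})

test_that("palindromic recognition makes forward scanning strand-complete", {
  s <- .rand_seq(50000, seed = 8)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (enz in default_enzymes()) {
    fwd <- .scan_oracle(s, enz$site)
    rev_hits <- .scan_oracle(rc, enz$site)
    # map reverse-strand starts back to forward coordinates
    remapped <- sort(nchar(s) - (rev_hits + enz$width - 1L) + 1L)
    expect_equal(fwd, remapped)
  }
})

test_that("RAD capture intervals follow the paired-end read geometry", {
  # site footprint at 0-based 10000 (1-based 10001), width 8
  iv <- rad_capture_intervals(10001L, 8L)
  expect_equal(iv$start, c(9901L, 10009L, 9501L, 10409L))
  expect_equal(iv$end, c(10000L, 10108L, 9600L, 10508L))
  # a planted SNP 50 bp upstream is captured; one 250 bp away is not
  covered <- function(p) any(p >= iv$start & p <= iv$end)
  expect_true(covered(9951))
  expect_false(covered(10001 - 250))
  # near-chromosome-start sites are clipped, never negative
  iv2 <- rad_capture_intervals(31L, 8L, chrom_len = 100000)
  expect_true(all(iv2$start >= 1))
  expect_true(all(iv2$end >= iv2$start))
})

test_that("ddRAD keeps only two-enzyme fragments in the size window", {
  enzs <- default_enzymes()
  mk <- function(gap, extra = "") {
    # EcoRI site, gap of A's (with optional insert), MspI site
    paste0(strrep("T", 50), "GAATTC",
           if (nchar(extra)) paste0(strrep("A", 75), extra,
                                    strrep("A", gap - 75 - nchar(extra)))
           else strrep("A", gap),
           "CCGG", strrep("T", 50))
  }
  # footprint-to-footprint length = 6 + gap + 4
  ref <- Biostrings::DNAStringSet(c(chr1 = mk(290)))  # length 300
  dd <- ddrad_fragments(ref, "chr1", enzs$EcoRI, enzs$MspI)
  expect_equal(nrow(dd$fragments), 1)
  expect_equal(dd$fragments$length, 300L)
  # internal EcoRI site breaks the fragment
  ref2 <- Biostrings::DNAStringSet(c(chr1 = mk(290, "GAATTC")))
  dd2 <- ddrad_fragments(ref2, "chr1", enzs$EcoRI, enzs$MspI)
  expect_equal(nrow(dd2$fragments), 0)
  # length 337 is just outside 300 +/- 36
  ref3 <- Biostrings::DNAStringSet(c(chr1 = mk(327)))
  expect_equal(nrow(ddrad_fragments(ref3, "chr1", enzs$EcoRI,
                                    enzs$MspI)$fragments), 0)
  # length 336 is just inside
  ref4 <- Biostrings::DNAStringSet(c(chr1 = mk(326)))
  expect_equal(nrow(ddrad_fragments(ref4, "chr1", enzs$EcoRI,
                                    enzs$MspI)$fragments), 1)
  expect_error(ddrad_fragments(ref, "chr1", enzs$EcoRI, enzs$EcoRI), "differ")
})

test_that("widening the ddRAD size tolerance never loses fragments", {
  s <- .rand_seq(200000, seed = 12)
  ref <- Biostrings::DNAStringSet(c(chr1 = s))
  enzs <- default_enzymes()
  n36 <- nrow(ddrad_fragments(ref, "chr1", enzs$EcoRI, enzs$MspI,
                              tol = 36)$fragments)
  n72 <- nrow(ddrad_fragments(ref, "chr1", enzs$EcoRI, enzs$MspI,
                              tol = 72)$fragments)
  expect_gte(n72, n36)
})

test_that("captured SNPs are counted once and bounded by the WGS total", {
  tracts <- data.frame(chrom = "chr1", start = 1L, end = 1000L)
  diag_sites <- data.frame(chrom = "chr1", pos = c(100L, 500L, 900L),
                           allele_A = "G", allele_B = "T", allele_out = "G",
                           B_specific = c(TRUE, TRUE, FALSE))
  overlapping <- data.frame(start = c(50L, 80L), end = c(150L, 120L))
  cc <- count_captured(tracts, list(rad = overlapping), diag_sites)
  expect_equal(cc$wgs, 2L)   # only B-specific sites count
  expect_equal(cc$rad, 1L)   # SNP at 100 covered twice, counted once
  none <- count_captured(tracts, list(rad = data.frame(start = integer(),
                                                       end = integer())),
                         diag_sites)
  expect_equal(none$rad, 0L)
})

test_that("capture pipeline equals the brute-force oracle on 50-kb sequences", {
  b <- simulate_bundle(simulation_config(
    seed = 31, chrom_lengths = c(chr1 = 50000L),
    tracts = data.frame(chrom = "chr1", start = 10001L, end = 40000L,
                        carriers = "F1,F2", zygosity = "het")))
  tracts <- data.frame(chrom = "chr1", start = 10001L, end = 40000L)
  ds <- b$truth$diagnostic_sites
  crep <- capture_report(b$reference, tracts, ds)
  s <- as.character(b$reference[["chr1"]])
  enzs <- default_enzymes()
  fd <- ds$pos
  bs <- ds$pos[ds$B_specific]
  bs_in <- bs[bs >= 10001 & bs <= 40000]
  expect_equal(crep$wgs, length(bs_in))
  # oracle: position-by-position membership in RAD capture regions around
  # conserved SbfI sites inside the tract
  sb <- .scan_oracle(substr(s, 10001, 40000), enzs$SbfI$site) + 10000L
  sb <- sb[vapply(sb, function(p) !any(fd >= p & fd <= p + 7L), logical(1))]
  rad_hit <- vapply(bs_in, function(p) {
    any(vapply(sb, function(site) {
      e <- site + 7L
      (p >= site - 100 && p <= site - 1) || (p >= e + 1 && p <= e + 100) ||
        (p >= site - 500 && p <= site - 401) || (p >= e + 401 && p <= e + 500)
    }, logical(1)))
  }, logical(1))
  expect_equal(crep$rad_sbfi, sum(rad_hit))
  # ddRAD oracle for EcoRI-MspI
  dd_oracle <- function(enzA, enzB) {
    reg <- substr(s, 10001, 40000)
    sa <- .scan_oracle(reg, enzA$site) + 10000L
    sa <- sa[vapply(sa, function(p) !any(fd >= p & fd <= p + enzA$width - 1L),
                    logical(1))]
    sbx <- .scan_oracle(reg, enzB$site) + 10000L
    sbx <- sbx[vapply(sbx, function(p) !any(fd >= p & fd <= p + enzB$width - 1L),
                      logical(1))]
    all_sites <- rbind(data.frame(p = sa, w = enzA$width, e = "A"),
                       data.frame(p = sbx, w = enzB$width, e = "B"))
    all_sites <- all_sites[order(all_sites$p), ]
    hits <- rep(FALSE, length(bs_in))
    if (nrow(all_sites) >= 2) for (i in seq_len(nrow(all_sites) - 1)) {
      if (all_sites$e[i] == all_sites$e[i + 1]) next
      fs <- all_sites$p[i]; fe <- all_sites$p[i + 1] + all_sites$w[i + 1] - 1L
      len <- fe - fs + 1L
      if (len < 264 || len > 336) next
      hits <- hits | (bs_in >= fs & bs_in <= min(fs + 99L, fe)) |
        (bs_in >= max(fe - 99L, fs) & bs_in <= fe)
    }
    sum(hits)
  }
  expect_equal(crep$ddrad_ecori_mspi, dd_oracle(enzs$EcoRI, enzs$MspI))
  expect_equal(crep$ddrad_sphi_mspi, dd_oracle(enzs$SphI, enzs$MspI))
})
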