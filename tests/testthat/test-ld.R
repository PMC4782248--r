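# Amplicon SNP filter, HWE exact test, D', genetic distance from a
# smoothed recombination map, and LD-decay fitting.

test_that("HWE exact test matches the allele-placement oracle up to n = 10", {
  for (n in c(3, 5, 8, 10)) {
    for (na in 1:n) {
      for (h in seq(na %% 2, na, by = 2)) {
        nAA_rare <- (na - h) / 2
        naa <- n - h - nAA_rare
        got <- hwe_exact(nAA_rare, h, naa)
        orc <- hwe_placement_oracle(nAA_rare, h, naa)
        expect_equal(got, orc, tolerance = 1e-10)
      }
    }
  }
  expect_equal(hwe_exact(48, 0, 0), 1)       # monomorphic
  expect_lt(hwe_exact(0, 48, 0), 0.05)       # extreme heterozygote excess
})

test_that("the amplicon SNP filter applies all five rules", {
  # 48 individuals; markers: 133 clean, 23 singletons, 13 HWE failures,
  # plus one triallelic, one indel-like and one low-depth marker
  n_ind <- 48
  mk_col <- function(nAA, nAa, naa)
    c(rep(list(c(0L, 0L)), nAA), rep(list(c(0L, 1L)), nAa),
      rep(list(c(1L, 1L)), naa))
  clean <- mk_col(12, 24, 12)                   # HWE-conformant, common
  singleton <- mk_col(47, 1, 0)
  hwe_fail <- mk_col(24, 0, 24)                 # total het deficit
  tri <- c(rep(list(c(0L, 1L)), 24), rep(list(c(0L, 2L)), 24))
  lowdp <- clean
  site_cols <- c(replicate(133, clean, simplify = FALSE),
                 replicate(23, singleton, simplify = FALSE),
                 replicate(13, hwe_fail, simplify = FALSE),
                 list(tri), list(lowdp))
  n_site <- length(site_cols)
  geno <- lapply(seq_len(n_ind), function(i)
    lapply(site_cols, function(sc) sc[[i]]))
  panel <- toy_panel(geno, ref = rep("G", n_site),
                     alt = rep("T,A", n_site), depth = 50)
  panel$sites$alt[n_site - 1L] <- "T,A"         # triallelic in use
  panel$sites$ref[n_site] <- "GA"               # indel-like record
  # depth exactly 20 fails the strict >20 amplicon rule at one marker
  panel$depth[n_site, 1] <- 20L
  fl <- filter_snps(panel)
  expect_equal(sum(fl$keep), 133)
  expect_equal(fl$n_singleton, 23)
  expect_equal(fl$n_hwe, 13)
  expect_false(fl$keep[n_site - 1L])  # triallelic removed
  expect_false(fl$keep[n_site])       # indel/low-depth removed
})

test_that("D' matches the 2x2-table computation on random configurations", {
  # perfectly coupled markers
  hapA <- rep(c(0, 1), each = 20); hapB <- hapA
  expect_equal(dprime(hapA, hapB)$Dprime, 1)
  # independent equifrequent markers with exactly balanced counts
  h1 <- c(rep(0, 50), rep(1, 50))
  h2 <- c(rep(0, 25), rep(1, 25), rep(0, 25), rep(1, 25))
  expect_equal(dprime(h1, h2)$Dprime, 0)
  # hand-specified table (40, 10, 10, 40)
  hA <- c(rep(1, 40), rep(1, 10), rep(0, 10), rep(0, 40))
  hB <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(dprime(hA, hB)$Dprime, dprime_table_oracle(40, 10, 10, 40))
  # 20 random haplotype configurations against the table oracle
  set.seed(2)
  for (k in 1:20) {
    n <- c(sample(1:30, 2), sample(1:30, 2))
    a <- c(rep(1, n[1]), rep(1, n[2]), rep(0, n[3]), rep(0, n[4]))
    b <- c(rep(1, n[1]), rep(0, n[2]), rep(1, n[3]), rep(0, n[4]))
    expect_equal(dprime(a, b)$Dprime,
                 dprime_table_oracle(n[1], n[2], n[3], n[4]))
    # allele-label swap invariance
    expect_equal(dprime(1 - a, b)$Dprime, dprime(a, b)$Dprime)
    expect_equal(dprime(a, 1 - b)$Dprime, dprime(a, b)$Dprime)
  }
  # monomorphic marker is flagged undefined
  expect_true(is.na(dprime(rep(0, 10), rep(c(0, 1), 5))$Dprime))
})

test_that("genetic distance integrates the smoothed map correctly", {
  # constant 3 cM/Mb over 1 Mb: distance is 3 cM and endpoints give 0
  obs <- data.frame(pos = seq(0, 2e6, by = 50000), rate = 3)
  m <- recombination_map(obs)
  expect_equal(genetic_distance(m, 5e5, 15e5), 3, tolerance = 1e-9)
  expect_equal(genetic_distance(m, 7e5, 7e5), 0)
  expect_error(genetic_distance(m, -10, 5e5), "outside")
  # piecewise-linear map: integral of the smoothed curve matches adaptive
  # quadrature of the package's own rate function to high accuracy
  obs2 <- data.frame(pos = seq(0, 4e6, by = 40000))
  obs2$rate <- ifelse(obs2$pos < 2e6, 1 + obs2$pos / 1e6, 5 - obs2$pos / 1e6)
  m2 <- recombination_map(obs2)
  for (pp in list(c(1e5, 3.9e6), c(5e5, 1.5e6), c(2.2e6, 3.1e6))) {
    oracle <- stats::integrate(function(x) m2$rate_fun(x) / 1e6,
                               pp[1], pp[2], rel.tol = 1e-7,
                               subdivisions = 2000L,
                               stop.on.error = FALSE)$value
    expect_equal(genetic_distance(m2, pp[1], pp[2]), oracle,
                 tolerance = 1e-5)
  }
  # additivity
  expect_equal(genetic_distance(m2, 1e5, 3e6),
               genetic_distance(m2, 1e5, 1e6) +
                 genetic_distance(m2, 1e6, 3e6), tolerance = 1e-9)
})

test_that("decay fit recovers the generating t and flags degeneracy", {
  set.seed(10)
  d <- runif(200, 0.05, 5)
  dp <- pmin(1, pmax(0, (1 - d / 100)^50 + rnorm(200, 0, 0.03)))
  pairs <- data.frame(Dprime = dp, d_cM = d, category = "within")
  fit <- fit_decay(pairs)
  expect_gt(fit$t_hat, 40); expect_lt(fit$t_hat, 60)
  expect_true(fit$ci_lo <= 50 && 50 <= fit$ci_hi)
  # all D' = 1: the model forces t = 0
  deg <- data.frame(Dprime = 1, d_cM = runif(10, 0, 4), category = "within")
  fdeg <- fit_decay(deg)
  expect_equal(fdeg$t_hat, 0)
  expect_true(fdeg$degenerate)
})

test_that("decay model limits hold: t = 0 or theta = 0 give D' = 1", {
  expect_equal((1 - 0.03)^0, 1)
  d0 <- data.frame(Dprime = rep(1, 10), d_cM = rep(0, 10),
                   category = "within")
  f <- fit_decay(d0)
  expect_equal(f$t_hat, 0)
})

test_that("diagnostic allele frequency is the mean per-site B fraction", {
  # 24 het + 24 homA at one diagnostic site: frequency 0.25
  geno <- lapply(1:48, function(i) list(if (i <= 24) c(0L, 1L) else c(0L, 0L)))
  panel <- toy_panel(geno, population = "focal")
  ds <- data.frame(chrom = "chr1", pos = 1L, allele_A = "G", allele_B = "T",
                   allele_out = "G", B_specific = TRUE,
                   stringsAsFactors = FALSE)
  amp <- data.frame(chrom = "chr1", start = 1L, end = 10L)
  got <- diag_allele_freq(panel, ds, amp)
  expect_equal(got$freq_B, 0.25)
  # all homA gives 0; an amplicon without diagnostic sites is flagged NA
  panel0 <- toy_panel(lapply(1:48, function(i) list(c(0L, 0L))),
                      population = "focal")
  expect_equal(diag_allele_freq(panel0, ds, amp)$freq_B, 0)
  amp2 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_true(is.na(diag_allele_freq(panel, ds, amp2)$freq_B))
})

test_that("recent introgression slows LD decay inside the tract", {
  set.seed(77)
  pos <- seq(50000, 4950000, by = 50000)           # 99 markers over 5 Mb
  obs <- data.frame(pos = seq(0, 5e6, by = 50000), rate = 3)
  m <- recombination_map(obs)
  cm <- vapply(pos, function(p) m$map_fun(p), numeric(1))
  zone <- c(2e6, 3e6)
  hap <- simulate_ld_panel(pos, cm, zone, n_hap = 200, t_old = 150,
                           t_recent = 8, donor_freq = 0.3)
  markers <- data.frame(chrom = "chr1", pos = pos)
  poly <- apply(hap, 2, function(x) mean(x) > 0.05 & mean(x) < 0.95)
  pl <- pair_ld(markers[poly, , drop = FALSE], hap[, poly, drop = FALSE],
                m, zone)
  fit <- fit_decay(pl, max_cM = 5)
  t_within <- fit$t_hat[fit$category == "within"]
  t_outside <- fit$t_hat[fit$category == "outside"]
  expect_gt(length(t_within), 0)
  expect_gt(length(t_outside), 0)
  expect_lt(t_within, t_outside)
})
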