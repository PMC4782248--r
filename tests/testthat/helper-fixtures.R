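# Shared fixtures and independent oracles used across test files.

# one medium simulated bundle reused by several files: 1 Mb, one planted
# 450-kb heterozygous tract carried by 3 of 4 focal individuals
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        seed = 42,
        chrom_lengths = c(chr1 = 1000000L),
        tracts = data.frame(chrom = "chr1", start = 300001L, end = 750000L,
                            carriers = "F1,F2,F3", zygosity = "het",
                            stringsAsFactors = FALSE))
      cache <<- simulate_bundle(cfg)
    }
    cache
  }
})

# tiny hand-built panel: `geno` is a list of per-individual lists of
# c(a1, a2) allele indices; one chromosome, positions 1..n_sites
toy_panel <- function(geno, ref = NULL, alt = NULL, depth = 50,
                      population = "pop") {
  n_ind <- length(geno)
  n_site <- length(geno[[1]])
  g1 <- sapply(geno, function(gg) vapply(gg, `[`, 0L, 1L))
  g2 <- sapply(geno, function(gg) vapply(gg, `[`, 0L, 2L))
  g1 <- matrix(as.integer(g1), n_site, n_ind)
  g2 <- matrix(as.integer(g2), n_site, n_ind)
  if (is.null(ref)) ref <- rep("G", n_site)
  if (is.null(alt)) alt <- rep("T", n_site)
  ids <- if (!is.null(names(geno))) names(geno) else
    paste0("i", seq_len(n_ind))
  haplotype_panel(
    data.frame(id = ids,
               population = rep_len(population, n_ind),
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = seq_len(n_site), ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    g1, g2, TRUE, matrix(as.integer(depth), n_site, n_ind))
}

# independent oracle for the per-site heterozygosity term: mean over all
# ordered chromosome pairs of the indicator that the two alleles differ,
# scaled to the unbiased estimator n/(n-1) * (1 - sum x^2) equivalence is
# exactly mean pairwise difference over unordered pairs
pairwise_het_oracle <- function(alleles) {
  n <- length(alleles)
  diff_count <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    diff_count <- diff_count + (alleles[a] != alleles[b])
  diff_count / choose(n, 2) * 1  # mean pairwise difference
}

# brute-force Mann-Whitney U via pair counting (independent of ranks)
mwu_paircount_oracle <- function(x, y) {
  U <- 0
  for (xi in x) for (yj in y) U <- U + (xi > yj) + 0.5 * (xi == yj)
  mu <- length(x) * length(y) / 2
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  Us <- apply(idx, 2, function(k) {
    U2 <- 0
    for (xi in pool[k]) for (yj in pool[-k]) U2 <- U2 + (xi > yj) + 0.5 * (xi == yj)
    U2
  })
  list(U = U, p = mean(abs(Us - mu) >= abs(U - mu) - 1e-9))
}

# exact HWE null distribution by exhaustive placement of the `na` rare
# alleles into the 2n ordered allele slots (slots 2i-1, 2i form individual
# i); every placement is equally likely under the null
hwe_placement_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (na == 0) return(1)
  cmb <- utils::combn(2 * n, na)
  pair <- ceiling(cmb / 2)
  dup <- if (na > 1)
    colSums(pair[-1, , drop = FALSE] == pair[-na, , drop = FALSE]) else
    rep(0L, ncol(cmb))
  hets <- na - 2L * dup
  pmf <- table(factor(hets, levels = seq(na %% 2, na, by = 2))) / ncol(cmb)
  obs <- as.character(nAa)
  sum(pmf[pmf <= pmf[[obs]] * (1 + 1e-9)])
}

# D' from the explicit 2x2 haplotype table (independent route)
dprime_table_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  if (D == 0) return(0)
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  abs(D / Dmax)
}

# brute-force Nei-Gojobori difference counts for one codon pair: enumerate
# every ordering of the differing positions, translate with seqinr (an
# independent code-table source), drop through-stop paths
ng_codon_oracle <- function(c1, c2) {
  translate1 <- function(codon)
    seqinr::translate(strsplit(codon, "")[[1]])
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  dpos <- which(x != y)
  if (!length(dpos)) return(c(Sd = 0, Nd = 0))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  res <- list()
  for (path in perms(dpos)) {
    cur <- x; sd <- 0; nd <- 0; bad <- FALSE
    for (p in path) {
      aa0 <- translate1(paste(cur, collapse = ""))
      cur[p] <- y[p]
      aa1 <- translate1(paste(cur, collapse = ""))
      if (aa1 == "*" && !identical(cur, y)) bad <- TRUE
      if (aa0 == aa1) sd <- sd + 1 else nd <- nd + 1
    }
    res[[length(res) + 1]] <- c(sd, nd, bad)
  }
  m <- do.call(rbind, res)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(Sd = mean(m[ok, 1]), Nd = mean(m[ok, 2]))
}

# Wright-Fisher style haplotype panel with a recent introgression pulse:
# standing variation evolves for t_old generations, then a fully coupled
# donor haplotype is injected into `zone` on a fraction of chromosomes and
# the panel evolves t_recent more generations. Marker positions in bp with
# genetic positions in cM supplied by `cm`.
simulate_ld_panel <- function(pos_bp, cm, zone, n_hap = 200, n_founder = 16,
                              t_old = 200, t_recent = 10, donor_freq = 0.3) {
  nm <- length(pos_bp)
  founders <- matrix(rbinom(n_founder * nm, 1, 0.5), n_founder, nm)
  # zone markers are species-diagnostic: the resident background is
  # monomorphic 0 there and allele 1 enters only on the donor haplotype
  founders[, pos_bp >= zone[1] & pos_bp <= zone[2]] <- 0L
  hap <- founders[sample.int(n_founder, n_hap, replace = TRUE), , drop = FALSE]
  r_adj <- pmin(0.5, diff(cm) / 100)  # recombination fraction per interval
  evolve <- function(hap, gens) {
    for (g in seq_len(gens)) {
      p1 <- sample.int(nrow(hap), nrow(hap), replace = TRUE)
      p2 <- sample.int(nrow(hap), nrow(hap), replace = TRUE)
      nxt <- hap[p1, , drop = FALSE]
      for (i in seq_len(nrow(hap))) {
        cross <- runif(nm - 1) < r_adj
        if (any(cross)) {
          state <- cumsum(c(FALSE, cross)) %% 2 == 1
          nxt[i, state] <- hap[p2[i], state]
        }
      }
      hap <- nxt
    }
    hap
  }
  hap <- evolve(hap, t_old)
  inside <- pos_bp >= zone[1] & pos_bp <= zone[2]
  donors <- runif(nrow(hap)) < donor_freq
  hap[donors, inside] <- 1L
  evolve(hap, t_recent)
}
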