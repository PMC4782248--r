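# Interallelic Ka/Ks by the Nei-Gojobori pathway-counting method, between
# the two phased haplotype coding sequences of a heterozygous individual.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.translate_codon <- function(codon, tab) {
  aa <- tab[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

# synonymous site fraction of one codon: per position, the fraction of the
# three alternative nucleotides that preserve the amino acid; mutations to
# stop codons count as nonsynonymous
.codon_sites <- function(codon, tab) {
  bases <- c("A", "C", "G", "T")
  aa <- tab[codon]
  if (is.na(aa) || aa == "*") return(c(S = NA_real_, N = NA_real_))
  s <- 0
  chars <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (b in setdiff(bases, chars[p])) {
    alt <- chars; alt[p] <- b
    if (tab[paste(alt, collapse = "")] == aa) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

# average synonymous/nonsynonymous difference counts between two codons
# over all shortest mutational pathways, excluding paths through stop
# codons (falling back to all paths when every path hits a stop)
.codon_diffs <- function(c1, c2, tab) {
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  dpos <- which(x != y)
  d <- length(dpos)
  if (d == 0) return(c(Sd = 0, Nd = 0))
  paths <- if (d == 1) list(dpos) else
    lapply(seq_len(factorial(d)), function(k) .perm_k(dpos, k))
  score <- function(path) {
    cur <- x; sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in path) {
      aa_from <- unname(tab[paste(cur, collapse = "")])
      cur[p] <- y[p]
      codon_to <- paste(cur, collapse = "")
      aa_to <- unname(tab[codon_to])
      if (aa_to == "*" && codon_to != c2) through_stop <- TRUE
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, through_stop)
  }
  sc <- vapply(paths, score, numeric(3))
  valid <- sc[3, ] == 0
  if (!any(valid)) valid <- rep(TRUE, ncol(sc))
  c(Sd = mean(sc[1, valid]), Nd = mean(sc[2, valid]))
}

# k-th permutation of a vector (lexicographic), k in 1..factorial(n)
.perm_k <- function(v, k) {
  n <- length(v); out <- integer(n); avail <- v; k <- k - 1
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    idx <- k %/% f + 1
    out[i] <- avail[idx]; avail <- avail[-idx]; k <- k %% f
  }
  out
}

#' Haplotype coding-sequence pair
#'
#' @param gene Gene identifier.
#' @param hap1,hap2 Coding sequences (character strings) of equal length
#'   divisible by 3, already oriented 5'->3' in reading frame.
#' @param masked_codons Integer indices of codons excluded from analysis
#'   (e.g. indel-overlapping codons).
#' @return A \code{HaplotypeCDS} object.
#' @export
haplotype_cds <- function(gene, hap1, hap2, masked_codons = integer(0)) {
  if (nchar(hap1) != nchar(hap2)) stop("haplotypes differ in length")
  if (nchar(hap1) %% 3 != 0) stop("CDS length not divisible by 3")
  structure(list(gene = gene, hap1 = toupper(hap1), hap2 = toupper(hap2),
                 masked_codons = as.integer(masked_codons)),
            class = "HaplotypeCDS")
}

#' Reconstruct the two haplotype coding sequences of one individual
#'
#' Applies each phased haplotype's alleles to the reference CDS. Codons
#' overlapping indel or MNP records (multi-nucleotide REF or ALT) are
#' masked. Codons holding two or more heterozygous SNPs require phase: an
#' unphased multi-het codon is an error (no guessing). Minus-strand CDS
#' are reverse-complemented into reading-frame orientation.
#'
#' @param reference \code{DNAStringSet}.
#' @param cds data.frame of exon intervals in genomic order: chrom, start,
#'   end (1-based inclusive), strand ("+"/"-"; one strand per gene).
#' @param panel \code{HaplotypePanel} with phased genotypes.
#' @param individual Individual id.
#' @param gene Gene identifier for the output.
#' @return A \code{HaplotypeCDS}.
#' @export
reconstruct_haplotype_cds <- function(reference, cds, panel, individual,
                                      gene = "gene") {
  j <- match(individual, panel$samples$id)
  if (is.na(j)) stop("unknown individual: ", individual)
  strand <- unique(cds$strand)
  if (length(strand) != 1) stop("mixed strands within one gene")
  chrom <- unique(cds$chrom)
  if (length(chrom) != 1) stop("mixed chromosomes within one gene")
  cds <- cds[order(cds$start), , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(k)
    cds$start[k]:cds$end[k]))
  refseq <- strsplit(as.character(Biostrings::subseq(
    reference[[chrom]], min(gpos), max(gpos))), "")[[1]]
  refcds <- refseq[gpos - min(gpos) + 1L]
  h1 <- refcds; h2 <- refcds
  masked_gpos <- integer(0)
  het_ci <- integer(0); het_phased <- logical(0)
  rows <- which(panel$sites$chrom == chrom & panel$sites$pos %in% gpos)
  al <- site_alleles(subset_panel(panel, site_idx = rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    pos <- panel$sites$pos[i]
    g1 <- panel$geno1[i, j]; g2 <- panel$geno2[i, j]
    if (is.na(g1) || is.na(g2)) next
    a1 <- al[[k]][g1 + 1L]; a2 <- al[[k]][g2 + 1L]
    multi <- nchar(panel$sites$ref[i]) != 1L || nchar(a1) != 1L ||
      nchar(a2) != 1L
    if (multi) {
      span <- max(nchar(panel$sites$ref[i]), nchar(a1), nchar(a2))
      masked_gpos <- c(masked_gpos, pos:(pos + span - 1L))
      next
    }
    ci <- match(pos, gpos)
    if (g1 != g2) {
      het_ci <- c(het_ci, ci)
      het_phased <- c(het_phased, panel$phased[i, j])
    }
    h1[ci] <- a1; h2[ci] <- a2
  }
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    h1 <- rev(unname(comp[h1])); h2 <- rev(unname(comp[h2]))
    gpos_or <- rev(gpos)
  } else gpos_or <- gpos
  n_codon <- length(h1) %/% 3L
  if (length(h1) %% 3L != 0L) stop("CDS length not divisible by 3")
  codon_of <- rep(seq_len(n_codon), each = 3L)
  # multi-het codons need phase: reconstruction must not guess haplotypes
  if (length(het_ci)) {
    ci_or <- if (strand == "-") length(h1) - het_ci + 1L else het_ci
    het_codon <- codon_of[ci_or]
    for (cdn in unique(het_codon)) {
      k <- het_codon == cdn
      if (sum(k) >= 2L && !all(het_phased[k]))
        stop("unphased heterozygous SNPs share codon ", cdn, " in ",
             individual, "; phase required for CDS reconstruction")
    }
  }
  masked <- sort(unique(codon_of[match(intersect(masked_gpos, gpos_or),
                                       gpos_or)]))
  haplotype_cds(gene, paste(h1, collapse = ""), paste(h2, collapse = ""),
                masked)
}

#' Nei-Gojobori Ka/Ks between two haplotype coding sequences
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon of the
#' first haplotype, averages synonymous/nonsynonymous differences over all
#' shortest mutational pathways between differing codons (paths through
#' stop codons excluded), converts the proportions with the Jukes-Cantor
#' correction d = -3/4 ln(1 - 4p/3), and reports Ka, Ks and their ratio
#' (\code{Inf} when Ks = 0 and Ka > 0).
#'
#' @param cds A \code{HaplotypeCDS}.
#' @param site_counting "hap1" (default): site totals from the first
#'   haplotype; "average": mean of both haplotypes' site totals.
#' @return \code{KaKsResult} list: N, S, Nd, Sd, pN, pS, Ka, Ks, ratio.
#'   Proportions >= 3/4 leave the corrected rate \code{NA} (flagged
#'   undefined).
#' @export
nei_gojobori <- function(cds, site_counting = c("hap1", "average")) {
  site_counting <- match.arg(site_counting)
  stopifnot(inherits(cds, "HaplotypeCDS"))
  tab <- .codon_table()
  n_codon <- nchar(cds$hap1) %/% 3L
  use <- setdiff(seq_len(n_codon), cds$masked_codons)
  codons1 <- substring(cds$hap1, (use - 1) * 3 + 1, use * 3)
  codons2 <- substring(cds$hap2, (use - 1) * 3 + 1, use * 3)
  # a terminal stop codon is part of the CDS but not of the analysis
  if (length(use) && use[length(use)] == n_codon) {
    last1 <- codons1[length(codons1)]; last2 <- codons2[length(codons2)]
    if ((!is.na(tab[last1]) && tab[last1] == "*") ||
        (!is.na(tab[last2]) && tab[last2] == "*")) {
      codons1 <- codons1[-length(codons1)]
      codons2 <- codons2[-length(codons2)]
    }
  }
  ok <- grepl("^[ACGT]{3}$", codons1) & grepl("^[ACGT]{3}$", codons2)
  codons1 <- codons1[ok]; codons2 <- codons2[ok]
  if (any(tab[codons1] == "*" | tab[codons2] == "*"))
    stop("internal stop codon in unmasked region")
  st1 <- vapply(codons1, .codon_sites, numeric(2), tab = tab)
  S <- sum(st1["S", ]); N <- sum(st1["N", ])
  if (site_counting == "average") {
    st2 <- vapply(codons2, .codon_sites, numeric(2), tab = tab)
    S <- (S + sum(st2["S", ])) / 2
    N <- (N + sum(st2["N", ])) / 2
  }
  dif <- which(codons1 != codons2)
  Sd <- 0; Nd <- 0
  for (i in dif) {
    d <- .codon_diffs(codons1[i], codons2[i], tab)
    Sd <- Sd + d["Sd"]; Nd <- Nd + d["Nd"]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (is.na(Ka) || is.na(Ks)) NA_real_
    else if (Ks == 0 && Ka > 0) Inf
    else if (Ks == 0) NA_real_
    else Ka / Ks
  structure(list(gene = cds$gene, N = N, S = S,
                 Nd = unname(Nd), Sd = unname(Sd),
                 pN = unname(pN), pS = unname(pS),
                 Ka = unname(Ka), Ks = unname(Ks), ratio = ratio,
                 n_codons = length(codons1)),
            class = "KaKsResult")
}

#' @export
print.KaKsResult <- function(x, ...) {
  cat(sprintf("KaKs [%s]: N=%.2f S=%.2f Nd=%.2f Sd=%.2f Ka=%s Ks=%s ratio=%s\n",
              x$gene, x$N, x$S, x$Nd, x$Sd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              if (is.infinite(x$ratio)) "inf" else format(x$ratio, digits = 4)))
  invisible(x)
}

#' Codon-based one-sided test of Ka/Ks = 1
#'
#' Large-sample Z test on pN - pS with binomial variances
#' p(1-p)/sites, testing positive selection (Ka/Ks > 1). An approximation
#' of the codon-based Z test implemented in standard phylogenetics
#' software.
#'
#' @param result A \code{KaKsResult}.
#' @return One-sided p-value; 1 when there are no differences.
#' @export
kaks_ratio_test <- function(result) {
  stopifnot(inherits(result, "KaKsResult"))
  if (result$Nd + result$Sd == 0) return(1)
  vN <- result$pN * (1 - result$pN) / result$N
  vS <- result$pS * (1 - result$pS) / result$S
  if (vN + vS == 0) return(if (result$pN > result$pS) 0 else 1)
  z <- (result$pN - result$pS) / sqrt(vN + vS)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Tabulate Ka/Ks results for several genes
#'
#' @param results List of \code{KaKsResult}s.
#' @return data.frame with the ratio rendered as the literal "inf" when
#'   Ks = 0 and Ka > 0.
#' @export
kaks_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(gene = r$gene, N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
               Ka = r$Ka, Ks = r$Ks,
               ratio = if (is.infinite(r$ratio)) "inf" else
                 format(r$ratio, digits = 6),
               p = kaks_ratio_test(r), stringsAsFactors = FALSE)))
}
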