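# Amplicon-style SNP filtering, Hardy-Weinberg exact test, D', genetic
# distances from a Loess-smoothed recombination map, and LD-decay fitting.

#' Amplicon SNP filter
#'
#' Retains markers that satisfy: read depth strictly above
#' \code{min_depth} in every individual; single-nucleotide alleles (no
#' indel / MNP records); exactly two alleles observed across all
#' individuals; minor allele carried by at least two individuals (no
#' singletons); Hardy-Weinberg exact p >= \code{hwe_alpha}.
#'
#' @param panel A \code{HaplotypePanel} with depth.
#' @param min_depth Strict lower depth bound (default 20: depth must be
#'   > 20, the amplicon convention, unlike the inclusive 20--200 WGS band).
#' @param hwe_alpha Exclusion level for the Hardy-Weinberg exact test.
#' @return List: \code{keep} (logical per site), \code{panel} (filtered
#'   \code{HaplotypePanel}), \code{n_singleton}, \code{n_hwe} (counts
#'   removed by the singleton and HWE rules among otherwise valid SNPs).
#' @export
filter_snps <- function(panel, min_depth = 20, hwe_alpha = 0.05) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  if (is.null(panel$depth)) stop("panel has no depth information")
  ns <- nrow(panel$sites)
  deep <- rowSums(panel$depth > min_depth) == ncol(panel$depth)
  alt_list <- strsplit(panel$sites$alt, ",", fixed = TRUE)
  is_snp <- nchar(panel$sites$ref) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L) || length(a) == 0L,
           logical(1))
  g1 <- panel$geno1; g2 <- panel$geno2
  biallelic <- logical(ns); singleton <- logical(ns); hwe_fail <- logical(ns)
  for (i in seq_len(ns)) {
    g <- c(g1[i, ], g2[i, ])
    obs <- sort(unique(g[!is.na(g)]))
    if (length(obs) != 2L) { biallelic[i] <- FALSE; next }
    biallelic[i] <- TRUE
    minor <- obs[which.min(c(sum(g == obs[1], na.rm = TRUE),
                             sum(g == obs[2], na.rm = TRUE)))]
    carriers <- sum(g1[i, ] == minor | g2[i, ] == minor, na.rm = TRUE)
    singleton[i] <- carriers < 2L
    nAA <- sum(g1[i, ] == obs[1] & g2[i, ] == obs[1], na.rm = TRUE)
    naa <- sum(g1[i, ] == obs[2] & g2[i, ] == obs[2], na.rm = TRUE)
    nAa <- sum(!is.na(g1[i, ]) & !is.na(g2[i, ])) - nAA - naa
    hwe_fail[i] <- hwe_exact(nAA, nAa, naa) < hwe_alpha
  }
  base_ok <- deep & is_snp & biallelic
  keep <- base_ok & !singleton & !hwe_fail
  list(keep = keep,
       panel = subset_panel(panel, site_idx = which(keep)),
       n_singleton = sum(base_ok & singleton),
       n_hwe = sum(base_ok & !singleton & hwe_fail))
}

#' Hardy-Weinberg exact test
#'
#' Conditional-on-allele-counts exact test: given the minor-allele count,
#' the p-value is the total probability of heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#'
#' @param nAA,nAa,naa Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype required")
  na <- min(2 * nAA + nAa, 2 * naa + nAa)      # rare allele count
  # possible heterozygote counts share the parity of na
  hets <- seq(na %% 2, na, by = 2)
  # log P(nAa = h | n, na) = log [ C(n; h, (na-h)/2, n-(na+h)/2) 2^h / C(2n, na) ]
  logp <- vapply(hets, function(h) {
    hom_rare <- (na - h) / 2
    hom_com <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) -
      lgamma(hom_com + 1) + h * log(2) -
      (lgamma(2 * n + 1) - lgamma(na + 1) - lgamma(2 * n - na + 1))
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(nAa, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}

#' Frequency of species-B diagnostic alleles per amplicon
#'
#' At each B-specific diagnostic site inside an amplicon the B-allele
#' frequency is the B-allele count over 2 x individuals; the amplicon
#' value is the mean over its diagnostic sites.
#'
#' @param panel A \code{HaplotypePanel} of the population.
#' @param diag_sites Polarized \code{DiagnosticSiteTable}.
#' @param amplicons data.frame: chrom, start, end (1-based inclusive),
#'   optionally \code{name}.
#' @return data.frame: amplicon coordinates, n_diag_sites, freq_B
#'   (\code{NA}, flagged undefined, for amplicons without diagnostic
#'   sites).
#' @export
diag_allele_freq <- function(panel, diag_sites, amplicons) {
  bs <- diag_sites[which(diag_sites$B_specific), , drop = FALSE]
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  out <- amplicons
  out$n_diag_sites <- 0L; out$freq_B <- NA_real_
  for (i in seq_len(nrow(amplicons))) {
    sel <- bs$chrom == amplicons$chrom[i] & bs$pos >= amplicons$start[i] &
      bs$pos <= amplicons$end[i]
    if (!any(sel)) next
    m <- match(paste(bs$chrom[sel], bs$pos[sel]), key_p)
    ok <- !is.na(m)
    if (!any(ok)) next
    rows <- m[ok]
    sub_sites <- panel$sites[rows, , drop = FALSE]
    a1 <- .allele_char(panel, panel$geno1[rows, , drop = FALSE], sub_sites)
    a2 <- .allele_char(panel, panel$geno2[rows, , drop = FALSE], sub_sites)
    target <- bs$allele_B[sel][ok]
    fb <- (rowSums(a1 == target, na.rm = TRUE) +
             rowSums(a2 == target, na.rm = TRUE)) /
      (rowSums(!is.na(a1)) + rowSums(!is.na(a2)))
    out$n_diag_sites[i] <- sum(ok)
    out$freq_B[i] <- mean(fb)
  }
  out
}

#' Normalized linkage-disequilibrium coefficient D'
#'
#' For two biallelic markers with phased haplotypes: D = p_AB - p_A p_B,
#' normalized by its maximum attainable magnitude given the allele
#' frequencies, reported as |D'|. D = 0 gives D' = 0.
#'
#' @param hapA,hapB Vectors of 0/1 alleles, one element per chromosome, in
#'   the same chromosome order.
#' @return List: \code{D}, \code{Dprime}; both \code{NA} (flagged) when a
#'   marker is monomorphic.
#' @export
dprime <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  ok <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[ok]; b <- hapB[ok]
  pA <- mean(a == 1); pB <- mean(b == 1)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, Dprime = NA_real_))
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  if (D == 0) return(list(D = 0, Dprime = 0))
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = abs(D / Dmax))
}

#' Smoothed recombination map
#'
#' Fits a Loess curve to (position, cM/Mb) observations, floors the
#' smoothed rate at 0, and integrates it on a 1-kb grid (trapezoid rule)
#' into a non-decreasing cumulative genetic map.
#'
#' @param observations data.frame with \code{pos} (bp) and \code{rate}
#'   (cM/Mb).
#' @param span Loess span (default 0.3).
#' @param grid_bp Integration grid spacing in bp.
#' @return Object of class \code{RecombinationMap} with \code{rate_fun}
#'   and cumulative \code{map_fun} (bp -> cM), plus the grid.
#' @export
recombination_map <- function(observations, span = 0.3, grid_bp = 1000) {
  stopifnot(all(c("pos", "rate") %in% names(observations)))
  obs <- observations[order(observations$pos), , drop = FALSE]
  fit <- stats::loess(rate ~ pos, data = obs, span = span,
                      degree = 2, surface = "direct")
  grid <- seq(min(obs$pos), max(obs$pos), by = grid_bp)
  if (grid[length(grid)] < max(obs$pos)) grid <- c(grid, max(obs$pos))
  r <- pmax(0, stats::predict(fit, newdata = data.frame(pos = grid)))
  # trapezoid integral of cM/Mb over Mb
  dx <- diff(grid) / 1e6
  cum <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dx))
  structure(list(grid = grid, rate = r, cum = cum,
                 rate_fun = stats::approxfun(grid, r, rule = 2),
                 map_fun = stats::approxfun(grid, cum, rule = 2),
                 range = range(obs$pos)),
            class = "RecombinationMap")
}

#' Genetic distance between two physical positions
#'
#' Definite integral of the smoothed recombination rate between the two
#' positions; symmetric and additive over adjacent intervals.
#'
#' @param map A \code{RecombinationMap}.
#' @param pos1,pos2 Positions in bp; must lie within the map range.
#' @return Distance in cM.
#' @export
genetic_distance <- function(map, pos1, pos2) {
  stopifnot(inherits(map, "RecombinationMap"))
  if (any(c(pos1, pos2) < map$range[1] - 1e-9) ||
      any(c(pos1, pos2) > map$range[2] + 1e-9))
    stop("position outside recombination-map range")
  abs(map$map_fun(pos2) - map$map_fun(pos1))
}

#' Pairwise D' with genetic distances and zone categories
#'
#' @param markers data.frame: chrom, pos for each marker, rows aligned to
#'   the haplotype matrix columns.
#' @param haplotypes 0/1 matrix (chromosomes x markers), two rows per
#'   individual.
#' @param map A \code{RecombinationMap} for the markers' chromosome.
#' @param zone \code{c(start, end)} of the focal tract (1-based
#'   inclusive); pairs are categorized as \code{within} (both markers
#'   inside), \code{outside} (both outside) or \code{across}.
#' @return \code{PairLD} data.frame: i, j, pos_i, pos_j, D, Dprime, d_cM,
#'   category.
#' @export
pair_ld <- function(markers, haplotypes, map, zone) {
  nm <- nrow(markers)
  stopifnot(ncol(haplotypes) == nm)
  inside <- markers$pos >= zone[1] & markers$pos <= zone[2]
  res <- list()
  for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    ld <- dprime(haplotypes[, i], haplotypes[, j])
    cat_ij <- if (inside[i] && inside[j]) "within"
      else if (!inside[i] && !inside[j]) "outside" else "across"
    res[[length(res) + 1L]] <-
      data.frame(i = i, j = j, pos_i = markers$pos[i], pos_j = markers$pos[j],
                 D = ld$D, Dprime = ld$Dprime,
                 d_cM = genetic_distance(map, markers$pos[i], markers$pos[j]),
                 category = cat_ij, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res); rownames(out) <- NULL
  out
}

#' Fit the LD-decay model D' = (1 - theta)^t
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the one-parameter
#' decay model per marker-pair category, with the recombination fraction
#' theta approximated from map distance as d_cM / 100, capped at 0.5
#' (optionally Haldane-corrected). Only pairs within \code{max_cM} are
#' used. The 95% confidence interval comes from the asymptotic parameter
#' covariance of the fit.
#'
#' @param pairs \code{PairLD} data.frame (needs \code{Dprime},
#'   \code{d_cM}, \code{category}).
#' @param max_cM Maximum pair distance used (default 5 cM).
#' @param haldane Use the Haldane map function to convert cM to
#'   recombination fraction instead of the linear approximation.
#' @param min_pairs Minimum pairs per category.
#' @return \code{DecayFit} data.frame: category, n_pairs, t_hat, se,
#'   ci_lo, ci_hi, degenerate (TRUE when all D' = 1 so t is pinned at 0).
#' @export
fit_decay <- function(pairs, max_cM = 5, haldane = FALSE, min_pairs = 3) {
  use <- pairs[!is.na(pairs$Dprime) & !is.na(pairs$d_cM) &
                 pairs$d_cM <= max_cM, , drop = FALSE]
  out <- list()
  for (cat_k in unique(use$category)) {
    u <- use[use$category == cat_k, , drop = FALSE]
    if (nrow(u) < min_pairs) next
    theta <- if (haldane) (1 - exp(-2 * u$d_cM / 100)) / 2
             else pmin(u$d_cM / 100, 0.5)
    if (all(u$Dprime >= 1 - 1e-12)) {
      out[[cat_k]] <- data.frame(category = cat_k, n_pairs = nrow(u),
                                 t_hat = 0, se = NA_real_, ci_lo = 0,
                                 ci_hi = 0, degenerate = TRUE)
      next
    }
    df_fit <- data.frame(Dp = u$Dprime, theta = theta)
    fit <- minpack.lm::nlsLM(Dp ~ (1 - theta)^t, data = df_fit,
                             start = list(t = 10), lower = 0,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    t_hat <- unname(stats::coef(fit)["t"])
    se <- sqrt(stats::vcov(fit)[1, 1])
    out[[cat_k]] <- data.frame(category = cat_k, n_pairs = nrow(u),
                               t_hat = t_hat, se = se,
                               ci_lo = max(0, t_hat - 1.96 * se),
                               ci_hi = t_hat + 1.96 * se,
                               degenerate = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}
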