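# Sliding-window statistics and the exact rank test.
#
# Windows are anchored at position 0 of each chromosome: window k covers
# the 1-based interval [k*step + 1, k*step + size], truncated at the
# chromosome end. Interior sites therefore fall in exactly size/step
# windows when step divides size.

#' Sliding-window grid for one chromosome
#'
#' @param chrom_len Chromosome length in bp.
#' @param size,step Window size and step in bp (\code{size >= step >= 1}).
#' @return data.frame with 1-based inclusive \code{start}, \code{end}.
#' @export
make_windows <- function(chrom_len, size, step) {
  stopifnot(size >= step, step >= 1)
  starts0 <- seq(0L, max(0L, as.integer(chrom_len) - 1L), by = as.integer(step))
  data.frame(start = starts0 + 1L,
             end = pmin(starts0 + as.integer(size), as.integer(chrom_len)))
}

# windowed sums of x over sorted 1-based positions pos
.win_sum <- function(pos, x, starts, ends) {
  cs <- c(0, cumsum(x))
  cs[findInterval(ends, pos) + 1L] - cs[findInterval(starts - 1L, pos) + 1L]
}

# per-site unbiased expected-heterozygosity terms n(1 - sum x^2)/(n - 1)
# over the 2N sampled chromosomes; 0 at monomorphic sites, NA where n < 2
.het_site_terms <- function(panel, rows) {
  g1 <- panel$geno1[rows, , drop = FALSE]
  g2 <- panel$geno2[rows, , drop = FALSE]
  n <- rowSums(!is.na(g1)) + rowSums(!is.na(g2))
  max_idx <- max(0L, suppressWarnings(max(c(g1, g2), na.rm = TRUE)))
  sum_sq <- rep(0, length(rows)); n_alleles <- rep(0L, length(rows))
  for (a in 0:max_idx) {
    cnt <- rowSums(g1 == a, na.rm = TRUE) + rowSums(g2 == a, na.rm = TRUE)
    sum_sq <- sum_sq + ifelse(n > 0, (cnt / pmax(n, 1))^2, 0)
    n_alleles <- n_alleles + (cnt > 0L)
  }
  term <- ifelse(n >= 2, n * (1 - sum_sq) / (n - 1), NA_real_)
  list(term = term, segregating = n_alleles >= 2L, n = n)
}

#' Average heterozygosity of a region
#'
#' The unbiased expected heterozygosity summed over segregating validated
#' sites and normalized per validated nucleotide:
#' \deqn{\hat h = \sum_{i=1}^{S} \frac{n (1 - \sum_j x_{ji}^2)}{n - 1} / V}
#' where S is the segregating-site count, n the number of sampled
#' chromosomes, x_ji the sample frequency of the j-th allele at site i and
#' V the count of validated sites. With \code{denominator = "callable"} the
#' count of validated sites is the region length times
#' \code{callable_fraction} (invariant positions included, the genome-scale
#' convention); with \code{"masked_sites"} it is the number of masked
#' variant records (SNP-level convention).
#'
#' @param panel A \code{HaplotypePanel}.
#' @param mask Logical site mask (default all valid).
#' @param chrom,start,end Region (1-based inclusive); defaults to the whole
#'   panel.
#' @param denominator "callable" or "masked_sites".
#' @param callable_fraction Fraction of region positions passing the
#'   coverage filter (see \code{\link{simulate_bundle}}).
#' @return List of class \code{HetWindow}: \code{chrom}, \code{start},
#'   \code{end}, \code{S}, \code{n} (median chromosomes sampled),
#'   \code{h_sum}, \code{valid_sites}, \code{h} (\code{NA}, flagged
#'   undefined, when \code{valid_sites} is 0).
#' @export
average_heterozygosity <- function(panel, mask = NULL, chrom = NULL,
                                   start = NULL, end = NULL,
                                   denominator = c("callable", "masked_sites"),
                                   callable_fraction = 1) {
  denominator <- match.arg(denominator)
  if (is.null(mask)) mask <- rep(TRUE, nrow(panel$sites))
  rows <- which(mask)
  if (!is.null(chrom)) {
    rows <- rows[panel$sites$chrom[rows] == chrom]
    if (!is.null(start)) rows <- rows[panel$sites$pos[rows] >= start]
    if (!is.null(end)) rows <- rows[panel$sites$pos[rows] <= end]
  }
  ht <- .het_site_terms(panel, rows)
  region_len <- if (!is.null(start) && !is.null(end)) end - start + 1L else
    sum(panel$sites$pos[rows] >= 0)  # no region given: only SNP-level denom
  valid <- switch(denominator,
                  callable = if (!is.null(start) && !is.null(end))
                    round(region_len * callable_fraction)
                  else stop("denominator 'callable' needs an explicit region"),
                  masked_sites = length(rows))
  h_sum <- sum(ht$term[ht$segregating], na.rm = TRUE)
  structure(list(chrom = chrom, start = start, end = end,
                 S = sum(ht$segregating, na.rm = TRUE),
                 n = if (length(ht$n)) stats::median(ht$n) else NA_real_,
                 h_sum = h_sum, valid_sites = valid,
                 h = if (valid > 0) h_sum / valid else NA_real_),
            class = "HetWindow")
}

#' Sliding-window average-heterozygosity track
#'
#' @inheritParams average_heterozygosity
#' @param size,step Window geometry in bp.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return data.frame: chrom, start, end, S, h_sum, valid_sites, h.
#' @export
het_window_track <- function(panel, mask = NULL, size = 500000, step = 100000,
                             chrom_lengths,
                             denominator = c("callable", "masked_sites"),
                             callable_fraction = 1) {
  denominator <- match.arg(denominator)
  if (is.null(mask)) mask <- rep(TRUE, nrow(panel$sites))
  out <- list()
  for (chrom in names(chrom_lengths)) {
    w <- make_windows(chrom_lengths[chrom], size, step)
    rows <- which(mask & panel$sites$chrom == chrom)
    ord <- rows[order(panel$sites$pos[rows])]
    pos <- panel$sites$pos[ord]
    ht <- .het_site_terms(panel, ord)
    term <- ifelse(ht$segregating, ht$term, 0)
    term[is.na(term)] <- 0
    h_sum <- .win_sum(pos, term, w$start, w$end)
    S <- .win_sum(pos, as.numeric(ht$segregating), w$start, w$end)
    valid <- switch(denominator,
                    callable = round((w$end - w$start + 1) * callable_fraction),
                    masked_sites = .win_sum(pos, rep(1, length(pos)),
                                            w$start, w$end))
    out[[chrom]] <- data.frame(chrom = chrom, start = w$start, end = w$end,
                               S = S, h_sum = h_sum, valid_sites = valid,
                               h = ifelse(valid > 0, h_sum / valid, NA_real_),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Per-individual heterozygous-site proportion in sliding windows
#'
#' Numerator: heterozygous genotypes of the individual among masked sites
#' in the window. Denominator: validated sites in the window (region length
#' times \code{callable_fraction}, or the masked variant-site count).
#'
#' @inheritParams het_window_track
#' @param individual Individual id.
#' @return data.frame: chrom, start, end, het, valid_sites, proportion
#'   (\code{NA} for windows with zero validated sites).
#' @export
het_site_proportion_windows <- function(panel, mask = NULL, size = 500000,
                                        step = 100000, individual,
                                        chrom_lengths,
                                        denominator = c("callable",
                                                        "masked_sites"),
                                        callable_fraction = 1) {
  denominator <- match.arg(denominator)
  j <- match(individual, panel$samples$id)
  if (is.na(j)) stop("unknown individual: ", individual)
  if (is.null(mask)) mask <- rep(TRUE, nrow(panel$sites))
  out <- list()
  for (chrom in names(chrom_lengths)) {
    w <- make_windows(chrom_lengths[chrom], size, step)
    rows <- which(mask & panel$sites$chrom == chrom)
    ord <- rows[order(panel$sites$pos[rows])]
    pos <- panel$sites$pos[ord]
    g1 <- panel$geno1[ord, j]; g2 <- panel$geno2[ord, j]
    het <- as.numeric(!is.na(g1) & !is.na(g2) & g1 != g2)
    n_het <- .win_sum(pos, het, w$start, w$end)
    valid <- switch(denominator,
                    callable = round((w$end - w$start + 1) * callable_fraction),
                    masked_sites = .win_sum(pos, rep(1, length(pos)),
                                            w$start, w$end))
    out[[chrom]] <- data.frame(chrom = chrom, start = w$start, end = w$end,
                               het = n_het, valid_sites = valid,
                               proportion = ifelse(valid > 0, n_het / valid,
                                                   NA_real_),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Genotype-class proportions in sliding windows
#'
#' Fractions of homA / het / homB / missing calls over B-specific
#' diagnostic sites per window, per individual. The four fractions sum to 1
#' in every window holding at least one B-specific site; windows without
#' B-specific sites are flagged undefined (\code{NA}).
#'
#' @param track A \code{GenotypeClassTrack} from \code{\link{classify}}.
#' @param size,step Window geometry in bp (defaults: the 500-kb screen with
#'   100-kb step).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return data.frame: individual, chrom, start, end, n_sites, frac_homA,
#'   frac_het, frac_homB, frac_missing.
#' @export
genotype_class_proportion_windows <- function(track, size = 500000,
                                              step = 100000, chrom_lengths) {
  stopifnot(inherits(track, "GenotypeClassTrack"))
  if (nrow(track$sites) == 0) stop("empty genotype-class track")
  out <- list()
  for (chrom in names(chrom_lengths)) {
    w <- make_windows(chrom_lengths[chrom], size, step)
    rows <- which(track$sites$chrom == chrom)
    ord <- rows[order(track$sites$pos[rows])]
    pos <- track$sites$pos[ord]
    for (j in seq_len(nrow(track$samples))) {
      cls <- track$class[ord, j]
      cnt <- lapply(0:3, function(k)
        .win_sum(pos, as.numeric(cls == k), w$start, w$end))
      tot <- cnt[[1]] + cnt[[2]] + cnt[[3]] + cnt[[4]]
      out[[paste(chrom, j)]] <-
        data.frame(individual = track$samples$id[j], chrom = chrom,
                   start = w$start, end = w$end, n_sites = tot,
                   frac_homA = ifelse(tot > 0, cnt[[1]] / tot, NA_real_),
                   frac_het = ifelse(tot > 0, cnt[[2]] / tot, NA_real_),
                   frac_homB = ifelse(tot > 0, cnt[[3]] / tot, NA_real_),
                   frac_missing = ifelse(tot > 0, cnt[[4]] / tot, NA_real_),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Exact two-sided Mann-Whitney U test
#'
#' Enumerates all \code{choose(n1 + n2, n1)} label assignments of the
#' pooled observations (mid-ranks for ties) and reports the two-sided
#' p-value \eqn{P(|U - n_1 n_2 / 2| \ge |U_{obs} - n_1 n_2 / 2|)}. Intended
#' for the small-sample regime (\code{n1 + n2 <= 20}) where the exact test
#' is feasible and the normal approximation is not trusted.
#'
#' @param x,y Numeric samples.
#' @return List: \code{U} (statistic for \code{x}), \code{p} (two-sided
#'   exact p-value).
#' @export
mwu_exact <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n > 20) stop("exact enumeration limited to n1 + n2 <= 20")
  rk <- rank(c(x, y))  # mid-ranks
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  cmb <- utils::combn(n, n1)
  Us <- colSums(matrix(rk[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  list(U = U_obs, p = p)
}
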