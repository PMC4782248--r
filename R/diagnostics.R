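# Species-diagnostic site discovery and genotype classification.
#
# Steps 1-3 of the introgression scan: (1) sites fixed-different between the
# two species panels, (2) polarization against the outgroup so that only
# mutations on the species-B lineage are kept as B-specific, (3) per-focal-
# individual classification into homA / het / homB at B-specific sites.

# fixed allele per site within a panel: the single observed allele character,
# NA when polymorphic or entirely missing
.fixed_allele <- function(panel) {
  g <- cbind(panel$geno1, panel$geno2)
  ns <- nrow(g)
  cols <- lapply(seq_len(ncol(g)), function(j) g[, j])
  mn <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), cols)
  mx <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), cols)
  fixed_idx <- ifelse(!is.na(mn) & mn == mx, mn, NA_integer_)
  out <- rep(NA_character_, ns)
  out[which(fixed_idx == 0L)] <- panel$sites$ref[which(fixed_idx == 0L)]
  i1 <- which(fixed_idx == 1L)
  out[i1] <- sub(",.*", "", panel$sites$alt[i1])
  hi <- which(fixed_idx >= 2L)
  if (length(hi)) {
    al <- strsplit(panel$sites$alt[hi], ",", fixed = TRUE)
    out[hi] <- mapply(function(a, i) a[i], al, fixed_idx[hi])
  }
  out
}

#' Find sites fixed-different between two species panels
#'
#' A site is diagnostic when every sampled chromosome in panel A carries one
#' allele, every chromosome in panel B carries another, and the two alleles
#' differ ("fixed within each species"). Missing genotypes are ignored, but
#' at least one observed chromosome per panel is required. Sites on excluded
#' chromosomes (typically sex chromosomes) are dropped.
#'
#' @param panel_A,panel_B \code{HaplotypePanel}s sharing a site coordinate
#'   space (same chrom/pos order).
#' @param mask Optional logical validity mask (e.g. \code{\link{coverage_mask}}
#'   over all individuals of both panels).
#' @param exclude_chroms Chromosomes to drop from the scan.
#' @return \code{DiagnosticSiteTable}: data.frame with \code{chrom},
#'   \code{pos}, \code{allele_A}, \code{allele_B}, \code{allele_out}
#'   (\code{NA} until \code{\link{polarize}}), \code{B_specific}.
#' @export
find_fixed_differences <- function(panel_A, panel_B, mask = NULL,
                                   exclude_chroms = character()) {
  stopifnot(inherits(panel_A, "HaplotypePanel"),
            inherits(panel_B, "HaplotypePanel"))
  if (nrow(panel_A$samples) == 0 || nrow(panel_B$samples) == 0)
    stop("empty panel")
  if (nrow(panel_A$sites) != nrow(panel_B$sites) ||
      !all(panel_A$sites$chrom == panel_B$sites$chrom) ||
      !all(panel_A$sites$pos == panel_B$sites$pos))
    stop("panels do not share a site coordinate space")
  if (is.null(mask)) mask <- rep(TRUE, nrow(panel_A$sites))
  fa <- .fixed_allele(panel_A)
  fb <- .fixed_allele(panel_B)
  keep <- mask & !is.na(fa) & !is.na(fb) & fa != fb &
    !(panel_A$sites$chrom %in% exclude_chroms)
  out <- data.frame(chrom = panel_A$sites$chrom[keep],
                    pos = panel_A$sites$pos[keep],
                    allele_A = fa[keep], allele_B = fb[keep],
                    allele_out = rep(NA_character_, sum(keep)),
                    B_specific = rep(NA, sum(keep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DiagnosticSiteTable", "data.frame")
  out
}

#' Polarize diagnostic sites against an outgroup
#'
#' A fixed difference is attributed to the species-B lineage (B-specific)
#' when the outgroup carries the species-A allele. Sites where the outgroup
#' is missing, polymorphic, or carries a third allele are uninformative for
#' polarity and get \code{B_specific = FALSE}; sites where the outgroup
#' matches the species-B allele are mutations on the A lineage.
#'
#' @param sites A \code{DiagnosticSiteTable}.
#' @param outgroup \code{HaplotypePanel} of outgroup individuals; outgroup
#'   monomorphism across all provided chromosomes is required for a call.
#' @return The table with \code{allele_out} and \code{B_specific} filled in.
#' @export
polarize <- function(sites, outgroup) {
  stopifnot(inherits(outgroup, "HaplotypePanel"))
  key_s <- paste(sites$chrom, sites$pos)
  key_o <- paste(outgroup$sites$chrom, outgroup$sites$pos)
  fo <- .fixed_allele(outgroup)
  m <- match(key_s, key_o)
  # sites absent from the outgroup's variant records carry the reference
  # (ancestral) state there, which is known from the site's own alleles only
  # when the outgroup panel shares the record; absent -> allele unknown
  allele_out <- ifelse(is.na(m), NA_character_, fo[m])
  sites$allele_out <- allele_out
  sites$B_specific <- !is.na(allele_out) & allele_out == sites$allele_A
  sites
}

#' Classify focal genotypes at B-specific diagnostic sites
#'
#' @param panel \code{HaplotypePanel} of the individuals to classify.
#' @param sites Polarized \code{DiagnosticSiteTable}; only rows with
#'   \code{B_specific == TRUE} are used.
#' @return \code{GenotypeClassTrack}: list with \code{samples}, \code{sites}
#'   (the B-specific subset) and \code{class}, an integer matrix
#'   (sites x individuals) coded 0 = homA, 1 = het, 2 = homB, 3 = missing
#'   (any missing or non-diagnostic allele).
#' @export
classify <- function(panel, sites) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  bs <- sites[which(sites$B_specific), , drop = FALSE]
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  m <- match(paste(bs$chrom, bs$pos), key_p)
  if (anyNA(m)) stop("diagnostic site(s) absent from the panel")
  sub_sites <- panel$sites[m, , drop = FALSE]
  a1 <- .allele_char(panel, panel$geno1[m, , drop = FALSE], sub_sites)
  a2 <- .allele_char(panel, panel$geno2[m, , drop = FALSE], sub_sites)
  # note: rows of a1/a2 are already the diagnostic subset
  isA1 <- a1 == bs$allele_A; isB1 <- a1 == bs$allele_B
  isA2 <- a2 == bs$allele_A; isB2 <- a2 == bs$allele_B
  cls <- matrix(3L, nrow(bs), ncol(a1))
  cls[isA1 & isA2] <- 0L
  cls[isB1 & isB2] <- 2L
  cls[(isA1 & isB2) | (isB1 & isA2)] <- 1L
  cls[is.na(a1) | is.na(a2)] <- 3L
  rownames(bs) <- NULL
  structure(list(samples = panel$samples, sites = bs, class = cls),
            class = "GenotypeClassTrack")
}

#' @export
print.GenotypeClassTrack <- function(x, ...) {
  cat(sprintf("GenotypeClassTrack: %d B-specific sites x %d individuals\n",
              nrow(x$sites), nrow(x$samples)))
  invisible(x)
}

#' Serialize a diagnostic-site table
#'
#' Tab-separated with header; positions stay 1-based.
#' @param sites A \code{DiagnosticSiteTable}.
#' @param path Output path.
#' @export
write_diagnostic_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
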