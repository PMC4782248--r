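#' Phased diploid genotype panel
#'
#' The central container of the pipeline: an ordered set of individuals with
#' population labels, a site table, two allele-index matrices (one per
#' haplotype), a phase-flag matrix and a per-site per-individual read-depth
#' matrix. Allele indices are 0-based into \code{c(ref, alt alleles)} as in
#' VCF; \code{NA} marks a missing allele call. Positions are stored 1-based
#' (the VCF convention); conversion to 0-based half-open coordinates happens
#' only at BED-style I/O boundaries.
#'
#' @param samples data.frame with columns \code{id} and \code{population}.
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref} and \code{alt} (comma-separated alternative alleles, ""
#'   if none).
#' @param geno1,geno2 integer matrices (sites x individuals) of allele
#'   indices for the first and second haplotype.
#' @param phased logical matrix (sites x individuals) or a single logical
#'   recycled to all genotypes.
#' @param depth integer matrix (sites x individuals) of read depths, or
#'   \code{NULL} when depth is unavailable.
#' @return An object of class \code{HaplotypePanel}.
#' @export
haplotype_panel <- function(samples, sites, geno1, geno2, phased = TRUE,
                            depth = NULL) {
  stopifnot(is.data.frame(samples), all(c("id", "population") %in% names(samples)))
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  ns <- nrow(sites); ni <- nrow(samples)
  geno1 <- as.matrix(geno1); geno2 <- as.matrix(geno2)
  stopifnot(nrow(geno1) == ns, ncol(geno1) == ni,
            nrow(geno2) == ns, ncol(geno2) == ni)
  if (is.logical(phased) && length(phased) == 1L)
    phased <- matrix(phased, ns, ni)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(nrow(depth) == ns, ncol(depth) == ni, all(depth >= 0, na.rm = TRUE))
  }
  if (anyDuplicated(samples$id)) stop("duplicate individual ids")
  rownames(samples) <- NULL; rownames(sites) <- NULL
  structure(list(samples = samples, sites = sites,
                 geno1 = geno1, geno2 = geno2,
                 phased = phased, depth = depth),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d individuals x %d sites (%d chromosome%s)\n",
              nrow(x$samples), nrow(x$sites),
              length(unique(x$sites$chrom)),
              if (length(unique(x$sites$chrom)) == 1L) "" else "s"))
  pops <- table(x$samples$population)
  cat("  populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat("  depth:", if (is.null(x$depth)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.HaplotypePanel <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a panel by individuals and/or sites
#'
#' @param panel A \code{HaplotypePanel}.
#' @param individuals Character vector of individual ids, or \code{NULL}.
#' @param population Population label(s); used when \code{individuals} is
#'   \code{NULL}.
#' @param site_idx Integer or logical index into the site table, or
#'   \code{NULL} to keep all sites.
#' @return A \code{HaplotypePanel}.
#' @export
subset_panel <- function(panel, individuals = NULL, population = NULL,
                         site_idx = NULL) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  cols <- seq_len(nrow(panel$samples))
  if (!is.null(individuals)) {
    cols <- match(individuals, panel$samples$id)
    if (anyNA(cols)) stop("unknown individual id(s): ",
                          paste(individuals[is.na(cols)], collapse = ", "))
  } else if (!is.null(population)) {
    cols <- which(panel$samples$population %in% population)
    if (!length(cols)) stop("no individuals in population ", population)
  }
  rows <- if (is.null(site_idx)) seq_len(nrow(panel$sites)) else site_idx
  haplotype_panel(panel$samples[cols, , drop = FALSE],
                  panel$sites[rows, , drop = FALSE],
                  panel$geno1[rows, cols, drop = FALSE],
                  panel$geno2[rows, cols, drop = FALSE],
                  panel$phased[rows, cols, drop = FALSE],
                  if (is.null(panel$depth)) NULL else
                    panel$depth[rows, cols, drop = FALSE])
}

#' Allele characters for each site of a panel
#'
#' @param panel A \code{HaplotypePanel}.
#' @return List (one element per site) of character vectors
#'   \code{c(ref, alts...)}; index \code{i} holds the allele with VCF index
#'   \code{i - 1}.
#' @export
site_alleles <- function(panel) {
  alt <- strsplit(panel$sites$alt, ",", fixed = TRUE)
  alt[panel$sites$alt == ""] <- list(character(0))
  mapply(function(r, a) c(r, a), panel$sites$ref, alt,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# allele character of haplotype matrix entries; m is an index matrix whose
# rows correspond to rows of `sites` (a subset of panel$sites)
.allele_char <- function(panel, m, sites = NULL) {
  if (is.null(sites)) sites <- panel$sites
  stopifnot(nrow(sites) == nrow(m))
  ref <- sites$ref
  alt1 <- sub(",.*", "", sites$alt)
  out <- matrix(NA_character_, nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) {
    idx <- m[, j]
    out[idx == 0L & !is.na(idx), j] <- ref[idx == 0L & !is.na(idx)]
    out[idx == 1L & !is.na(idx), j] <- alt1[idx == 1L & !is.na(idx)]
    hi <- which(idx >= 2L)
    if (length(hi)) {
      al <- strsplit(sites$alt[hi], ",", fixed = TRUE)
      out[hi, j] <- mapply(function(a, i) a[i], al, idx[hi])
    }
  }
  out
}
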