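#' Read a VCF into a HaplotypePanel
#'
#' Parses a VCF 4.2 file (plain text or bgzip) via \pkg{vcfR} and converts
#' the GT (and, when present, DP) fields into the package's panel container.
#' 1-based VCF positions are preserved, missing genotypes become \code{NA}
#' allele indices, and multiallelic records are retained with all alleles.
#'
#' @param path Path to a VCF file.
#' @param populations Optional named character vector mapping individual id
#'   to population label; unlisted individuals get population \code{"NA"}.
#' @return A \code{HaplotypePanel}.
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  ids <- colnames(v@gt)[-1]
  if (is.null(ids)) ids <- character(0)
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = as.character(fix[, "REF"]),
                      alt = ifelse(is.na(fix[, "ALT"]), "", as.character(fix[, "ALT"])),
                      stringsAsFactors = FALSE)
  if (n_site == 0L || length(ids) == 0L) {
    samples <- data.frame(id = ids,
                          population = rep("NA", length(ids)),
                          stringsAsFactors = FALSE)
    z <- matrix(integer(0), n_site, length(ids))
    return(haplotype_panel(samples, sites, z, z, matrix(logical(0), n_site, length(ids)),
                           NULL))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- any(grepl("DP", v@gt[, "FORMAT"]))
  dp <- if (has_dp)
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)) else NULL

  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^[^/|]*[/|]", "", gt)
  phased <- grepl("|", gt, fixed = TRUE)
  to_idx <- function(a) {
    a[a %in% c(".", "")] <- NA_character_
    suppressWarnings(matrix(as.integer(a), n_site, length(ids)))
  }
  g1 <- to_idx(a1); g2 <- to_idx(a2)
  g1[is.na(gt)] <- NA_integer_; g2[is.na(gt)] <- NA_integer_
  phased[is.na(gt)] <- FALSE
  samples <- data.frame(id = ids, population = rep("NA", length(ids)),
                        stringsAsFactors = FALSE)
  if (!is.null(populations))
    samples$population <- ifelse(ids %in% names(populations),
                                 unname(populations[ids]), "NA")
  haplotype_panel(samples, sites, g1, g2,
                  matrix(phased, n_site, length(ids)),
                  if (is.null(dp)) NULL else
                    matrix(as.integer(round(dp)), n_site, length(ids)))
}

#' Write a HaplotypePanel as a plain-text VCF 4.2 file
#'
#' Deterministic writer emitting GT (with "|" for phased genotypes) and,
#' when depth is present, DP. Records are ordered by chromosome (order of
#' first appearance) then position.
#'
#' @param panel A \code{HaplotypePanel}.
#' @param path Output path.
#' @param contigs Optional named integer vector of chromosome lengths for
#'   the header.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(panel, path, contigs = NULL) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples$id), collapse = "\t"), con)
  n <- nrow(panel$sites)
  if (n == 0L) return(invisible(path))
  ord <- order(match(panel$sites$chrom, unique(panel$sites$chrom)),
               panel$sites$pos)
  has_dp <- !is.null(panel$depth)
  fmt <- if (has_dp) "GT:DP" else "GT"
  idx_chr <- function(m) ifelse(is.na(m), ".", as.character(m))
  g1 <- idx_chr(panel$geno1); g2 <- idx_chr(panel$geno2)
  sep <- ifelse(panel$phased, "|", "/")
  gtf <- matrix(paste0(g1, sep, g2), n, ncol(g1))
  if (has_dp) gtf <- matrix(paste0(gtf, ":", panel$depth), n, ncol(g1))
  alt <- ifelse(panel$sites$alt == "", ".", panel$sites$alt)
  body <- paste(panel$sites$chrom[ord], panel$sites$pos[ord], ".",
                panel$sites$ref[ord], alt[ord], ".", "PASS", ".", fmt,
                sep = "\t")
  if (ncol(gtf) > 0)
    body <- paste(body, apply(gtf[ord, , drop = FALSE], 1, paste, collapse = "\t"),
                  sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Coverage validity mask
#'
#' A site is valid when every individual's read depth lies inside the
#' inclusive band \code{[low, high]} (default 20--200x). Sites failing the
#' band in any individual are excluded from all downstream per-site
#' statistics.
#'
#' @param panel A \code{HaplotypePanel} with depth.
#' @param low,high Inclusive depth bounds.
#' @return Logical vector, one element per site.
#' @export
coverage_mask <- function(panel, low = 20, high = 200) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  if (is.null(panel$depth))
    stop("panel has no depth information; cannot build a coverage mask")
  d <- panel$depth
  rowSums(d >= low & d <= high, na.rm = FALSE) == ncol(d)
}

#' Read / write BED-style interval tables
#'
#' BED files are 0-based half-open; internally the package uses 1-based
#' inclusive positions, so these helpers do the conversion.
#'
#' @param x data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive) plus any extra columns.
#' @param path File path.
#' @return \code{read_bed}: data.frame with 1-based inclusive
#'   \code{start}/\code{end}; \code{write_bed}: \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- x
  out$start <- as.integer(out$start) - 1L  # to 0-based half-open
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names Names for the columns beyond the first three.
#' @export
read_bed <- function(path, col_names = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  x$start <- x$start + 1L  # to 1-based inclusive
  if (!is.null(col_names) && ncol(x) >= 3 + length(col_names))
    names(x)[3 + seq_along(col_names)] <- col_names
  x
}
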