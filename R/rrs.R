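# In silico RAD and ddRAD sequencing.
#
# Determines which diagnostic SNPs inside introgression tracts would be
# captured by reduced-representation designs, under the perfect-sequencing
# assumption (every conserved restriction site / size-selected fragment is
# sequenced at full depth). Recognition-site scanning runs on the forward
# strand; the default enzymes are palindromic, so the scan is
# strand-complete. Cut offsets are ignored: interval arithmetic uses the
# recognition-site footprint, immaterial at 100-bp read scale.

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param site Recognition sequence (IUPAC allowed; defaults are exact).
#' @return An \code{Enzyme} object.
#' @export
enzyme <- function(name, site) {
  site <- toupper(site)
  if (nchar(site) < 4) stop("recognition sequence must be >= 4 bp")
  structure(list(name = name, site = site, width = nchar(site)),
            class = "Enzyme")
}

#' Default enzyme set
#'
#' SbfI (CCTGCAGG) for RAD; EcoRI (GAATTC), MspI (CCGG) and SphI (GCATGC)
#' for the two ddRAD designs.
#' @return Named list of \code{Enzyme} objects.
#' @export
default_enzymes <- function() {
  list(SbfI = enzyme("SbfI", "CCTGCAGG"),
       EcoRI = enzyme("EcoRI", "GAATTC"),
       MspI = enzyme("MspI", "CCGG"),
       SphI = enzyme("SphI", "GCATGC"))
}

# all forward-strand occurrences (1-based start positions) of an enzyme's
# recognition sequence in one chromosome sequence
.enzyme_sites <- function(seq, enz, region = NULL) {
  sub <- seq
  offset <- 0L
  if (!is.null(region)) {
    sub <- Biostrings::subseq(seq, region[1], region[2])
    offset <- region[1] - 1L
  }
  m <- Biostrings::matchPattern(enz$site, sub, fixed = FALSE)
  Biostrings::start(m) + offset
}

#' Find species-conserved restriction sites
#'
#' All forward-strand occurrences of the recognition sequence whose
#' footprint overlaps no interspecies fixed difference; only conserved
#' sites are informative for RAD/ddRAD because a fixed difference inside
#' the site causes allele-specific cutting.
#'
#' @param reference A \code{DNAStringSet} (or single \code{DNAString}).
#' @param chrom Chromosome name within \code{reference}.
#' @param fixed_diff_pos Integer vector of 1-based positions of fixed
#'   interspecies differences on \code{chrom} (all fixed differences, not
#'   only B-specific ones).
#' @param enz An \code{Enzyme}.
#' @param region Optional \code{c(start, end)} (1-based inclusive).
#' @return Integer vector of conserved site start positions.
#' @export
find_conserved_sites <- function(reference, chrom, fixed_diff_pos, enz,
                                 region = NULL) {
  seq <- if (inherits(reference, "DNAStringSet")) reference[[chrom]] else reference
  starts <- .enzyme_sites(seq, enz, region)
  if (!length(starts)) return(integer(0))
  keep <- vapply(starts, function(s)
    !any(fixed_diff_pos >= s & fixed_diff_pos <= s + enz$width - 1L),
    logical(1))
  starts[keep]
}

#' RAD capture intervals around a conserved restriction site
#'
#' Models 2 x 100 bp paired-end RAD sequencing: 100 bp immediately
#' upstream and downstream of the restriction-site footprint, plus the
#' 100-bp mate footprints whose near edge lies 400 bp away from the site
#' on each flank. Intervals are clipped to chromosome bounds.
#'
#' @param site_start 1-based start of the recognition footprint.
#' @param site_width Footprint width in bp.
#' @param read_length Read length in bp (default 100).
#' @param far_offset Near-edge distance of the mate footprint from the
#'   site (default 400 bp).
#' @param chrom_len Chromosome length for clipping.
#' @return data.frame of 1-based inclusive intervals: start, end.
#' @export
rad_capture_intervals <- function(site_start, site_width, read_length = 100,
                                  far_offset = 400, chrom_len = Inf) {
  s <- site_start; e <- site_start + site_width - 1L
  iv <- data.frame(
    start = c(s - read_length, e + 1L,
              s - far_offset - read_length, e + far_offset + 1L),
    end = c(s - 1L, e + read_length,
            s - far_offset - 1L, e + far_offset + read_length))
  iv$start <- pmax(iv$start, 1L)
  iv$end <- pmin(iv$end, chrom_len)
  iv[iv$start <= iv$end, , drop = FALSE]
}

#' Size-selected ddRAD fragments and their capture intervals
#'
#' Fragments bounded by one cut site of each enzyme with no internal site
#' of either (size-selected libraries cannot contain internally cut
#' fragments), with total length -- measured across both recognition
#' footprints -- inside \code{size +/- tol}. Capture intervals are the
#' \code{read_length} bp inward from both fragment ends.
#'
#' @param reference \code{DNAStringSet} or \code{DNAString}.
#' @param chrom Chromosome name (ignored for a bare \code{DNAString}).
#' @param enzA,enzB Distinct \code{Enzyme}s.
#' @param fixed_diff_pos Fixed-difference positions used to drop
#'   non-conserved sites (default none).
#' @param size,tol Fragment size selection in bp (default 300 +/- 36).
#' @param read_length Read length in bp.
#' @param region Optional \code{c(start, end)} restriction.
#' @return List: \code{fragments} (data.frame start, end, length) and
#'   \code{capture} (data.frame start, end of capture intervals).
#' @export
ddrad_fragments <- function(reference, chrom = 1L, enzA, enzB,
                            fixed_diff_pos = integer(0), size = 300,
                            tol = 36, read_length = 100, region = NULL) {
  if (identical(enzA$site, enzB$site)) stop("enzymes must differ")
  seq <- if (inherits(reference, "DNAStringSet")) reference[[chrom]] else reference
  sa <- find_conserved_sites(seq, chrom, fixed_diff_pos, enzA, region)
  sb <- find_conserved_sites(seq, chrom, fixed_diff_pos, enzB, region)
  sites <- rbind(data.frame(start = sa, width = enzA$width, enz = "A"),
                 data.frame(start = sb, width = enzB$width, enz = "B"))
  sites <- sites[order(sites$start), , drop = FALSE]
  frag <- list()
  if (nrow(sites) >= 2) for (i in seq_len(nrow(sites) - 1L)) {
    # consecutive sites of different enzymes: no internal cut by construction
    if (sites$enz[i] == sites$enz[i + 1L]) next
    fs <- sites$start[i]
    fe <- sites$start[i + 1L] + sites$width[i + 1L] - 1L
    len <- fe - fs + 1L
    if (len >= size - tol && len <= size + tol)
      frag[[length(frag) + 1L]] <- data.frame(start = fs, end = fe,
                                              length = len)
  }
  fragments <- if (length(frag)) do.call(rbind, frag) else
    data.frame(start = integer(), end = integer(), length = integer())
  capture <- if (nrow(fragments))
    unique(rbind(
      data.frame(start = fragments$start,
                 end = pmin(fragments$start + read_length - 1L, fragments$end)),
      data.frame(start = pmax(fragments$end - read_length + 1L,
                              fragments$start),
                 end = fragments$end)))
  else data.frame(start = integer(), end = integer())
  rownames(fragments) <- NULL; rownames(capture) <- NULL
  list(fragments = fragments, capture = capture)
}

#' Count diagnostic SNPs captured per tract
#'
#' Number of distinct B-specific diagnostic sites inside each tract that
#' fall in at least one capture interval; a whole-genome-sequencing column
#' reports all B-specific diagnostic sites in the tract.
#'
#' @param tracts data.frame: chrom, start, end (1-based inclusive).
#' @param capture data.frame of capture intervals (start, end) per design,
#'   as a named list of data.frames keyed by design; intervals are assumed
#'   to be on \code{tracts}' chromosome unless a \code{chrom} column is
#'   present.
#' @param diag_sites \code{DiagnosticSiteTable}; only
#'   \code{B_specific == TRUE} rows count.
#' @return \code{CaptureReport} data.frame: one row per tract with
#'   \code{wgs} and one count column per design.
#' @export
count_captured <- function(tracts, capture, diag_sites) {
  bs <- diag_sites[which(diag_sites$B_specific), , drop = FALSE]
  out <- tracts[, c("chrom", "start", "end"), drop = FALSE]
  out$wgs <- vapply(seq_len(nrow(tracts)), function(i)
    sum(bs$chrom == tracts$chrom[i] & bs$pos >= tracts$start[i] &
          bs$pos <= tracts$end[i]), integer(1))
  for (design in names(capture)) {
    iv <- capture[[design]]
    out[[design]] <- vapply(seq_len(nrow(tracts)), function(i) {
      p <- bs$pos[bs$chrom == tracts$chrom[i] & bs$pos >= tracts$start[i] &
                    bs$pos <= tracts$end[i]]
      if (!length(p) || !nrow(iv)) return(0L)
      ivi <- if ("chrom" %in% names(iv))
        iv[iv$chrom == tracts$chrom[i], , drop = FALSE] else iv
      if (!nrow(ivi)) return(0L)
      sum(vapply(p, function(pp) any(pp >= ivi$start & pp <= ivi$end),
                 logical(1)))
    }, integer(1))
  }
  class(out) <- c("CaptureReport", "data.frame")
  out
}

#' Capture report for the standard designs over called tracts
#'
#' Runs SbfI RAD and the EcoRI-MspI / SphI-MspI ddRAD designs within each
#' tract and tallies captured B-specific diagnostic SNPs.
#'
#' @param reference \code{DNAStringSet}.
#' @param tracts data.frame: chrom, start, end.
#' @param diag_sites Polarized \code{DiagnosticSiteTable} (its full site
#'   list provides the fixed differences that disqualify restriction
#'   sites).
#' @param read_length,far_offset,size,tol Design geometry.
#' @return A \code{CaptureReport} with columns wgs, rad_sbfi,
#'   ddrad_ecori_mspi, ddrad_sphi_mspi.
#' @export
capture_report <- function(reference, tracts, diag_sites, read_length = 100,
                           far_offset = 400, size = 300, tol = 36) {
  enz <- default_enzymes()
  out <- NULL
  for (i in seq_len(nrow(tracts))) {
    chrom <- tracts$chrom[i]
    chrom_len <- length(reference[[chrom]])
    region <- c(max(1L, tracts$start[i]), min(chrom_len, tracts$end[i]))
    fd <- diag_sites$pos[diag_sites$chrom == chrom]
    sb <- find_conserved_sites(reference, chrom, fd, enz$SbfI, region)
    rad_iv <- if (length(sb)) do.call(rbind, lapply(sb, rad_capture_intervals,
                                                    site_width = enz$SbfI$width,
                                                    read_length = read_length,
                                                    far_offset = far_offset,
                                                    chrom_len = chrom_len))
      else data.frame(start = integer(), end = integer())
    dd1 <- ddrad_fragments(reference, chrom, enz$EcoRI, enz$MspI, fd,
                           size, tol, read_length, region)$capture
    dd2 <- ddrad_fragments(reference, chrom, enz$SphI, enz$MspI, fd,
                           size, tol, read_length, region)$capture
    row <- count_captured(tracts[i, , drop = FALSE],
                          list(rad_sbfi = rad_iv, ddrad_ecori_mspi = dd1,
                               ddrad_sphi_mspi = dd2), diag_sites)
    out <- if (is.null(out)) row else rbind(out, row)
  }
  if (is.null(out))
    out <- count_captured(tracts, list(rad_sbfi = data.frame(start = integer(),
                                                             end = integer())),
                          diag_sites)
  rownames(out) <- NULL
  out
}
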