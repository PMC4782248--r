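# Candidate screening and introgression-tract border calling.
#
# Two-stage procedure: a 500-kb/100-kb genotype-class screen flags windows
# where more than 2% of the B-specific sites carry species-B alleles (het
# or homB) in at least one individual; flagged windows are merged into
# candidate regions, and a 1-kb tiling-window dominant-genotype analysis
# inside candidates calls per-individual tracts and their borders.

# merge 1-based inclusive intervals (data.frame chrom,start,end), assuming
# any overlap or adjacency merges
.merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  out <- list()
  for (chrom in unique(x$chrom)) {
    xi <- x[x$chrom == chrom, , drop = FALSE]
    xi <- xi[order(xi$start), , drop = FALSE]
    s <- xi$start[1]; e <- xi$end[1]
    for (i in seq_len(nrow(xi))[-1]) {
      if (xi$start[i] <= e + 1L) e <- max(e, xi$end[i])
      else { out[[length(out) + 1L]] <- data.frame(chrom, start = s, end = e)
             s <- xi$start[i]; e <- xi$end[i] }
    }
    out[[length(out) + 1L]] <- data.frame(chrom, start = s, end = e)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  res
}

#' Screen 500-kb windows for candidate introgression regions
#'
#' A window qualifies when the fraction of its B-specific diagnostic sites
#' carried in a heterozygous or homozygous-B state exceeds the threshold in
#' at least one individual of the population. Overlapping qualifying
#' windows are merged into maximal candidate regions.
#'
#' @param geno_windows Output of
#'   \code{\link{genotype_class_proportion_windows}} for the population.
#' @param threshold Qualifying fraction (strictly exceeded; default 0.02).
#' @return data.frame of candidate regions: chrom, start, end.
#' @export
screen_candidates <- function(geno_windows, threshold = 0.02) {
  gw <- geno_windows
  frac_B <- gw$frac_het + gw$frac_homB
  hit <- !is.na(frac_B) & frac_B > threshold
  qual <- gw[hit, c("chrom", "start", "end"), drop = FALSE]
  qual <- unique(qual)
  .merge_intervals(qual)
}

#' Refine candidates and call per-individual tracts with borders
#'
#' Inside each candidate region, 1-kb tiling windows (anchored on the
#' absolute 1-kb grid of the chromosome) are labeled per individual by the
#' dominant genotype among the B-specific diagnostic sites they contain:
#' B-dominant when het + homB calls are the strict majority (>50%),
#' A-dominant when homA calls are, uninformative on ties or when empty.
#' Maximal runs of B-dominant windows -- bridged across uninformative
#' stretches up to \code{max_gap} bp but terminated by any A-dominant
#' window -- become tracts; borders fall on the window edges flanking the
#' run. Tracts are retained when longer than \code{min_length} bp and
#' supported by at least \code{min_sites} B-carrying segregating sites.
#'
#' @param candidates data.frame from \code{\link{screen_candidates}}.
#' @param track A \code{GenotypeClassTrack}.
#' @param min_length Minimum emitted tract length in bp, exclusive
#'   (default: >10 kb).
#' @param min_sites Minimum count of het/homB diagnostic sites summed over
#'   the tract (default 5).
#' @param max_gap Maximum run of uninformative bp bridged inside a tract.
#' @param window 1-kb refinement window size in bp.
#' @return data.frame of \code{IntrogressionTract} records: chrom, start,
#'   end, individual, n_sites, dominant_state ("het" or "hom").
#' @export
refine_and_call <- function(candidates, track, min_length = 10000,
                            min_sites = 5, max_gap = 5000, window = 1000) {
  stopifnot(inherits(track, "GenotypeClassTrack"))
  res <- list()
  for (r in seq_len(nrow(candidates))) {
    chrom <- candidates$chrom[r]
    cs <- candidates$start[r]; ce <- candidates$end[r]
    rows <- which(track$sites$chrom == chrom & track$sites$pos >= cs &
                    track$sites$pos <= ce)
    if (!length(rows)) {
      message("candidate region ", chrom, ":", cs, "-", ce,
              " has no informative B-specific sites; dropped")
      next
    }
    ord <- rows[order(track$sites$pos[rows])]
    pos <- track$sites$pos[ord]
    # absolute 1-kb grid windows covering the candidate
    w0 <- (floor((cs - 1) / window)):(floor((ce - 1) / window))
    wstart <- w0 * window + 1L; wend <- wstart + as.integer(window) - 1L
    for (j in seq_len(nrow(track$samples))) {
      cls <- track$class[ord, j]
      nA <- .win_sum(pos, as.numeric(cls == 0L), wstart, wend)
      nB <- .win_sum(pos, as.numeric(cls == 1L | cls == 2L), wstart, wend)
      lab <- integer(length(nA))          # 0 uninformative, 1 A-dom, 2 B-dom
      lab[nA > nB] <- 1L
      lab[nB > nA] <- 2L
      runs <- .b_runs(lab, max_gap %/% window)
      if (!nrow(runs)) next
      for (k in seq_len(nrow(runs))) {
        ts <- wstart[runs$from[k]]; te <- wend[runs$to[k]]
        sel <- pos >= ts & pos <= te
        n_supp <- sum(cls[sel] %in% c(1L, 2L))
        if ((te - ts + 1L) <= min_length || n_supp < min_sites) next
        n_het <- sum(cls[sel] == 1L); n_hom <- sum(cls[sel] == 2L)
        res[[length(res) + 1L]] <-
          data.frame(chrom = chrom, start = ts, end = te,
                     individual = track$samples$id[j], n_sites = n_supp,
                     dominant_state = if (n_hom > n_het) "hom" else "het",
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               individual = character(), n_sites = integer(),
               dominant_state = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  unique(out)
}

# maximal runs of label 2 in `lab`, bridging runs of label 0 up to
# `max_gap_windows` windows; label 1 always terminates a run
.b_runs <- function(lab, max_gap_windows) {
  from <- integer(0); to <- integer(0)
  i <- 1L; n <- length(lab)
  while (i <= n) {
    if (lab[i] == 2L) {
      s <- i; e <- i; k <- i + 1L
      while (k <= n) {
        if (lab[k] == 2L) { e <- k; k <- k + 1L }
        else if (lab[k] == 0L) {
          gap <- 0L; k2 <- k
          while (k2 <= n && lab[k2] == 0L) { gap <- gap + 1L; k2 <- k2 + 1L }
          if (k2 <= n && lab[k2] == 2L && gap <= max_gap_windows) k <- k2
          else break
        } else break
      }
      from <- c(from, s); to <- c(to, e)
      i <- e + 1L
    } else i <- i + 1L
  }
  data.frame(from = from, to = to)
}

#' Merge per-individual tracts into population-level introgression sites
#'
#' Union over individuals, mirroring the "in at least one individual in a
#' population" convention.
#'
#' @param tracts data.frame from \code{\link{refine_and_call}}.
#' @return data.frame: chrom, start, end.
#' @export
merge_tracts <- function(tracts) {
  if (nrow(tracts) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  .merge_intervals(tracts[, c("chrom", "start", "end"), drop = FALSE])
}

#' Overlap of two introgression-site sets
#'
#' A tract of \code{set1} counts as shared when it overlaps any tract of
#' \code{set2} by at least 1 bp.
#'
#' @param set1,set2 data.frames with chrom, start, end (1-based inclusive).
#' @return List: \code{shared} (subset of \code{set1}), \code{private}
#'   (rest of \code{set1}), \code{fraction} = shared / nrow(set1).
#' @export
overlap_tracts <- function(set1, set2) {
  if (nrow(set1) == 0) return(list(shared = set1, private = set1,
                                   fraction = NaN))
  hit <- vapply(seq_len(nrow(set1)), function(i) {
    any(set2$chrom == set1$chrom[i] & set2$start <= set1$end[i] &
          set2$end >= set1$start[i])
  }, logical(1))
  list(shared = set1[hit, , drop = FALSE],
       private = set1[!hit, , drop = FALSE],
       fraction = mean(hit))
}

#' Write tracts as a BED file
#'
#' Columns: chrom, start (0-based), end, individual, n_sites,
#' dominant_state.
#' @param tracts data.frame from \code{\link{refine_and_call}}.
#' @param path Output path.
#' @export
write_tracts_bed <- function(tracts, path) {
  write_bed(tracts[, c("chrom", "start", "end", "individual", "n_sites",
                       "dominant_state")], path)
}
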