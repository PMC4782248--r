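# End-to-end orchestration of the introgression scan.

#' Default scan parameters
#'
#' The thresholds of the published procedure: inclusive 20--200x coverage
#' band, 500-kb/100-kb screen windows with a 2% qualifying fraction, 1-kb
#' refinement windows, >10-kb / >=5-supporting-site tract filters, 300 +/-
#' 36 bp ddRAD size selection, 5-cM LD pair cutoff and 0.05 HWE exclusion
#' level.
#'
#' @return Named list of parameters.
#' @export
scan_params <- function() {
  list(cov_low = 20, cov_high = 200,
       screen_size = 500000, screen_step = 100000,
       screen_threshold = 0.02,
       refine_window = 1000, min_tract_length = 10000,
       min_tract_sites = 5, max_gap = 5000,
       ddrad_size = 300, ddrad_tol = 36,
       read_length = 100, far_offset = 400,
       max_cM = 5, hwe_alpha = 0.05)
}

#' Run the introgression scan end to end
#'
#' Builds the coverage mask, discovers and polarizes diagnostic sites,
#' classifies the target populations, screens and refines introgression
#' tracts per population, and (optionally) tallies RAD/ddRAD capture of
#' the called tracts. Deterministic: identical inputs give identical
#' outputs.
#'
#' @param bundle A simulation bundle from \code{\link{simulate_bundle}},
#'   or a list with the same elements built from real data
#'   (\code{reference}, \code{panel}, \code{config$chrom_lengths},
#'   \code{config$exclude_chroms}).
#' @param populations Character vector of population labels to scan
#'   (default: focal and comparison).
#' @param params Parameter list, see \code{\link{scan_params}}.
#' @param outdir Optional output directory for BED/TSV artifacts.
#' @param capture Also compute the reduced-representation capture report
#'   for the first population's merged tracts.
#' @return List: \code{mask}, \code{diagnostic_sites}, per-population
#'   \code{tracts} and merged \code{sites}, \code{overlap} between the
#'   first two populations (when two are scanned), \code{capture_report}.
#' @export
run_pipeline <- function(bundle, populations = c("focal", "comparison"),
                         params = scan_params(), outdir = NULL,
                         capture = FALSE) {
  panel <- bundle$panel
  excl <- bundle$config$exclude_chroms
  chrom_lengths <- bundle$config$chrom_lengths
  mask <- coverage_mask(panel, params$cov_low, params$cov_high)
  pa <- subset_panel(panel, population = "species_a")
  pb <- subset_panel(panel, population = "species_b")
  og <- subset_panel(panel, population = "outgroup")
  sites <- find_fixed_differences(pa, pb, mask, exclude_chroms = excl)
  sites <- polarize(sites, og)
  tracts <- list(); merged <- list()
  empty_tracts <- data.frame(chrom = character(), start = integer(),
                             end = integer(), individual = character(),
                             n_sites = integer(),
                             dominant_state = character(),
                             stringsAsFactors = FALSE)
  for (pop in populations) {
    pp <- subset_panel(panel, population = pop)
    track <- classify(pp, sites)
    if (nrow(track$sites) == 0) {
      tracts[[pop]] <- empty_tracts
      merged[[pop]] <- merge_tracts(empty_tracts)
      next
    }
    gw <- genotype_class_proportion_windows(track, params$screen_size,
                                            params$screen_step,
                                            chrom_lengths[!(names(chrom_lengths)
                                                            %in% excl)])
    cand <- screen_candidates(gw, params$screen_threshold)
    tr <- refine_and_call(cand, track, params$min_tract_length,
                          params$min_tract_sites, params$max_gap,
                          params$refine_window)
    tracts[[pop]] <- tr
    merged[[pop]] <- merge_tracts(tr)
  }
  ov <- if (length(populations) >= 2)
    overlap_tracts(merged[[populations[1]]], merged[[populations[2]]])
  else NULL
  cap <- NULL
  if (capture && nrow(merged[[populations[1]]]) > 0)
    cap <- capture_report(bundle$reference, merged[[populations[1]]], sites,
                          params$read_length, params$far_offset,
                          params$ddrad_size, params$ddrad_tol)
  res <- list(mask = mask, diagnostic_sites = sites, tracts = tracts,
              sites_merged = merged, overlap = ov, capture_report = cap,
              params = params)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_diagnostic_sites(sites, file.path(outdir, "diagnostic_sites.tsv"))
    for (pop in names(tracts))
      if (nrow(tracts[[pop]]) > 0)
        write_tracts_bed(tracts[[pop]],
                         file.path(outdir, paste0("tracts_", pop, ".bed")))
    if (!is.null(cap))
      utils::write.table(cap, file.path(outdir, "capture_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
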