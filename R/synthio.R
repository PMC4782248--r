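#' Configuration for the two-species genome simulator
#'
#' Describes the statistical structure the downstream analysis assumes: two
#' species panels diverged by a per-bp substitution probability, an outgroup
#' lineage with private substitutions, within-population polymorphism with
#' target heterozygous-site proportions, planted introgression tracts
#' carried by subsets of the focal population, a per-site read-depth model
#' with a dropout fraction that exercises the 20--200x coverage filter, and
#' a spatially varying recombination map.
#'
#' @param seed Integer seed; all randomness in \code{\link{simulate_bundle}}
#'   flows from it through one generator.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param interspecies_div Per-bp substitution probability between the two
#'   species (default 0.0144, the empirical divergence regime the pipeline
#'   was designed around).
#' @param outgroup_extra_div Per-bp substitution probability on the private
#'   outgroup branch.
#' @param pi_focal,pi_anadromous Target per-bp heterozygous-site proportions
#'   for the focal and comparison ("anadromous-like") populations.
#' @param panel_sizes Named integer vector with elements \code{species_a},
#'   \code{species_b}, \code{outgroup}, \code{focal}, \code{comparison}.
#' @param tracts data.frame of planted introgression tracts with columns
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#'   \code{carriers} (comma-separated focal individual ids) and
#'   \code{zygosity} ("het" or "hom").
#' @param coverage_mean,coverage_sd Per-site per-individual depth model:
#'   depth = max(0, round(Normal(mean, sd))).
#' @param dropout_rate Fraction of (site, individual) depths forced below 20
#'   to push sites outside the valid coverage band.
#' @param recomb_profile data.frame of recombination-rate knots with columns
#'   \code{chrom}, \code{pos} (bp) and \code{rate} (cM/Mb).
#' @param exclude_chroms Chromosomes tagged as excluded from the
#'   introgression scan (the sex-chromosome exclusion).
#' @param mnp_rate,indel_rate Optional low per-bp rates of 2-bp MNPs and
#'   1-bp deletions segregating in the ingroup, used only to exercise the
#'   amplicon SNP-type filters.
#' @return A validated \code{SimulationConfig} list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 1000000L),
                              interspecies_div = 0.0144,
                              outgroup_extra_div = 0.01,
                              pi_focal = 1.5e-3,
                              pi_anadromous = 3.1e-3,
                              panel_sizes = c(species_a = 10L, species_b = 10L,
                                              outgroup = 2L, focal = 4L,
                                              comparison = 4L),
                              tracts = NULL,
                              coverage_mean = 60, coverage_sd = 15,
                              dropout_rate = 0,
                              recomb_profile = NULL,
                              exclude_chroms = character(),
                              mnp_rate = 0, indel_rate = 0) {
  probs <- c(interspecies_div, outgroup_extra_div, pi_focal, pi_anadromous,
             dropout_rate, mnp_rate, indel_rate)
  if (any(probs < 0 | probs > 1)) stop("all rates must lie in [0, 1]")
  need <- c("species_a", "species_b", "outgroup", "focal", "comparison")
  if (!all(need %in% names(panel_sizes)))
    stop("panel_sizes must name: ", paste(need, collapse = ", "))
  if (any(panel_sizes < 1)) stop("all panel sizes must be >= 1")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (!is.null(tracts)) {
    stopifnot(all(c("chrom", "start", "end", "carriers", "zygosity") %in%
                    names(tracts)))
    if (!all(tracts$zygosity %in% c("het", "hom")))
      stop("tract zygosity must be 'het' or 'hom'")
    bad <- !(tracts$chrom %in% names(chrom_lengths)) |
      tracts$start < 1 | tracts$end > chrom_lengths[tracts$chrom] |
      tracts$start > tracts$end
    if (any(bad)) stop("tract interval(s) outside chromosome bounds")
    # conflicting zygosity for one carrier on overlapping tracts is ill-posed
    carr <- strsplit(tracts$carriers, ",", fixed = TRUE)
    for (id in unique(unlist(carr))) {
      k <- which(vapply(carr, function(x) id %in% x, logical(1)))
      if (length(k) < 2) next
      for (a in k) for (b in k) if (a < b &&
            tracts$chrom[a] == tracts$chrom[b] &&
            tracts$start[a] <= tracts$end[b] && tracts$start[b] <= tracts$end[a] &&
            tracts$zygosity[a] != tracts$zygosity[b])
        stop("overlapping tracts with conflicting zygosity for carrier ", id)
    }
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 interspecies_div = interspecies_div,
                 outgroup_extra_div = outgroup_extra_div,
                 pi_focal = pi_focal, pi_anadromous = pi_anadromous,
                 panel_sizes = panel_sizes, tracts = tracts,
                 coverage_mean = coverage_mean, coverage_sd = coverage_sd,
                 dropout_rate = dropout_rate, recomb_profile = recomb_profile,
                 exclude_chroms = exclude_chroms,
                 mnp_rate = mnp_rate, indel_rate = indel_rate),
            class = "SimulationConfig")
}

.other_base <- function(base, rng_u) {
  # deterministic pick of a base != `base` driven by uniform draws in [0,1)
  bases <- c("A", "C", "G", "T")
  idx <- match(base, bases)
  pick <- floor(rng_u * 3) + 1L            # 1..3
  alt <- matrix(c(2:4, c(1L, 3:4), c(1:2, 4L), 1:3), nrow = 3)
  bases[alt[cbind(pick, idx)]]
}

#' Simulate a two-species resequencing bundle with truth set
#'
#' Generates, deterministically from \code{config$seed}: a reference genome
#' (the ancestral sequence), fixed interspecies differences assigned 50:50
#' to the two ingroup lineages (infinite-sites, no back mutation), private
#' outgroup substitutions, within-population polymorphism calibrated so the
#' expected per-individual heterozygous-site proportion equals the
#' configured pi, planted introgression tracts in which carrier individuals
#' hold species-B alleles on one (het) or both (hom) haplotypes, per-site
#' per-individual read depths, and a recombination-map table.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param outdir Optional directory; when given, writes reference FASTA,
#'   panel VCF, recombination map TSV, truth-tract BED and diagnostic-site
#'   TSV there.
#' @return List with elements \code{reference} (DNAStringSet), \code{panel}
#'   (\code{HaplotypePanel} over all individuals), \code{map} (data.frame),
#'   \code{truth} (list: \code{tracts}, \code{diagnostic_sites}),
#'   \code{callable_fraction} (analytic probability that a site passes the
#'   20--200x filter in all individuals) and \code{config}.
#' @export
simulate_bundle <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ps <- config$panel_sizes
  ids <- c(paste0("A", seq_len(ps["species_a"])),
           paste0("B", seq_len(ps["species_b"])),
           paste0("OUT", seq_len(ps["outgroup"])),
           paste0("F", seq_len(ps["focal"])),
           paste0("C", seq_len(ps["comparison"])))
  pops <- rep(c("species_a", "species_b", "outgroup", "focal", "comparison"),
              times = ps[c("species_a", "species_b", "outgroup", "focal",
                           "comparison")])
  n_ind <- length(ids)
  is_A <- pops == "species_a"; is_B <- pops == "species_b"
  is_out <- pops == "outgroup"; is_F <- pops == "focal"
  is_C <- pops == "comparison"
  in_group <- !is_out

  ref_seqs <- character(0)
  site_list <- list(); g1_list <- list(); g2_list <- list()
  diag_list <- list()

  for (chrom in names(config$chrom_lengths)) {
    L <- as.integer(config$chrom_lengths[chrom])
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ref_seqs[chrom] <- paste(ref, collapse = "")

    n_div <- stats::rbinom(1, L, config$interspecies_div)
    pos_div <- sort(sample.int(L, n_div))
    lineage_B <- stats::runif(n_div) < 0.5
    derived <- .other_base(ref[pos_div], stats::runif(n_div))

    n_out <- stats::rbinom(1, L, config$outgroup_extra_div)
    pos_out <- sort(sample.int(L, n_out))
    out_derived <- .other_base(ref[pos_out], stats::runif(n_out))

    draw_poly <- function(rate) {
      n <- stats::rbinom(1, L, 2 * rate)
      p <- sort(sample.int(L, min(n, L)))
      p <- p[!(p %in% pos_div) & !(p %in% pos_out)]
      list(pos = p, alt = .other_base(ref[p], stats::runif(length(p))))
    }
    pf <- draw_poly(config$pi_focal)
    pc0 <- draw_poly(config$pi_anadromous)
    keep <- !(pc0$pos %in% pf$pos)
    pc <- list(pos = pc0$pos[keep], alt = pc0$alt[keep])

    pos_all <- sort(unique(c(pos_div, pos_out, pf$pos, pc$pos)))
    ns <- length(pos_all)
    i_div <- match(pos_all, pos_div)     # NA where not a divergence site
    i_out <- match(pos_all, pos_out)
    i_pf <- match(pos_all, pf$pos)
    i_pc <- match(pos_all, pc$pos)

    ref_s <- ref[pos_all]
    # per-site allele registry: ref plus alternatives in deterministic order
    alt1 <- ifelse(is.na(i_div), NA, derived[i_div])
    alt_out <- ifelse(is.na(i_out), NA, out_derived[i_out])
    altF <- ifelse(is.na(i_pf), NA, pf$alt[i_pf])
    altC <- ifelse(is.na(i_pc), NA, pc$alt[i_pc])
    alts <- vector("list", ns)
    for (i in seq_len(ns)) {
      a <- c(alt1[i], alt_out[i], altF[i], altC[i])
      alts[[i]] <- setdiff(unique(a[!is.na(a)]), ref_s[i])
    }
    idx_of <- function(ch) {
      out <- integer(ns); out[] <- 0L
      known <- !is.na(ch)
      out[known] <- mapply(function(a, alleles, r) {
        if (a == r) 0L else match(a, alleles)
      }, ch[known], alts[known], ref_s[known])
      out[!known] <- NA_integer_
      out
    }
    idx_div <- idx_of(alt1)      # index of the ingroup-derived allele
    idx_outg <- idx_of(alt_out)  # index of the outgroup-derived allele
    idx_F <- idx_of(altF); idx_C <- idx_of(altC)

    linB <- rep(NA, ns); linB[!is.na(i_div)] <- lineage_B[i_div[!is.na(i_div)]]
    # species-A and species-B allele indices at divergence sites
    iA <- ifelse(!is.na(i_div) & !linB, idx_div, 0L)
    iB <- ifelse(!is.na(i_div) & linB, idx_div, 0L)
    iOUT <- ifelse(!is.na(i_out), idx_outg, 0L)

    g1 <- matrix(0L, ns, n_ind); g2 <- matrix(0L, ns, n_ind)
    # species assignment: panels A, focal, comparison carry allele_A;
    # panel B carries allele_B; outgroup carries its own lineage state
    sel_div <- !is.na(i_div)
    for (j in which(is_A | is_F | is_C)) {
      g1[sel_div, j] <- iA[sel_div]; g2[sel_div, j] <- iA[sel_div]
    }
    for (j in which(is_B)) {
      g1[sel_div, j] <- iB[sel_div]; g2[sel_div, j] <- iB[sel_div]
    }
    sel_out <- !is.na(i_out)
    for (j in which(is_out)) {
      g1[sel_out, j] <- iOUT[sel_out]; g2[sel_out, j] <- iOUT[sel_out]
    }
    # within-population polymorphism, haplotype allele frequency 0.5
    plant_poly <- function(sel, idx, cols) {
      rows <- which(!is.na(idx))
      if (!length(rows)) return()
      for (j in cols) {
        h1 <- stats::runif(length(rows)) < 0.5
        h2 <- stats::runif(length(rows)) < 0.5
        g1[rows[h1], j] <<- idx[rows[h1]]
        g2[rows[h2], j] <<- idx[rows[h2]]
      }
    }
    plant_poly(i_pf, idx_F, which(is_F))
    plant_poly(i_pc, idx_C, which(is_C))
    # planted introgression tracts: carriers hold species-B alleles inside
    if (!is.null(config$tracts)) {
      tr <- config$tracts[config$tracts$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(tr))) {
        rows <- which(sel_div & pos_all >= tr$start[k] & pos_all <= tr$end[k])
        carriers <- strsplit(tr$carriers[k], ",", fixed = TRUE)[[1]]
        cols <- match(carriers, ids)
        if (anyNA(cols)) stop("unknown tract carrier id")
        for (j in cols) {
          g2[rows, j] <- iB[rows]
          if (tr$zygosity[k] == "hom") g1[rows, j] <- iB[rows]
        }
      }
    }

    alt_str <- vapply(alts, paste, collapse = ",", FUN.VALUE = "")
    site_list[[chrom]] <- data.frame(chrom = rep(chrom, ns), pos = pos_all,
                                     ref = ref_s, alt = alt_str,
                                     stringsAsFactors = FALSE)
    g1_list[[chrom]] <- g1; g2_list[[chrom]] <- g2

    if (n_div > 0) {
      all_alleles <- mapply(function(r, a) c(r, a), ref_s, alts,
                            SIMPLIFY = FALSE)
      sel <- which(sel_div)
      aA <- mapply(function(i, al) al[iA[i] + 1L], sel, all_alleles[sel])
      aB <- mapply(function(i, al) al[iB[i] + 1L], sel, all_alleles[sel])
      aO <- mapply(function(i, al) al[(if (is.na(i_out[i])) 0L else iOUT[i]) + 1L],
                   sel, all_alleles[sel])
      diag_list[[chrom]] <- data.frame(chrom = chrom, pos = pos_all[sel],
                                       allele_A = unname(aA), allele_B = unname(aB),
                                       allele_out = unname(aO),
                                       B_specific = unname(aO == aA),
                                       stringsAsFactors = FALSE)
    }
  }

  sites <- do.call(rbind, site_list); rownames(sites) <- NULL
  if (is.null(sites))
    sites <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
  g1 <- do.call(rbind, g1_list); g2 <- do.call(rbind, g2_list)
  if (is.null(g1)) { g1 <- matrix(0L, 0, n_ind); g2 <- g1 }
  ns_tot <- nrow(sites)

  # optional MNP / 1-bp deletion records for the amplicon-filter exercises
  if ((config$mnp_rate > 0 || config$indel_rate > 0) && ns_tot >= 0) {
    extra <- list()
    for (chrom in names(config$chrom_lengths)) {
      L <- as.integer(config$chrom_lengths[chrom])
      refchars <- strsplit(ref_seqs[chrom], "")[[1]]
      mk <- function(n_sites, kind) {
        if (n_sites == 0) return(NULL)
        p <- sort(sample.int(L - 2L, n_sites))
        p <- p[!(p %in% sites$pos[sites$chrom == chrom])]
        if (!length(p)) return(NULL)
        refa <- paste0(refchars[p], refchars[p + 1L])
        alta <- if (kind == "mnp")
          paste0(.other_base(refchars[p], stats::runif(length(p))),
                 .other_base(refchars[p + 1L], stats::runif(length(p))))
        else substr(refa, 1, 1)
        data.frame(chrom = chrom, pos = p, ref = refa, alt = alta,
                   stringsAsFactors = FALSE)
      }
      extra[[paste0(chrom, "_mnp")]] <- mk(stats::rbinom(1, L, config$mnp_rate), "mnp")
      extra[[paste0(chrom, "_ind")]] <- mk(stats::rbinom(1, L, config$indel_rate), "indel")
    }
    extra <- do.call(rbind, extra)
    if (!is.null(extra) && nrow(extra)) {
      ge1 <- matrix(0L, nrow(extra), n_ind); ge2 <- ge1
      for (j in which(in_group)) {
        ge1[stats::runif(nrow(extra)) < 0.5, j] <- 1L
        ge2[stats::runif(nrow(extra)) < 0.5, j] <- 1L
      }
      sites <- rbind(sites, extra)
      g1 <- rbind(g1, ge1); g2 <- rbind(g2, ge2)
      ord <- order(match(sites$chrom, names(config$chrom_lengths)), sites$pos)
      sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
      g1 <- g1[ord, , drop = FALSE]; g2 <- g2[ord, , drop = FALSE]
      ns_tot <- nrow(sites)
    }
  }

  depth <- matrix(pmax(0L, as.integer(round(stats::rnorm(ns_tot * n_ind,
                                                         config$coverage_mean,
                                                         config$coverage_sd)))),
                  ns_tot, n_ind)
  if (config$dropout_rate > 0 && ns_tot > 0) {
    drop <- matrix(stats::runif(ns_tot * n_ind) < config$dropout_rate,
                   ns_tot, n_ind)
    depth[drop] <- as.integer(sample.int(20L, sum(drop), replace = TRUE) - 1L)
  }

  panel <- haplotype_panel(data.frame(id = ids, population = pops,
                                      stringsAsFactors = FALSE),
                           sites, g1, g2, TRUE, depth)

  p_band <- stats::pnorm(200.5, config$coverage_mean, config$coverage_sd) -
    stats::pnorm(19.5, config$coverage_mean, config$coverage_sd)
  callable_fraction <- ((1 - config$dropout_rate) * p_band)^n_ind

  diag_sites <- do.call(rbind, diag_list)
  if (is.null(diag_sites))
    diag_sites <- data.frame(chrom = character(), pos = integer(),
                             allele_A = character(), allele_B = character(),
                             allele_out = character(), B_specific = logical())
  rownames(diag_sites) <- NULL
  truth <- list(tracts = config$tracts, diagnostic_sites = diag_sites)

  map <- NULL
  if (!is.null(config$recomb_profile)) {
    prof <- config$recomb_profile
    map <- do.call(rbind, lapply(split(prof, prof$chrom), function(p) {
      grid <- seq(min(p$pos), max(p$pos), by = 50000)
      data.frame(chrom = p$chrom[1], pos = grid,
                 rate = stats::approx(p$pos, p$rate, xout = grid)$y,
                 stringsAsFactors = FALSE)
    }))
    rownames(map) <- NULL
  }

  bundle <- list(reference = Biostrings::DNAStringSet(ref_seqs),
                 panel = panel, map = map, truth = truth,
                 callable_fraction = callable_fraction, config = config)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Write a simulated bundle to disk
#'
#' @param bundle Result of \code{\link{simulate_bundle}}.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$reference,
                              file.path(outdir, "reference.fa"))
  write_vcf(bundle$panel, file.path(outdir, "panel.vcf"),
            contigs = bundle$config$chrom_lengths)
  if (!is.null(bundle$map))
    utils::write.table(bundle$map, file.path(outdir, "recomb_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth$tracts))
    write_bed(bundle$truth$tracts[, c("chrom", "start", "end", "carriers",
                                      "zygosity")],
              file.path(outdir, "truth_tracts.bed"))
  utils::write.table(bundle$truth$diagnostic_sites,
                     file.path(outdir, "truth_diagnostic_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Per-individual heterozygous-site proportion
#'
#' Count of heterozygous genotypes at validated sites divided by the number
#' of validated nucleotide sites. When \code{callable_sites} is supplied it
#' is used as the denominator (the genome-scale count of sites passing the
#' coverage filter, including invariant positions); otherwise the
#' denominator is the number of masked variant sites, which is only
#' meaningful for SNP-level summaries.
#'
#' @param panel A \code{HaplotypePanel}.
#' @param individual Individual id.
#' @param mask Logical site mask (default: all sites valid).
#' @param callable_sites Optional denominator in bp.
#' @return Proportion in [0, 1]; \code{NA} (flagged undefined) when the
#'   denominator is zero.
#' @export
observed_het_proportion <- function(panel, individual, mask = NULL,
                                    callable_sites = NULL) {
  j <- match(individual, panel$samples$id)
  if (is.na(j)) stop("unknown individual: ", individual)
  if (is.null(mask)) mask <- rep(TRUE, nrow(panel$sites))
  g1 <- panel$geno1[mask, j]; g2 <- panel$geno2[mask, j]
  ok <- !is.na(g1) & !is.na(g2)
  het <- sum(g1[ok] != g2[ok])
  denom <- if (is.null(callable_sites)) sum(ok) else callable_sites
  if (is.na(denom) || denom <= 0) return(NA_real_)
  het / denom
}
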