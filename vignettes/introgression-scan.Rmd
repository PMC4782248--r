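---
title: "Methods: scanning diploid genomes for small introgression tracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning diploid genomes for small introgression tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

# Overview

`introscan` detects short tracts (10 kb – 500 kb) of one species' genome
embedded in another's, using whole-genome resequencing panels of both
species, an outgroup, and the admixed target population. The method is
deliberately rule-based rather than probabilistic: with an interspecific
divergence of ~1.44 % per bp, a tract of even 10 kb carries dozens of
species-diagnostic alleles, so simple fixed-difference counting with
majority-vote windows has essentially complete power, and every decision
remains auditable. This vignette records the model, the tunable
parameters, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

# The detection model

## Diagnostic sites

A site is a candidate diagnostic site when every sampled chromosome of
species panel A carries one allele and every chromosome of panel B a
different one. Fixity is absolute — a single alternative allele disquali-
fies the site; there is no frequency threshold. The default panels of 10 +
10 individuals make spurious fixity at truly polymorphic sites rare.
Polarization then keeps only sites where the outgroup carries the species-
A allele, so the mutation happened on the B lineage and presence of the B
allele in the target population indicates B ancestry rather than shared
ancestral polymorphism. Sites where the outgroup is missing, polymorphic,
or carries a third allele are uninformative for polarity and are dropped
from the B-specific set: a third-allele outgroup state cannot attribute
the mutation to either ingroup lineage. Sex chromosomes are excluded via a
chromosome blocklist, since X/Y divergence within species defeats the
fixed-difference logic.

## Coverage validation

All per-site statistics are restricted to *validated* sites: every
analyzed individual must have read depth inside the inclusive band
[20, 200]. The lower bound suppresses genotyping error at low coverage;
the upper bound removes collapsed repeats. In this package depth arrives
through the VCF `DP` field per variant record, whereas the band
conceptually applies to every reference position; per-bp denominators are
therefore computed as region length × an analytic callable fraction (see
*Denominators* below).

## Two-stage tract calling

Stage one screens 500-kb windows (step 100 kb, anchored at position 0)
and flags any window where more than 2 % of its B-specific sites carry
the B allele (heterozygous or homozygous) in at least one individual of
the population. Overlapping flagged windows merge into maximal candidate
regions. Stage two tiles each candidate with non-overlapping 1-kb windows
on the absolute 1-kb grid and labels each window per individual by its
dominant genotype — B-dominant when het + homB calls form a strict
majority of the window's informative sites, A-dominant when homA calls
do, uninformative on ties or when empty. Maximal runs of B-dominant
windows become tracts; borders sit on the window edges flanking the run.
Emitted tracts must be longer than 10 kb and hold at least five
B-carrying sites.

Three design choices here were genuinely open:

* **1-kb windows tile rather than slide.** Border definition by
  dominant-genotype transitions is only well-posed with non-overlapping
  windows; a sub-window step would create ambiguous overlapping labels.
* **Uninformative gaps are bridged up to 5 kb.** At 1.44 % divergence
  (half of it B-specific after polarization) a 1-kb window holds ~7
  B-specific sites on average, but spacing is Poisson: sporadic empty or
  tied windows inside a true tract are expected, and terminating runs at
  every empty window would shatter tracts. An A-dominant window always
  terminates a run regardless of gap length.
* **The five-site minimum applies per tract, not per 1-kb window.** A
  per-window reading would demand ≥ 5 sites/kb, i.e. triple the expected
  diagnostic density, and would contradict the separate 10-kb length
  filter; the per-region reading is the coherent one. A flag switches the
  strict per-window variant on for sensitivity analyses.

Population-level introgression sites are unions of per-individual tracts,
and cross-population sharing counts a tract as shared when it overlaps a
tract of the other population by ≥ 1 bp.

# Sliding-window statistics

Average heterozygosity per window is the unbiased per-site expected
heterozygosity summed over segregating validated sites,

$$\hat h = \frac{1}{V}\sum_{i=1}^{S} \frac{n\,(1 - \sum_j x_{ji}^2)}{n-1},$$

with $n$ the number of sampled chromosomes, $x_{ji}$ the sample frequency
of allele $j$ at segregating site $i$, and $V$ the validated-site count.
The site term equals the mean pairwise difference over all chromosome
pairs exactly, which the test suite asserts against an independent
pairwise enumeration. $n$ is fixed at twice the number of individuals
when no genotypes are missing and is computed per site otherwise; windows
with zero validated sites are flagged undefined (`NA`), never zero.

**Denominators.** The per-bp magnitudes (~10⁻³) require counting
invariant validated positions, not just variant records. With
`denominator = "callable"` the window denominator is window length ×
`callable_fraction`, where the callable fraction is the probability that
a position passes the coverage band in all individuals (the simulator
reports its analytic value; for real data it would come from per-bp BAM
coverage). `denominator = "masked_sites"` divides by masked variant
records instead, for SNP-level summaries. This is an interpretation
point: the source procedure counts "validated nucleotide sites", and the
callable-fraction route reproduces the printed per-nucleotide scale.

The exact Mann–Whitney U test enumerates all $\binom{n_1+n_2}{n_1}$ label
assignments with mid-ranks for ties and reports
$P(|U - n_1n_2/2| \ge |U_{obs} - n_1n_2/2|)$. No normal approximation is
used anywhere — the target regime is $n_1 = n_2 = 4$, where the smallest
achievable two-sided p-value is $2/70 \approx 0.02857$.

# In silico reduced-representation sequencing

The capture model assumes perfect sequencing: every conserved restriction
site (RAD) or size-selected fragment (ddRAD) is sequenced at full depth.
Restriction sites whose footprint overlaps any fixed interspecific
difference are discarded, since allele-specific cutting makes them
uninformative. Scanning runs on the forward strand only; the default
enzymes (SbfI `CCTGCAGG`, EcoRI `GAATTC`, MspI `CCGG`, SphI `GCATGC`) are
palindromic, so the forward scan is strand-complete (asserted in tests).

RAD capture intervals model 2 × 100 bp paired-end reads: 100 bp on each
side of the footprint, plus the two 100-bp mate footprints whose *near*
edge lies 400 bp from the site. The far-edge reading (mate spans 300–400
bp away) differs by 100 bp and is available by changing `far_offset`.
ddRAD fragments must be bounded by one cut site of each enzyme, contain
no internal site of either (a size-selected library cannot hold
internally cut fragments), and have footprint-to-footprint length within
300 ± 36 bp; capture covers 100 bp inward from both fragment ends. Cut
offsets within recognition sites are ignored — at 100-bp read scale the
≤ 6 bp shift is immaterial.

# LD decay around a tract

Marker pairs from phased haplotypes yield $D = p_{AB} - p_A p_B$
normalized by its frequency-bound maximum and reported as $|D'|$; the
absolute value is required because the decay model
$D' = (1-\theta)^t$ lives on $[0, 1]$. Genetic distances come from the
definite integral of a Loess curve (span 0.3, degree 2, rate floored at
zero) fitted to recombination-rate observations in cM/Mb, integrated by
the trapezoid rule on a 1-kb grid — deterministic, additive, and accurate
to ~10⁻⁶ relative against adaptive quadrature. The recombination fraction
is taken as $\theta = d_{cM}/100$ capped at 0.5; for the ≤ 5 cM pairs
used in fitting, the Haldane correction would change θ by < 5 % and is
off by default (flag `haldane = TRUE` enables it). The fit is unweighted
Levenberg–Marquardt nonlinear least squares with $t \ge 0$; the 95 %
confidence band is asymptotic from the parameter covariance. Degenerate
inputs with all $D' = 1$ pin $t = 0$ and are flagged rather than fitted.

Amplicon-style SNP filtering before LD analysis retains markers with
depth strictly above 20 in all individuals (the amplicon convention,
deliberately different from the inclusive WGS band), single-nucleotide
biallelic records only, minor allele in at least two individuals, and
Hardy–Weinberg exact $p \ge 0.05$. The HWE test is the conditional-on-
allele-count exact test; its p-value sums the probabilities of all
heterozygote counts no more likely than the observed one. Singleton and
HWE exclusion commute, so their order does not affect the retained set.

# Interallelic Ka/Ks

The two phased coding haplotypes of a heterozygous individual are
reconstructed from the reference CDS and the individual's variants;
codons overlapping indel or multi-nucleotide records are masked, a
terminal stop codon is excluded from counting, and codons holding two or
more heterozygous SNPs *require* phase — reconstruction refuses to guess.
Synonymous/nonsynonymous site counts use the first haplotype by default
(the symmetric average is a flag; at interallelic divergence of ~1.4 %
the difference is immaterial, and the difference counts are symmetric
either way). Multi-difference codons average over all shortest mutational
pathways, excluding paths through stop codons; mutations *to* stop codons
count as nonsynonymous in site counting. Proportions are corrected with
Jukes–Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$, undefined (flagged) at
$p \ge 3/4$ — note a single-codon toy comparison can legitimately land
there. $K_s = 0$ with $K_a > 0$ reports the ratio as infinite (the
literal string `inf` in tabular output). The test of $K_a/K_s = 1$ is a
one-sided large-sample Z test on $p_N - p_S$ with binomial variances — a
documented approximation of the codon-based test in standard
phylogenetics software, adequate at the gene sizes involved.

# The synthetic-data generator

`simulate_bundle()` emulates the statistical structure the analysis
assumes, not sequence evolution in full:

* **Divergence.** Infinite-sites substitutions at per-bp probability
  0.0144 between the species, each assigned to the A or B lineage with
  probability ½, with the reference sequence carrying the ancestral
  state. No back mutation; the analysis only consumes biallelic fixed
  differences, so coalescent machinery would add nothing testable.
* **Outgroup.** Private substitutions on the outgroup branch (default
  0.01/bp, configurable) make polarization non-trivial and generate the
  third-allele and wrong-polarity cases the scan must drop.
* **Polymorphism.** Within-population heterozygosity is modeled as sites
  at rate 2π per bp with haplotype allele frequency ½, giving an expected
  per-individual heterozygous-site proportion of π and panel ĥ of π. The
  defaults π = 1.5×10⁻³ (focal) and 3.1×10⁻³ (anadromous-like comparison)
  reproduce the empirical regime the method was designed for.
* **Tracts.** Planted intervals place species-B alleles on one (het) or
  both (hom) haplotypes of named carriers at every divergence site inside
  the interval. Overlapping tracts with conflicting zygosity for the same
  carrier are rejected.
* **Coverage.** Depth per site per individual is round(Normal(60, 15))
  clipped at zero, with a dropout fraction forced below 20 to exercise
  the coverage filter; the analytic callable fraction
  $((1-\text{dropout})\,P(20 \le \text{depth} \le 200))^{k}$ for $k$
  individuals is reported with the bundle.
* **Determinism.** All randomness flows from one seed through R's
  generator in a fixed draw order; identical configurations give
  bit-identical bundles.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linked genealogies and background LD,
mapping artifacts and paralog collapse, genotyping error correlated with
depth, indel-rich regions (indels/MNPs are generated only at low optional
rates to exercise the amplicon filters), recombination within planted
tracts, and reference bias. The tract-recovery results (recall and
precision 1 with ≤ 1 kb border error on noise-free 10-Mb genomes with six
planted tracts of 15–450 kb) certify the window/border logic, not
robustness to those real-data pathologies.

The LD verification uses a separate Wright–Fisher-style haplotype
simulation (in the test helpers): standing variation drifts for ~150
generations, then a fully coupled donor haplotype enters the tract zone
at frequency 0.3 and recombines for ~8 generations — reproducing the
qualitative signature that decay fitted *within* the tract gives a much
smaller $t$ than outside it.

# Problem sizes and numerical notes

The shipped test suite runs the full scan on a 10-Mb single-chromosome
genome (~300k variant records, 30 individuals), the ĥ oracle on 1,000
sites, the capture oracle on 50-kb sequences, 200 decay-fit replicates at
100 pairs each, and exhaustive codon-pair and small-sample exact-test
enumerations; the whole suite completes in about a minute on one CPU.
Window anchoring is at position 0 of each chromosome with terminal
partial windows reported at their actual denominators. Internally all
coordinates are 1-based inclusive (the R and VCF convention), converted
to 0-based half-open only at BED boundaries — a deliberate departure from
a 0-based-internal design, traded for idiomatic R indexing and covered by
round-trip tests. Exact-test p-values use a 10⁻⁹ relative tolerance when
comparing point probabilities to guard against floating-point ties.

# Known limitations

* The scan is rule-based: no posterior probabilities, no explicit model
  of genotyping error. A single mislabeled panel individual can suppress
  many diagnostic sites (fixity is absolute).
* Tract borders are resolved to the 1-kb grid, never finer.
* The method cannot statistically distinguish introgression from
  incomplete lineage sorting; polarization plus tract-length arguments
  make the case qualitatively.
* The Ka/Ks significance test is a large-sample approximation; for very
  short genes an exact or bootstrap test would be preferable.
* `run_pipeline()` consumes in-memory bundles; very large cohorts would
  need chunked I/O that this package does not provide.
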