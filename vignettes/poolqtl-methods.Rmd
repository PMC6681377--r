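---
title: "Pool-based QTL discovery in backcross hybrids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-based QTL discovery in backcross hybrids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Interspecific kiwifruit hybrids between *Actinidia chinensis* and the
high-vitamin-C species *A. eriantha* segregate bimodally for fruit ascorbate
(AsA, mg/100 g fresh weight), the signature of a dominant major gene. In a
polyploid, highly heterozygous background, individual genotyping is
impractical, so the locus is mapped by sequencing pooled DNA of phenotypic
extremes: four pools of 20 vines arranged as a 2x2 design of AsA (high/low)
by fruit weight (high/low), the second trait being uncorrelated with the
first. The orthogonal design yields *replicated* contrasts: each trait can
be tested within the two strata of the other, and the fruit-weight scan
doubles as a negative control.

The donor haplotype carrying the QTL sits in a terminal block with strongly
suppressed recombination, so the entire block is transmitted as one
Mendelian unit — a supergene. `poolqtl` implements every stage of this
design as testable code on synthetic data: cohort and pool simulation,
pooled counts in Popoolation2 sync format, site filtering and coverage
resampling, the replicated Cochran-Mantel-Haenszel (CMH) scan, QTL-seq
bulked-segregant analysis (BSA) with a tetraploid-backcross population
model, allele-of-origin expression fingerprinting, and the marker-validation
and metabolite statistics.

## Population and genome model

The simulated cohort is a tetraploid backcross: each individual carries the
donor block with probability 1/2 (1:1 segregation), and a carrier bears the
donor haplotype on one of four homologues, so a carrier's chromatids are
donor at fraction 0.25 (`donor_dosage_fraction`; 0.5 would describe a
diploid heterozygote). Tetraploid meiosis is not modelled mechanistically;
carrier status plus this dosage fraction is the contract, which reproduces
the key expectation that a bulk composed entirely of carriers has donor
allele frequency 0.25 at linked sites, and a non-carrier bulk 0.

Recombination is modelled as a 0/free dichotomy: zero inside the suppressed
block (all block SNPs share one genotype draw per pool) and free between all
other SNPs (an independent `Binomial(pool size, 1/2)` carrier draw per site
and pool). The data demonstrate suppression but provide no rate, and this is
the simplest structure exhibiting the observed step-shaped allelic
expression profile. Coordinates are 1-based inclusive everywhere, matching
the sync convention.

The canonical scenario (`asa_scenario()`) uses 29 chromosomes of 20 Mbp with
200 evenly spaced donor-diagnostic SNPs each, a suppressed block across
chr26:1-10 Mbp, the QTL at 7.6 Mbp, and an AsA effect of 250 mg/100 g FW.
Chromosome length and SNP density are package choices at a desk scale that
keeps a full scan under a minute; the block location, QTL position, pool
design and effect size are the study conditions being emulated.

## Trait generation

Trait 1 (AsA) is normal within genotype class with the QTL effect added to
carriers; trait 2 (fruit weight) is a single normal independent of carrier
status; families shift trait 1 by a normal deviate. The default preset
(`trait_preset_asa()`) places non-carriers at 93.7 +/- 32.8 and uses a wider
carrier SD (58.3), chosen so that median-split pools reproduce the reference
pool phenotype summaries (high-AsA pools near 386-434, low near 87-100
mg/100 g FW; fruit-weight pools near 96 g and 57-60 g). Pool allocation is
deterministic rank selection: top and bottom 2n by trait 1, each split by
trait 2 rank.

## Sequencing model

Read depth per pool and site is Poisson with configurable mean (default 40,
matching the coverage-normalisation target). Donor reads are binomial at the
pool's true donor frequency, and a fraction `error_rate` of reads (default
0.001) is redistributed uniformly over the other three nucleotides. Pools
are treated as exactly equimolar — within-pool DNA normalisation noise is
not modelled, as no estimate of it is available. No read-level (FASTQ)
structure, mapping bias or indel process is simulated; consequently,
passing tests show that the *statistics* behave as designed under the
assumed sampling model, not that they are robust to alignment artefacts of
real pool-seq data.

## Site filters and resampling

`filter_sites()` keeps sites where at least two nucleotides reach the
`min_count` floor (6) summed over pools and every pool's depth is within
`[min_coverage, max_coverage]` (4 and 120 by default; the source protocol
used both 120 and 200 as maxima, so the maximum accepts a per-pool vector).
The allele-count rule is applied to sums over pools (Popoolation2
semantics). N and deletion reads count toward depth but never form the
tested allele pair, because the CMH test operates on a biallelic nucleotide
contrast. `resample_counts()` draws with replacement to a uniform target
depth; note that resampling *adds* multinomial noise on top of the original
read sampling, which visibly widens the null of downstream tests — the
discovery scan in `analysis/02_cmh_scan.R` therefore runs on non-resampled
counts, with the normalised variant written alongside for comparison.

## The replicated CMH scan

At each site the two most frequent nucleotides (ties broken A < C < G < T)
form a 2x2 table per stratum: high-contrast pool vs low-contrast pool by
major vs minor allele. The statistic is

    chi2 = (|sum_k (a_k - E a_k)| - c)^2 / sum_k Var(a_k)

with hypergeometric conditional moments per stratum and a chi-square
reference with 1 df; the continuity correction `c` defaults to off,
matching the pooled-GWAS convention. With one stratum this is the classical
2x2 chi-square (with the (n-1)/n variance convention). The
Mantel-Haenszel common odds ratio `sum(a d / n) / sum(b c / n)` is reported
per site, `NA` when its denominator vanishes, and BH adjustment is applied
genome-wide across all retained sites.

One calibration subtlety is worth knowing. Under a pure read-sampling null
(the same true allele frequency in every pool) the test holds its size:
type-I error at alpha = 0.05 stays within [0.04, 0.06] at 40x. In a
segregating population, however, an unlinked site's pool frequencies also
fluctuate by genotype sampling (`Binomial(20, 1/2)` carriers per pool),
which the conditional variance does not see; the genome-wide null is
therefore mildly over-dispersed, and an occasional off-target site can
reach small adjusted p-values. This is a property of pool-based CMH scans
generally, and the reason the scan's conclusions rest on the extreme,
block-wide signal rather than single borderline sites.

## Bulked-segregant analysis with the BC4x model

Standard QTL-seq supports F2 and RIL populations; neither describes a
tetraploid backcross, so the bulk-frequency simulation is extended with a
`BC4x` type: expected donor allele frequency 0 in the non-carrier bulk and
0.25 in the carrier bulk, 1:1 segregation. Selection on the dominant trait
is assumed perfect (complete penetrance), so a linked carrier bulk has zero
genotype-sampling variance; misclassification is not modelled.

Per site and bulk the SNP-index is `alt / (ref + alt)`; the statistic is
the difference (delta) between high and low bulks, smoothed with a tricube
kernel `w(u) = (1 - |u|^3)^3` over SNP positions within half a 1-Mbp window
(the QTL-seq convention of evaluating at SNPs rather than fixed tiles).
The null is simulated in two stages — genotype sampling of each bulk, then
binomial reads at the site depth — with 10,000 bootstrap replicates per
depth, and each SNP's smoothed delta receives an empirical two-sided
p-value against the same tricube combination of resampled null site deltas.

Two numerical choices matter here. First, the empirical p-value is the
plug-in estimator `mean(|null| >= |obs|)`, whose resolution is 1/reps; the
add-one variant would floor p at 1/(reps+1), and after genome-wide BH
adjustment across ~5,800 SNPs no site could then reach an FDR of 0.001 with
10,000 replicates — the plug-in estimator lets a signal that exceeds every
null replicate be called at any FDR. Second, because a plug-in zero can
also arise by multiplicity somewhere in a genome scan, reported intervals
must comprise at least `min_snps` (5) significant SNPs, allow internal gaps
of at most one window, and span more than `min_span` (two windows): the
kernel propagates a single cluster of extreme null deltas over at most
about one window of positions, whereas a genuine selected region stays
significant across many windows. With these rules, null-effect simulations
yield no intervals in the large majority of runs, while the suppressed
block is recovered as a single interval by both bulk pairings.

One caveat is inherited from the linkage model rather than the calling
rule: under a null *effect*, the suppressed block still segregates as one
unit, so all its SNPs share one genotype draw per pool. A rare extreme draw
(roughly 1-2% of runs) elevates the whole block coherently and is then
indistinguishable from a true signal — a genuine property of supergene
linkage, not an artefact.

BH adjustment is applied per scan across all SNPs (the per-SNP reading of
the ambiguous published description; window-level merging happens after).

## Allelic-expression fingerprinting

Homeo-SNPs — fixed differences between the two parental species — assign
per-site counts to species of origin; anything other than the two indexed
alleles is ambiguous, and counts are conserved. Assignment operates on
count tables rather than reads (the read-level tool it mirrors splits BAM
files; at count level the expectations are identical, which is the
documented divergence). Gene-level donor proportions are computed on
informative counts only. `detect_introgression()` reports runs of at least
`min_genes` (5) consecutive informative genes with donor proportion at
least `tau_present` (0.2) in carriers and at most `tau_absent` (0.02) in
non-carriers: the two thresholds separate heterozygous expression (about
0.5, possibly biased) from error-rate leakage. The magnitude of allelic
expression bias in carriers is not quantified upstream, so it is a free
simulator parameter (`bias`, default 0.5).

## Marker validation and metabolite contrasts

`two_way_anova()` decomposes trait variance sequentially (type-I) with
marker dosage entered first — matching the convention in which the marker
share is quoted before the family share — and reports percent variance,
F tests and a per-allele effect estimate; an option reverses the entry
order. Putative recombinants are individuals whose studentised residual
exceeds `z_cut` (2.5) *and* whose trait lies inside the opposite dosage
class's range (computed from non-outlying individuals); the source analysis
names no rule beyond "residual analysis", so this rule is this package's
explicit choice, tuned to flag phenotype-genotype discordance rather than
mere noise.

`metab_contrast()` follows the reported table arithmetic exactly: group
areas are arithmetic means of raw areas, the ratio is the ratio of group
means (not the mean of per-sample ratios), the fold change is log2 of that
ratio, and printed values are rounded to two decimals with halves away from
zero. The p-value is a two-sided Welch t-test on log areas. The same
function serves two-group trait comparisons such as leaf AsA by genotype
class.

## Problem sizes and reproducibility

The analysis scripts and the acceptance tests run the canonical scenario:
29 x 200 SNPs, 4 x 20 pools at 40x, 10,000 BSA bootstraps — about half a
minute per scan on one core. Unit tests use smaller genomes (2-8
chromosomes, 30-100 SNPs) and explicit seeds throughout; every simulation
function takes a `seed` argument and is byte-reproducible under it. Null
calibrations (CMH type-I error, BSA null centring) use 10,000 replicates.

## Known limitations

- No read-level simulation, mapping bias, or variant-calling error model.
- The 0/free recombination dichotomy ignores partial recombination at the
  block boundary; interval edges are only resolved to about one window.
- Pool DNA is exactly equimolar; individual contribution variance is not
  modelled.
- The CMH genome-wide null is over-dispersed by genotype sampling (see
  above); no overdispersion correction is applied, by design fidelity.
- Differential-expression testing of the transcriptome data is out of
  scope; only allele-of-origin proportions are produced.
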