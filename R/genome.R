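#' Genome model for pooled-sequencing simulations
#'
#' Describes the chromosomes, the positions of donor-diagnostic SNPs (fixed
#' differences between the donor and recipient species), and an optional
#' recombination-suppressed block that is inherited as a single unit.
#' Coordinates are 1-based and inclusive throughout, matching the sync
#' file convention.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param snp_positions named list (one element per chromosome) of strictly
#'   increasing integer positions of donor-diagnostic SNPs.
#' @param suppressed_block `NULL`, or a list with elements `chrom`, `start`,
#'   `end` giving the interval (bp, inclusive) transmitted without
#'   recombination.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, snp_positions, suppressed_block = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names in 'chromosomes'")
  if (!all(chromosomes$length >= 1))
    stop("chromosome lengths must be >= 1")
  if (!all(names(snp_positions) %in% chromosomes$name))
    stop("'snp_positions' names must match chromosome names")
  for (ch in names(snp_positions)) {
    p <- snp_positions[[ch]]
    if (length(p) && (any(p < 1) || is.unsorted(p, strictly = TRUE)))
      stop("SNP positions on ", ch, " must be >= 1 and strictly increasing")
    len <- chromosomes$length[chromosomes$name == ch]
    if (length(p) && max(p) > len)
      stop("SNP positions on ", ch, " exceed chromosome length")
  }
  if (!is.null(suppressed_block)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(suppressed_block)))
    if (!suppressed_block$chrom %in% chromosomes$name)
      stop("suppressed_block chromosome not in genome")
    len <- chromosomes$length[chromosomes$name == suppressed_block$chrom]
    if (suppressed_block$start < 1 || suppressed_block$end > len ||
        suppressed_block$start > suppressed_block$end)
      stop("suppressed_block must lie within its chromosome")
  }
  structure(list(chromosomes = chromosomes,
                 snp_positions = snp_positions,
                 suppressed_block = suppressed_block),
            class = "genome_model")
}

#' QTL model
#'
#' A single major locus with a dominant effect carried on a donor haplotype.
#' `donor_dosage_fraction` is the fraction of chromatids in a carrier that
#' bear the donor allele: 0.25 for a tetraploid backcross carrier with the
#' donor haplotype on one of four homologues, 0.5 for a diploid heterozygote.
#'
#' @param chrom,pos location of the locus.
#' @param effect trait units added to carriers (dominant: carrier status, not
#'   dosage, sets the effect).
#' @param donor_dosage_fraction fraction of carrier chromatids bearing the
#'   donor allele; must be in (0, 0.5].
#' @param seg_ratio expected carrier frequency among progeny (1:1 segregation
#'   by default).
#' @return An object of class `qtl_model`.
#' @export
qtl_model <- function(chrom, pos, effect = 250, donor_dosage_fraction = 0.25,
                      seg_ratio = 0.5) {
  if (!(donor_dosage_fraction > 0 && donor_dosage_fraction <= 0.5))
    stop("'donor_dosage_fraction' must be in (0, 0.5]")
  if (!(seg_ratio > 0 && seg_ratio < 1))
    stop("'seg_ratio' must be in (0, 1)")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 effect = effect, dominance = TRUE,
                 donor_dosage_fraction = donor_dosage_fraction,
                 seg_ratio = seg_ratio),
            class = "qtl_model")
}

#' Canonical high-ascorbate backcross scenario
#'
#' Convenience constructor for the package's reference simulation: a genome of
#' `n_chrom` chromosomes carrying evenly spaced donor-diagnostic SNPs, with a
#' recombination-suppressed terminal block on one chromosome harbouring a
#' dominant QTL. Defaults follow the kiwifruit setting: 29 chromosomes, a
#' suppressed block spanning the first 10 Mbp of chromosome 26, the QTL at
#' 7.6 Mbp inside it, a trait effect of 250 (mg/100 g FW semantics), and a
#' tetraploid-backcross donor dosage of 0.25.
#'
#' The QTL position is always included among the SNP positions of its
#' chromosome so that pooled counts can be simulated at the selected locus.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length common chromosome length in bp.
#' @param snps_per_chrom number of diagnostic SNPs per chromosome.
#' @param qtl_chrom,qtl_pos QTL location.
#' @param block_start,block_end suppressed block interval on `qtl_chrom`.
#' @param effect,donor_dosage_fraction,seg_ratio passed to [qtl_model()].
#' @return list with elements `genome` ([genome_model]) and `qtl`
#'   ([qtl_model]).
#' @export
asa_scenario <- function(n_chrom = 29, chrom_length = 2e7, snps_per_chrom = 200,
                         qtl_chrom = "chr26", qtl_pos = 7.6e6,
                         block_start = 1, block_end = 1e7,
                         effect = 250, donor_dosage_fraction = 0.25,
                         seg_ratio = 0.5) {
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = chrom_length)
  pos <- round(seq(chrom_length / (2 * snps_per_chrom), chrom_length,
                   length.out = snps_per_chrom))
  snps <- stats::setNames(rep(list(as.integer(pos)), n_chrom), chroms$name)
  if (!qtl_chrom %in% chroms$name) stop("'qtl_chrom' not in genome")
  qp <- as.integer(qtl_pos)
  if (!qp %in% snps[[qtl_chrom]])
    snps[[qtl_chrom]] <- sort(unique(c(snps[[qtl_chrom]], qp)))
  g <- genome_model(chroms, snps,
                    suppressed_block = list(chrom = qtl_chrom,
                                            start = block_start,
                                            end = block_end))
  q <- qtl_model(qtl_chrom, qp, effect = effect,
                 donor_dosage_fraction = donor_dosage_fraction,
                 seg_ratio = seg_ratio)
  list(genome = g, qtl = q)
}

# is position pos on chromosome ch inside the suppressed block?
.in_block <- function(genome, ch, pos) {
  b <- genome$suppressed_block
  if (is.null(b)) return(rep(FALSE, length(pos)))
  ch == b$chrom & pos >= b$start & pos <= b$end
}
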