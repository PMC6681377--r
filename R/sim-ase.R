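#' Simulate per-gene allele-of-origin expression counts
#'
#' Places `n_genes` equal-width genes along the chromosome carrying the
#' suppressed block (the introgression) and draws, for one sample group,
#' gene-level read counts split by species of origin. Genes inside the
#' introgression in a carrier group express the donor allele with proportion
#' `bias` (0.5 for unbiased heterozygous expression); genes outside the
#' introgression, and all genes in non-carrier groups, receive donor reads
#' only at `error_rate`.
#'
#' @param genome a [genome_model] with a suppressed block (the introgression).
#' @param carrier does the group carry the donor introgression?
#' @param n_genes number of genes (0 returns an empty profile).
#' @param bias donor expression proportion inside the introgression in
#'   carriers (0 <= bias <= 1).
#' @param depth_mean mean informative read count per gene (Poisson).
#' @param error_rate donor-read leakage rate outside the introgression.
#' @param seed optional integer seed.
#' @return data.frame as from [gene_proportions()] (`gene_id`, `chrom`,
#'   `start`, `end`, counts, `proportion_b`, `informative`).
#' @export
simulate_ase_counts <- function(genome, carrier, n_genes, bias = 0.5,
                                depth_mean = 200, error_rate = 0,
                                seed = NULL) {
  if (bias < 0 || bias > 1) stop("'bias' must be in [0, 1]")
  if (is.null(genome$suppressed_block))
    stop("genome has no suppressed block (introgression) defined")
  if (n_genes == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), count_a = integer(),
                      count_b = integer(), count_ambiguous = integer(),
                      proportion_b = numeric(), informative = logical()))
  if (!is.null(seed)) set.seed(seed)
  b <- genome$suppressed_block
  len <- genome$chromosomes$length[genome$chromosomes$name == b$chrom]
  bounds <- round(seq(1, len, length.out = n_genes + 1))
  start <- bounds[-(n_genes + 1)]
  end <- pmax(start, bounds[-1] - 1)
  mid <- (start + end) / 2
  inside <- mid >= b$start & mid <= b$end
  p_donor <- ifelse(carrier & inside, bias, error_rate)
  depth <- stats::rpois(n_genes, depth_mean)
  count_b <- stats::rbinom(n_genes, depth, p_donor)
  out <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                    chrom = b$chrom, start = as.integer(start),
                    end = as.integer(end), count_a = depth - count_b,
                    count_b = count_b, count_ambiguous = 0L,
                    stringsAsFactors = FALSE)
  out$proportion_b <- ifelse(depth > 0, out$count_b / depth, NA_real_)
  out$informative <- depth > 0
  out
}
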