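#' Simulate pooled sequencing counts in sync form
#'
#' Generates per-pool nucleotide counts at every donor-diagnostic SNP of the
#' genome. Inside the recombination-suppressed block containing the QTL, each
#' pool's donor-allele frequency is fixed at
#' `carriers_in_pool * donor_dosage_fraction / pool_size` (the block is
#' inherited as one unit, so it is constant across all block SNPs for a given
#' pool). Elsewhere, sites recombine freely: the number of donor-segment
#' carriers in a pool is drawn independently per site as
#' `Binomial(pool_size, seg_ratio)`, regardless of QTL carrier status. Read
#' depth is Poisson (or fixed) per pool and site; donor reads are binomial at
#' the pool frequency; a fraction `error_rate` of reads is redistributed
#' uniformly over the three other nucleotides.
#'
#' @param pools a [construct_pools()] design.
#' @param cohort the cohort the pools were drawn from.
#' @param genome a [genome_model]; the QTL locus must be among its SNP
#'   positions.
#' @param qtl a [qtl_model].
#' @param depth_mean mean read depth per pool (> 0).
#' @param depth_dist `"poisson"` (default) or `"fixed"`.
#' @param error_rate per-read base error probability (0 <= e < 0.05).
#' @param seed optional integer seed.
#' @return a [sync] object with attributes `sites` (data.frame `chrom`,
#'   `pos`, `ref`, `alt`, `linked` — `alt` is the donor-diagnostic allele),
#'   `freq` (sites x pools matrix of true donor-allele frequencies before
#'   read sampling) and `carriers` (QTL carriers per pool).
#' @export
simulate_pool_counts <- function(pools, cohort, genome, qtl, depth_mean = 40,
                                 depth_dist = c("poisson", "fixed"),
                                 error_rate = 0.001, seed = NULL) {
  depth_dist <- match.arg(depth_dist)
  if (depth_mean <= 0) stop("'depth_mean' must be > 0")
  if (error_rate < 0 || error_rate >= 0.05)
    stop("'error_rate' must be in [0, 0.05)")
  snp_chrom <- rep(names(genome$snp_positions),
                   lengths(genome$snp_positions))
  snp_pos <- unlist(genome$snp_positions, use.names = FALSE)
  if (!any(snp_chrom == qtl$chrom & snp_pos == qtl$pos))
    stop("QTL locus ", qtl$chrom, ":", qtl$pos,
         " is not among the genome's SNP positions")
  if (!is.null(seed)) set.seed(seed)

  S <- length(snp_pos)
  pool_ids <- pools$pools$pool
  P <- length(pool_ids)
  sizes <- vapply(pools$members, length, 1L)
  carriers <- vapply(pools$members, function(ids)
    sum(cohort$carrier[match(ids, cohort$id)]), 1L)

  ref <- sample(NUC4, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(NUC4, r), 1), "")
  linked <- .in_block(genome, snp_chrom, snp_pos)

  ddf <- qtl$donor_dosage_fraction
  freq <- matrix(0, S, P, dimnames = list(NULL, pool_ids))
  for (p in seq_len(P)) {
    f <- stats::rbinom(S, sizes[p], qtl$seg_ratio) * ddf / sizes[p]
    f[linked] <- carriers[p] * ddf / sizes[p]
    freq[, p] <- f
  }

  depth <- if (depth_dist == "poisson") {
    matrix(stats::rpois(S * P, depth_mean), S, P)
  } else matrix(as.integer(round(depth_mean)), S, P)
  alt_reads <- matrix(stats::rbinom(S * P, depth, freq), S, P)
  ref_reads <- depth - alt_reads

  # lookup: for each nucleotide (sync base index), the other three nucleotides
  others <- t(vapply(NUC4, function(b) match(setdiff(NUC4, b), BASES6),
                     integer(3)))
  ri <- match(ref, BASES6)
  ai <- match(alt, BASES6)

  counts <- array(0L, dim = c(S, 6, P))
  add <- function(site, base, pool, value) {
    idx <- site + (base - 1L) * S + (pool - 1L) * (S * 6L)
    counts[idx] <<- counts[idx] + value
  }
  spread_errors <- function(n_err, from_base, pool) {
    e1 <- stats::rbinom(S, n_err, 1 / 3)
    e2 <- stats::rbinom(S, n_err - e1, 1 / 2)
    e3 <- n_err - e1 - e2
    add(seq_len(S), others[from_base, 1], pool, e1)
    add(seq_len(S), others[from_base, 2], pool, e2)
    add(seq_len(S), others[from_base, 3], pool, e3)
  }
  for (p in seq_len(P)) {
    if (error_rate > 0) {
      err_ref <- stats::rbinom(S, ref_reads[, p], error_rate)
      err_alt <- stats::rbinom(S, alt_reads[, p], error_rate)
    } else {
      err_ref <- err_alt <- integer(S)
    }
    add(seq_len(S), ri, p, ref_reads[, p] - err_ref)
    add(seq_len(S), ai, p, alt_reads[, p] - err_alt)
    if (error_rate > 0) {
      spread_errors(err_ref, ri, p)
      spread_errors(err_alt, ai, p)
    }
  }

  out <- sync(snp_chrom, snp_pos, ref, counts, pool_ids)
  attr(out, "sites") <- data.frame(chrom = snp_chrom, pos = snp_pos,
                                   ref = ref, alt = alt, linked = linked,
                                   stringsAsFactors = FALSE)
  attr(out, "freq") <- freq
  attr(out, "carriers") <- carriers
  out
}
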