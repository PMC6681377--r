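#' Filter sync sites on allele count and coverage
#'
#' Applies the Popoolation2-style site filters used ahead of the CMH scan:
#' a site is kept when (i) at least two of the four nucleotides reach
#' `min_count` reads summed over all pools, and (ii) every pool's total depth
#' lies within `[min_coverage, max_coverage]`. N and deletion reads count
#' toward depth but never form the tested allele pair. The operation is total
#' (no errors) and idempotent.
#'
#' @param x a [sync] object.
#' @param min_count allele-count floor summed over pools (default 6).
#' @param min_coverage per-pool minimum depth (default 4).
#' @param max_coverage per-pool maximum depth; a scalar, or a vector with one
#'   value per pool (the source protocol used 120 for some pools and 200 for
#'   others).
#' @return the filtered [sync] object.
#' @export
filter_sites <- function(x, min_count = 6, min_coverage = 4, max_coverage = 120) {
  if (any(min_coverage > max_coverage))
    stop("'min_coverage' must be <= 'max_coverage'")
  npool <- length(x$pools)
  maxc <- rep_len(max_coverage, npool)
  minc <- rep_len(min_coverage, npool)
  tot <- sync_totals(x)[, NUC4, drop = FALSE]
  biallelic <- rowSums(tot >= min_count) >= 2L
  dep <- sync_depth(x)
  cov_ok <- rowSums(dep >= rep(minc, each = nrow(dep)) &
                    dep <= rep(maxc, each = nrow(dep))) == npool
  sync_subset(x, which(biallelic & cov_ok))
}

#' Resample pooled counts to a uniform target depth
#'
#' Draws, for every pool at every site, `target` reads with replacement with
#' probabilities proportional to the observed counts (multinomial
#' resampling), so that all output depths equal `target` while expected
#' allele frequencies are preserved.
#'
#' @param x a [sync] object.
#' @param target target depth per pool (>= 1).
#' @param seed optional integer seed.
#' @return a [sync] object with every pool depth equal to `target`.
#' @export
resample_counts <- function(x, target = 40, seed = NULL) {
  if (target < 1) stop("'target' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dep <- sync_depth(x)
  if (any(dep == 0)) {
    bad <- which(dep == 0, arr.ind = TRUE)[1, ]
    stop("zero-depth pool '", x$pools[bad[2]], "' at ", x$chrom[bad[1]], ":",
         x$pos[bad[1]], " cannot be resampled")
  }
  out <- x$counts
  for (p in seq_along(x$pools)) {
    cm <- x$counts[, , p, drop = TRUE]
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1)
    out[, , p] <- t(apply(cm, 1, function(cc)
      stats::rmultinom(1, target, cc)[, 1]))
  }
  sync(x$chrom, x$pos, x$ref, out, x$pools)
}
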