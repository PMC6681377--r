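#' Population model for bulked-segregant analysis
#'
#' Encodes the expected donor-allele frequencies of the two bulks and the
#' carrier segregation ratio for the supported population types:
#' \describe{
#'   \item{F2}{1:2:1 genotype segregation, dosages \{0, 0.5, 1\}; a perfectly
#'     linked high bulk is fixed for the donor allele.}
#'   \item{RIL}{1:1 segregation of homozygotes, dosages \{0, 1\}.}
#'   \item{BC4x}{tetraploid backcross with a dominant donor haplotype on one
#'     of four homologues, 1:1 carrier segregation; expected bulk donor-allele
#'     frequencies are 0 (non-carrier bulk) and 0.25 (carrier bulk).}
#' }
#'
#' @param type one of `"F2"`, `"RIL"`, `"BC4x"`.
#' @return object of class `population_model`.
#' @export
population_model <- function(type = c("BC4x", "F2", "RIL")) {
  type <- match.arg(type)
  m <- switch(type,
    BC4x = list(type = "BC4x", bulk_freq = c(low = 0, high = 0.25),
                seg_ratio = 0.5, dosage = 0.25),
    F2   = list(type = "F2", bulk_freq = c(low = 0, high = 1),
                seg_ratio = 0.5, dosage = NA_real_),
    RIL  = list(type = "RIL", bulk_freq = c(low = 0, high = 1),
                seg_ratio = 0.5, dosage = NA_real_))
  structure(m, class = "population_model")
}

#' SNP-index of one bulk at one site
#'
#' The fraction of reads carrying the alternate (donor) allele,
#' `alt / (ref + alt)`. Zero-depth sites are undefined (`NA`).
#'
#' @param ref,alt reference and alternate read counts (vectorised).
#' @return numeric vector of proportions in `[0, 1]`, `NA` where depth is 0.
#' @export
snp_index <- function(ref, alt) {
  if (any(ref < 0 | alt < 0)) stop("read counts must be >= 0")
  ifelse(ref + alt > 0, alt / (ref + alt), NA_real_)
}

#' Simulate the donor-allele frequency of a bulk
#'
#' In the linked case (the site is the selection criterion) bulk composition
#' is deterministic: a BC4x carrier bulk has frequency exactly 0.25 and a
#' non-carrier bulk 0; F2/RIL high bulks are fixed for the donor allele. At a
#' null (unlinked) site the bulk's genotypes are drawn from the population's
#' segregation model: BC4x carriers `Binomial(bulk_size, 1/2)` each
#' contributing dosage 0.25; F2 genotype counts multinomial 1:2:1 with
#' dosages \{0, 0.5, 1\}; RIL `Binomial(bulk_size, 1/2)` with dosages
#' \{0, 1\}.
#'
#' @param model a [population_model].
#' @param bulk_size number of individuals in the bulk (>= 1).
#' @param linked is the site completely linked to the selected locus?
#' @param bulk `"high"` or `"low"`: which selected bulk (linked case only).
#' @param n number of independent draws.
#' @param seed optional integer seed.
#' @return numeric vector of length `n` of donor-allele frequencies.
#' @export
simulate_bulk_freq <- function(model, bulk_size, linked = FALSE,
                               bulk = c("high", "low"), n = 1, seed = NULL) {
  bulk <- match.arg(bulk)
  if (bulk_size < 1) stop("'bulk_size' must be >= 1")
  if (!inherits(model, "population_model")) stop("unknown population model")
  if (!is.null(seed)) set.seed(seed)
  if (linked) return(rep(unname(model$bulk_freq[bulk]), n))
  switch(model$type,
    BC4x = stats::rbinom(n, bulk_size, model$seg_ratio) * model$dosage / bulk_size,
    RIL  = stats::rbinom(n, bulk_size, 0.5) / bulk_size,
    F2   = {
      hom <- stats::rbinom(n, bulk_size, 0.25)
      het <- stats::rbinom(n, bulk_size - hom, 2 / 3)
      (hom + 0.5 * het) / bulk_size
    })
}

#' Simulate the null distribution of the delta SNP-index
#'
#' Per replicate, each bulk's donor-allele frequency is drawn under the null
#' (unlinked) genotype-sampling model, reads are drawn binomially at depth
#' `depth`, and the difference of the two bulks' SNP-indices is returned.
#' This is the two-stage (genotype sampling then read sampling) null used to
#' derive confidence thresholds.
#'
#' @param model a [population_model].
#' @param bulk_size individuals per bulk.
#' @param depth read depth per bulk (> 0).
#' @param reps number of replicates (>= 100; 10,000 by default).
#' @param seed optional integer seed.
#' @return numeric vector of `reps` null delta values.
#' @export
simulate_null_delta <- function(model, bulk_size, depth, reps = 10000,
                                seed = NULL) {
  if (depth <= 0) stop("'depth' must be > 0")
  if (reps < 100) stop("'reps' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  fh <- simulate_bulk_freq(model, bulk_size, linked = FALSE, n = reps)
  fl <- simulate_bulk_freq(model, bulk_size, linked = FALSE, n = reps)
  ih <- stats::rbinom(reps, depth, fh) / depth
  il <- stats::rbinom(reps, depth, fl) / depth
  ih - il
}

#' Simulated null thresholds for the delta SNP-index
#'
#' Runs [simulate_null_delta()] at each requested depth and stores both the
#' full null draws (used for empirical p-values in [call_qtl()]) and
#' two-sided quantile bands at the requested confidence levels.
#'
#' @param model a [population_model].
#' @param bulk_size individuals per bulk.
#' @param depths integer vector of depths to simulate.
#' @param reps replicates per depth (default 10,000).
#' @param levels confidence levels for the quantile bands.
#' @param seed optional integer seed.
#' @return object of class `threshold_table`: list with `depths`, `null`
#'   (reps x depths matrix), `bands` (data.frame of per-depth two-sided
#'   quantiles), `reps`, `model`, `bulk_size`.
#' @export
threshold_table <- function(model, bulk_size, depths, reps = 10000,
                            levels = c(0.95, 0.99), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depths <- sort(unique(as.integer(depths)))
  null <- vapply(depths, function(d)
    simulate_null_delta(model, bulk_size, d, reps), numeric(reps))
  probs <- sort(c((1 - levels) / 2, 1 - (1 - levels) / 2))
  qs <- t(apply(null, 2, stats::quantile, probs = probs, names = FALSE))
  bands <- data.frame(depth = depths, qs)
  names(bands) <- c("depth", sprintf("q%g", 100 * probs))
  structure(list(depths = depths, null = null, bands = bands, reps = reps,
                 model = model, bulk_size = bulk_size),
            class = "threshold_table")
}

# tricube row-normalised weight matrix over positions within +/- window/2
.tricube_weights <- function(pos, window) {
  h <- window / 2
  u <- abs(outer(pos, pos, "-")) / h
  w <- ifelse(u < 1, (1 - u^3)^3, 0)
  sweep(w, 1, rowSums(w), "/")
}

#' Tricube-windowed delta SNP-index
#'
#' Evaluates, at every SNP, the tricube-weighted mean of the per-site delta
#' over sites within half a window, `w(u) = (1 - |u|^3)^3` for
#' `|u| = distance / (window/2) < 1` (QTL-seq convention: the window slides
#' over SNP positions rather than fixed tiles, so no window is empty).
#'
#' @param records data.frame with columns `chrom`, `pos`, `delta`, sorted by
#'   position within chromosome.
#' @param window window size in bp (default 1 Mbp).
#' @return `records` with columns `delta_w` (windowed delta) and `n_w`
#'   (number of SNPs contributing) appended.
#' @export
windowed_delta <- function(records, window = 1e6) {
  stopifnot(all(c("chrom", "pos", "delta") %in% names(records)))
  out <- records
  out$delta_w <- NA_real_
  out$n_w <- NA_integer_
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    if (is.unsorted(records$pos[i]))
      stop("records must be sorted by position within chromosome (", ch, ")")
    W <- .tricube_weights(records$pos[i], window)
    out$delta_w[i] <- as.numeric(W %*% records$delta[i])
    out$n_w[i] <- as.integer(rowSums(W > 0))
  }
  out
}

#' Call QTL intervals from windowed delta SNP-indices
#'
#' For every SNP the tricube-windowed delta is referred to its null
#' distribution: null site deltas are resampled (per contributing site, at
#' the nearest simulated depth) from the [threshold_table()] draws and
#' combined with the same tricube weights, giving an empirical two-sided
#' p-value `mean(|null_w| >= |obs_w|)` with resolution `1/reps`. P-values are
#' BH-adjusted across all SNPs of the scan; significant SNPs separated by at
#' most `max_gap` bp are merged and reported as intervals when they comprise
#' at least `min_snps` SNPs and span more than `min_span` bp. The span
#' requirement
#' (default twice the window) discards single-window noise excursions: the
#' tricube kernel propagates one cluster of extreme site deltas over at most
#' about one window of positions, whereas a genuine QTL region under
#' selection stays significant across many windows.
#'
#' @param records data.frame with `chrom`, `pos`, `delta` and per-bulk depths
#'   `depth_high`, `depth_low`, sorted by position within chromosome.
#' @param thresholds a [threshold_table()] simulated under the matching
#'   population model and bulk size.
#' @param window window size in bp.
#' @param fdr BH false-discovery threshold (default 0.001).
#' @param min_snps minimum run of consecutive significant SNPs that
#'   constitutes an interval (default 5).
#' @param min_span minimum interval span in bp (default `2 * window`).
#' @param max_gap significant SNPs closer than this are joined into one
#'   interval (default one window, the resolution of the smoothed scan).
#' @param seed optional integer seed for the null resampling.
#' @return list with `sites` (per-SNP data.frame adding `delta_w`, `n_w`,
#'   `p`, `p_adj`, `significant`) and `intervals` (data.frame `chrom`,
#'   `start`, `end`, `n_snps`, `p_adj_min`).
#' @export
call_qtl <- function(records, thresholds, window = 1e6, fdr = 0.001,
                     min_snps = 5, min_span = 2 * window, max_gap = window,
                     seed = NULL) {
  stopifnot(inherits(thresholds, "threshold_table"),
            all(c("chrom", "pos", "delta", "depth_high", "depth_low") %in%
                  names(records)))
  if (!is.null(seed)) set.seed(seed)
  R <- thresholds$reps
  site_depth <- round((records$depth_high + records$depth_low) / 2)
  didx <- vapply(site_depth, function(d) which.min(abs(thresholds$depths - d)), 1L)
  if (any(abs(thresholds$depths[didx] - site_depth) > 0))
    warning("some site depths absent from the threshold table; ",
            "using nearest simulated depth")

  out <- records
  out$delta_w <- NA_real_; out$n_w <- NA_integer_; out$p <- NA_real_
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    if (is.unsorted(records$pos[i]))
      stop("records must be sorted by position within chromosome (", ch, ")")
    W <- .tricube_weights(records$pos[i], window)
    obs <- as.numeric(W %*% records$delta[i])
    S <- length(i)
    draw <- matrix(thresholds$null[cbind(sample.int(R, S * R, replace = TRUE),
                                         rep(didx[i], times = R))], S, R)
    null_w <- W %*% draw
    out$delta_w[i] <- obs
    out$n_w[i] <- as.integer(rowSums(W > 0))
    out$p[i] <- rowMeans(abs(null_w) >= abs(obs))
  }
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr

  ivs <- list()
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch & out$significant, ]
    if (!nrow(sub)) next
    grp <- cumsum(c(1L, diff(sub$pos) > max_gap))
    for (g in split(seq_len(nrow(sub)), grp)) {
      span <- sub$pos[g[length(g)]] - sub$pos[g[1]]
      if (length(g) < min_snps || span <= min_span) next
      ivs[[length(ivs) + 1L]] <- data.frame(
        chrom = ch, start = sub$pos[g[1]], end = sub$pos[g[length(g)]],
        n_snps = length(g), p_adj_min = min(sub$p_adj[g]),
        stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(ivs)) do.call(rbind, ivs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_snps = integer(), p_adj_min = numeric())
  list(sites = out, intervals = intervals)
}

#' Extract per-bulk allele depths from pooled counts
#'
#' Converts a sync object plus a donor-diagnostic site table into the
#' two-bulk allele-depth records consumed by the BSA functions, using one
#' pool as the high bulk and one as the low bulk. Sites where either bulk has
#' zero informative depth (ref + alt reads) are skipped with a message.
#'
#' @param x a [sync] object.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (the `sites`
#'   attribute of [simulate_pool_counts()], or any fixed-SNP allowlist).
#' @param high_pool,low_pool pool names in `x$pools`.
#' @return data.frame with `chrom`, `pos`, per-bulk ref/alt depths,
#'   `index_high`, `index_low`, `delta`, `depth_high`, `depth_low`.
#' @export
sync_to_bulks <- function(x, sites, high_pool, low_pool) {
  ph <- match(high_pool, x$pools); pl <- match(low_pool, x$pools)
  if (is.na(ph) || is.na(pl)) stop("bulk pools not found in sync object")
  key <- match(paste(sites$chrom, sites$pos), paste(x$chrom, x$pos))
  if (anyNA(key)) stop("some allowlist sites are absent from the sync object")
  ri <- match(sites$ref, BASES6); ai <- match(sites$alt, BASES6)
  idx <- function(p, b) x$counts[cbind(key, b, p)]
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref_high = idx(ph, ri), alt_high = idx(ph, ai),
                    ref_low = idx(pl, ri), alt_low = idx(pl, ai),
                    stringsAsFactors = FALSE)
  out$depth_high <- out$ref_high + out$alt_high
  out$depth_low <- out$ref_low + out$alt_low
  drop <- out$depth_high == 0 | out$depth_low == 0
  if (any(drop)) {
    message(sum(drop), " site(s) skipped: zero informative depth in a bulk")
    out <- out[!drop, ]
  }
  out$index_high <- snp_index(out$ref_high, out$alt_high)
  out$index_low <- snp_index(out$ref_low, out$alt_low)
  out$delta <- out$index_high - out$index_low
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
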