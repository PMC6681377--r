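#' Build stratified 2x2 tables from pooled counts
#'
#' For each site, the allele pair is the two nucleotides with the highest
#' totals summed over pools (N and deletions never enter the pair); ties are
#' broken by nucleotide order A < C < G < T. Within each level of the
#' stratifying trait, the high- and low-contrast pools contribute the rows of
#' a 2x2 table (major-allele count, minor-allele count).
#'
#' @param x a [sync] object.
#' @param design data.frame with columns `pool`, `trait1`, `trait2` (levels
#'   `"high"`/`"low"`), one row per pool, exactly one pool per design cell.
#' @param contrast which trait defines the high/low contrast (the other trait
#'   defines the strata): `"trait1"` (default) or `"trait2"`.
#' @return list with `major`, `minor` (per-site allele characters), matrices
#'   `a`, `b`, `c`, `d` (sites x strata: high-pool major/minor, low-pool
#'   major/minor counts) and logical `informative` (`FALSE` where no second
#'   allele exists; such sites are flagged and excluded from scans).
#' @export
build_strata <- function(x, design, contrast = c("trait1", "trait2")) {
  contrast <- match.arg(contrast)
  stratum_trait <- if (contrast == "trait1") "trait2" else "trait1"
  stopifnot(all(c("pool", "trait1", "trait2") %in% names(design)))
  if (!setequal(design$pool, x$pools) || nrow(design) != length(x$pools))
    stop("design pools do not match the sync pools")
  cells <- table(design[[contrast]], design[[stratum_trait]])
  if (any(cells != 1))
    stop("design must have exactly one pool per trait1 x trait2 cell")

  S <- length(x$pos)
  # nucleotide totals in A,C,G,T order so max.col ties resolve to A<C<G<T
  acgt <- c("A", "C", "G", "T")
  tot <- sync_totals(x)[, acgt, drop = FALSE]
  i1 <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(S), i1)] <- -Inf
  i2 <- max.col(tot2, ties.method = "first")
  major <- acgt[i1]
  minor <- acgt[i2]
  informative <- tot[cbind(seq_len(S), i2)] > 0

  strata <- sort(unique(design[[stratum_trait]]))
  K <- length(strata)
  mj <- match(major, BASES6)
  mn <- match(minor, BASES6)
  a <- b <- cc <- d <- matrix(0L, S, K, dimnames = list(NULL, strata))
  for (k in seq_len(K)) {
    hi <- design$pool[design[[contrast]] == "high" &
                        design[[stratum_trait]] == strata[k]]
    lo <- design$pool[design[[contrast]] == "low" &
                        design[[stratum_trait]] == strata[k]]
    ph <- match(hi, x$pools); pl <- match(lo, x$pools)
    a[, k] <- x$counts[cbind(seq_len(S), mj, ph)]
    b[, k] <- x$counts[cbind(seq_len(S), mn, ph)]
    cc[, k] <- x$counts[cbind(seq_len(S), mj, pl)]
    d[, k] <- x$counts[cbind(seq_len(S), mn, pl)]
  }
  list(major = major, minor = minor, a = a, b = b, c = cc, d = d,
       informative = informative)
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Computes the CMH chi-squared statistic
#' `(|sum_k (a_k - E a_k)| - correction)^2 / sum_k Var(a_k)` with
#' hypergeometric conditional moments per stratum, and its p-value from a
#' chi-square distribution with one degree of freedom. With a single stratum
#' and no correction this reduces to the classical 2x2 chi-square test.
#'
#' Inputs are the four cell counts per stratum, either as vectors of length K
#' (one site) or as sites x K matrices (vectorised over sites). Degenerate
#' sites whose margins give zero variance in every stratum return `chi2 = 0`,
#' `p = 1`, flagged in `degenerate`.
#'
#' @param a,b,c,d high-pool major, high-pool minor, low-pool major, low-pool
#'   minor counts per stratum.
#' @param correct apply a 0.5 continuity correction (default `FALSE`,
#'   matching the pooled-GWAS convention).
#' @return list with numeric `chi2`, `p` and logical `degenerate`, one entry
#'   per site.
#' @export
cmh_test <- function(a, b, c, d, correct = FALSE) {
  if (is.null(dim(a))) {
    a <- matrix(a, 1); b <- matrix(b, 1); c <- matrix(c, 1); d <- matrix(d, 1)
  }
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("cell counts must be >= 0")
  n <- a + b + c + d
  if (any(n == 0)) stop("every stratum must have a positive total")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  E <- r1 * c1 / n
  V <- r1 * r2 * c1 * c2 / (n^2 * pmax(n - 1, 1))
  S <- rowSums(a - E)
  Vs <- rowSums(V)
  degenerate <- Vs == 0
  cc <- if (correct) 0.5 else 0
  chi2 <- ifelse(degenerate, 0, (pmax(abs(S) - cc, 0))^2 / ifelse(Vs == 0, 1, Vs))
  p <- ifelse(degenerate, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = as.numeric(chi2), p = as.numeric(p), degenerate = degenerate)
}

#' Mantel-Haenszel common odds ratio
#'
#' `OR_MH = (sum_k a_k d_k / n_k) / (sum_k b_k c_k / n_k)`. Sites with a zero
#' denominator are reported as `NA` (undefined), not fabricated.
#'
#' @inheritParams cmh_test
#' @return numeric vector of common odds ratios (one per site).
#' @export
mh_common_or <- function(a, b, c, d) {
  if (is.null(dim(a))) {
    a <- matrix(a, 1); b <- matrix(b, 1); c <- matrix(c, 1); d <- matrix(d, 1)
  }
  n <- a + b + c + d
  num <- rowSums(a * d / n)
  den <- rowSums(b * c / n)
  ifelse(den > 0, num / den, NA_real_)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted p-values (monotonicity enforced,
#' order-preserving); errors on p-values outside `[0, 1]`.
#'
#' @param p vector of p-values.
#' @return vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Replicated CMH association scan
#'
#' Runs the stratified CMH test at every informative site of a (filtered,
#' optionally resampled) sync object, contrasting high against low pools of
#' one trait within strata defined by the other trait, and returns
#' genome-wide BH-adjusted p-values and Mantel-Haenszel common odds ratios.
#'
#' @inheritParams build_strata
#' @param correct continuity correction flag (see [cmh_test()]).
#' @return data.frame with `chrom`, `pos`, `major`, `minor`, `chi2`, `p`,
#'   `p_adj`, `or_mh`, one row per informative site.
#' @export
cmh_scan <- function(x, design, contrast = c("trait1", "trait2"),
                     correct = FALSE) {
  contrast <- match.arg(contrast)
  st <- build_strata(x, design, contrast)
  keep <- which(st$informative)
  res <- cmh_test(st$a[keep, , drop = FALSE], st$b[keep, , drop = FALSE],
                  st$c[keep, , drop = FALSE], st$d[keep, , drop = FALSE],
                  correct = correct)
  or <- mh_common_or(st$a[keep, , drop = FALSE], st$b[keep, , drop = FALSE],
                     st$c[keep, , drop = FALSE], st$d[keep, , drop = FALSE])
  data.frame(chrom = x$chrom[keep], pos = x$pos[keep],
             major = st$major[keep], minor = st$minor[keep],
             chi2 = res$chi2, p = res$p, p_adj = bh_adjust(res$p),
             or_mh = or, stringsAsFactors = FALSE)
}
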