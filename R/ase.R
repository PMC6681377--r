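#' Homeo-SNP index
#'
#' A table of fixed nucleotide differences between the recipient species
#' (allele `a`) and the donor species (allele `b`), used to assign read
#' counts to their species of origin. Duplicate positions are rejected.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param allele_a,allele_b recipient and donor nucleotides (must differ).
#' @return data.frame of class `homeo_index`.
#' @export
homeo_index <- function(chrom, pos, allele_a, allele_b) {
  if (any(allele_a == allele_b))
    stop("'allele_a' and 'allele_b' must differ at every site")
  if (!all(c(allele_a, allele_b) %in% NUC4))
    stop("alleles must be nucleotides A/C/G/T")
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    stop("duplicate positions in homeo-SNP index: ", key[duplicated(key)][1])
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    allele_a = allele_a, allele_b = allele_b,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("homeo_index", "data.frame")
  out
}

#' Assign per-site counts to species of origin
#'
#' Reads matching `allele_a` at an indexed site count to the recipient
#' species, reads matching `allele_b` to the donor; any other nucleotide is
#' ambiguous. Sites absent from the index contribute only ambiguous counts.
#' Counts are conserved: `count_a + count_b + count_ambiguous` equals the
#' site depth.
#'
#' @param site_counts data.frame with `chrom`, `pos` and nucleotide count
#'   columns `A`, `C`, `G`, `T`.
#' @param index a [homeo_index()].
#' @return `site_counts` with `count_a`, `count_b`, `count_ambiguous`
#'   appended.
#' @export
assign_counts <- function(site_counts, index) {
  stopifnot(all(c("chrom", "pos", NUC4) %in% names(site_counts)))
  if (anyDuplicated(paste(index$chrom, index$pos)))
    stop("duplicate positions in homeo-SNP index")
  depth <- rowSums(site_counts[, NUC4])
  m <- match(paste(site_counts$chrom, site_counts$pos),
             paste(index$chrom, index$pos))
  cnt <- as.matrix(site_counts[, NUC4])
  pick <- function(allele) {
    v <- integer(nrow(site_counts))
    ok <- !is.na(m)
    v[ok] <- cnt[cbind(which(ok), match(allele[m[ok]], NUC4))]
    v
  }
  out <- site_counts
  out$count_a <- pick(index$allele_a)
  out$count_b <- pick(index$allele_b)
  out$count_ambiguous <- as.integer(depth - out$count_a - out$count_b)
  out
}

#' Per-gene allele-of-origin counts and proportions
#'
#' Sums assigned site counts over each gene span and computes the donor
#' proportion `count_b / (count_a + count_b)` on informative counts only.
#' Genes with no informative site are flagged (`informative = FALSE`,
#' proportion `NA`).
#'
#' @param assigned output of [assign_counts()].
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @return data.frame with per-gene `count_a`, `count_b`, `count_ambiguous`,
#'   `proportion_b`, `informative`.
#' @export
gene_proportions <- function(assigned, genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  out <- genes
  out$count_a <- out$count_b <- out$count_ambiguous <- 0L
  for (g in seq_len(nrow(genes))) {
    i <- assigned$chrom == genes$chrom[g] &
      assigned$pos >= genes$start[g] & assigned$pos <= genes$end[g]
    out$count_a[g] <- sum(assigned$count_a[i])
    out$count_b[g] <- sum(assigned$count_b[i])
    out$count_ambiguous[g] <- sum(assigned$count_ambiguous[i])
  }
  informative <- (out$count_a + out$count_b) > 0
  out$proportion_b <- ifelse(informative,
                             out$count_b / (out$count_a + out$count_b),
                             NA_real_)
  out$informative <- informative
  out
}

#' Detect a donor introgression from paired allelic-expression profiles
#'
#' Scans ordered per-gene donor proportions of a carrier and a non-carrier
#' sample group for maximal runs of at least `min_genes` consecutive
#' informative genes whose donor proportion is at least `tau_present` in the
#' carrier group and at most `tau_absent` in the non-carrier group. Each such
#' run is reported as a donor-introgression interval spanning the first gene
#' start to the last gene end. Detection uses proportions only, so it is
#' invariant to per-gene depth rescaling.
#'
#' @param carrier,non_carrier [gene_proportions()] outputs for the two
#'   groups (same genes).
#' @param tau_absent maximum donor proportion compatible with absence
#'   (default 0.02, above error-rate leakage).
#' @param tau_present minimum donor proportion indicating presence (default
#'   0.2, below heterozygous expression at 0.5).
#' @param min_genes minimum run length (default 5).
#' @return data.frame `chrom`, `start`, `end`, `n_genes`; empty (with a
#'   warning) when fewer than `min_genes` genes are informative in both
#'   groups.
#' @export
detect_introgression <- function(carrier, non_carrier, tau_absent = 0.02,
                                 tau_present = 0.2, min_genes = 5) {
  if (!(tau_absent >= 0 && tau_absent < tau_present && tau_present <= 1))
    stop("need 0 <= tau_absent < tau_present <= 1")
  key <- paste(carrier$chrom, carrier$start, carrier$gene_id)
  if (!identical(key, paste(non_carrier$chrom, non_carrier$start,
                            non_carrier$gene_id)))
    stop("carrier and non-carrier profiles must cover the same genes")
  ok <- carrier$informative & non_carrier$informative
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_genes = integer())
  if (sum(ok) < min_genes) {
    warning("fewer than ", min_genes, " genes informative in both groups")
    return(empty)
  }
  ca <- carrier[ok, ]; nc <- non_carrier[ok, ]
  o <- order(ca$chrom, ca$start)
  ca <- ca[o, ]; nc <- nc[o, ]
  ivs <- list()
  for (ch in unique(ca$chrom)) {
    i <- which(ca$chrom == ch)
    cond <- ca$proportion_b[i] >= tau_present & nc$proportion_b[i] <= tau_absent
    r <- rle(cond)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_genes)) {
      ivs[[length(ivs) + 1L]] <- data.frame(
        chrom = ch, start = ca$start[i[starts[k]]],
        end = ca$end[i[ends[k]]], n_genes = r$lengths[k],
        stringsAsFactors = FALSE)
    }
  }
  if (length(ivs)) do.call(rbind, ivs) else empty
}
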