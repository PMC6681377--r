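BASES6 <- c("A", "T", "C", "G", "N", "del")
NUC4 <- c("A", "T", "C", "G")

#' Construct a sync object
#'
#' Container for Popoolation2-style pooled nucleotide counts: one row per
#' genomic site, a reference nucleotide, and per-pool counts of A, T, C, G, N
#' and deletions (the "A:T:C:G:N:del" column order of the sync text format).
#' Positions are 1-based.
#'
#' @param chrom,pos,ref per-site chromosome, position, reference nucleotide.
#' @param counts integer array `[site, base, pool]` with 6 base rows in sync
#'   order; dimnames for bases/pools are set automatically.
#' @param pools pool names (default `pool1..poolP`).
#' @return object of class `sync`.
#' @export
sync <- function(chrom, pos, ref, counts, pools = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(dim(counts)) == 3,
            dim(counts)[1] == n, dim(counts)[2] == 6)
  if (any(counts < 0)) stop("counts must be non-negative")
  npool <- dim(counts)[3]
  if (is.null(pools)) pools <- paste0("pool", seq_len(npool))
  dimnames(counts) <- list(NULL, BASES6, pools)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts, pools = pools),
            class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat("sync object:", length(x$pos), "sites,", length(x$pools), "pools (",
      paste(x$pools, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
length.sync <- function(x) length(x$pos)

# subset a sync object by site index
sync_subset <- function(x, i) {
  sync(x$chrom[i], x$pos[i], x$ref[i], x$counts[i, , , drop = FALSE], x$pools)
}

# per-pool read depth (all six count columns), sites x pools matrix
sync_depth <- function(x) apply(x$counts, c(1, 3), sum)

# per-base totals summed over pools, sites x 6 matrix
sync_totals <- function(x) apply(x$counts, c(1, 2), sum)

#' Read a sync file
#'
#' Parses the tab-separated Popoolation2 sync format (`chrom pos ref` then one
#' "A:T:C:G:N:del" colon-separated count column per pool). Transparent to
#' gzip-compressed files. Malformed count strings are reported with their
#' line number.
#'
#' @param path file path (plain or `.gz`).
#' @return a [sync] object (zero sites for an empty file).
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(sync(character(), integer(), character(),
                array(integer(), dim = c(0, 6, 1))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]) || nf[1] < 4)
    stop("line ", which(nf != nf[1] | nf < 4)[1],
         ": expected chrom, pos, ref and at least one pool column")
  npool <- nf[1] - 3L
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop("line ", which(is.na(pos))[1], ": malformed position")
  counts <- array(0L, dim = c(length(lines), 6, npool))
  for (p in seq_len(npool)) {
    cs <- strsplit(m[, 3L + p], ":", fixed = TRUE)
    bad <- lengths(cs) != 6L
    if (any(bad))
      stop("line ", which(bad)[1], ": malformed count string '",
           m[which(bad)[1], 3L + p], "'")
    v <- suppressWarnings(as.integer(unlist(cs)))
    if (anyNA(v)) {
      row <- ceiling(which(is.na(v))[1] / 6)
      stop("line ", row, ": non-integer count in pool ", p)
    }
    counts[, , p] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  sync(m[, 1], pos, m[, 3], counts)
}

#' Write a sync file
#'
#' Inverse of [read_sync()]; `write_sync` then `read_sync` round-trips
#' losslessly, and re-writing reproduces the text byte for byte.
#'
#' @param x a [sync] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_sync <- function(x, path) {
  cols <- lapply(seq_along(x$pools), function(p) {
    m <- format(x$counts[, , p, drop = TRUE], trim = TRUE, scientific = FALSE)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    apply(m, 1, paste, collapse = ":")
  })
  lines <- do.call(paste, c(list(x$chrom, format(x$pos, trim = TRUE,
                                                 scientific = FALSE), x$ref),
                            cols, sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
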