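# Shared fixtures for the scan tests: simulate a cohort, build the 2x2 pool
# design, generate pooled counts and apply the default site filters.
scan_fixture <- function(n_chrom = 8, snps_per_chrom = 60, effect = 250,
                         qtl_chrom = "chr2", n = 200, seed = 101,
                         depth_mean = 40, error_rate = 0.001) {
  sc <- asa_scenario(n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
                     qtl_chrom = qtl_chrom, effect = effect)
  coh <- simulate_cohort(sc$genome, sc$qtl, n = n, seed = seed)
  pd <- construct_pools(coh, 20)
  sy <- simulate_pool_counts(pd, coh, sc$genome, sc$qtl,
                             depth_mean = depth_mean,
                             error_rate = error_rate, seed = seed + 1)
  syf <- filter_sites(sy)
  sites <- attr(sy, "sites")
  sites <- sites[match(paste(syf$chrom, syf$pos),
                       paste(sites$chrom, sites$pos)), ]
  list(scenario = sc, cohort = coh, design = pd, sync = syf, sites = sites)
}

# standard 2x2 design table matching construct_pools() pool naming
design_2x2 <- function() {
  data.frame(pool = paste0("pool", 1:4),
             trait1 = c("high", "high", "low", "low"),
             trait2 = c("high", "low", "high", "low"),
             stringsAsFactors = FALSE)
}

# small sync object from a sites x 6 x pools count array
toy_sync <- function(counts, chrom = NULL, pos = NULL, ref = NULL) {
  S <- dim(counts)[1]
  sync(chrom %||% rep("chr1", S), pos %||% seq_len(S) * 100,
       ref %||% rep("A", S), counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
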