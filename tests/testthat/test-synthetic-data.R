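test_that("cohort traits respond to the QTL effect and trait2 is independent", {
  sc0 <- asa_scenario(effect = 0)
  coh0 <- simulate_cohort(sc0$genome, sc0$qtl, n = 2000, seed = 101)
  expect_lt(abs(cor(coh0$carrier, coh0$trait1)), 0.1)

  tp <- trait_preset_asa()
  tp$trait1$sd <- 50
  tp$trait1$sd_carrier <- 50
  tp$family_sd <- 0
  sc <- asa_scenario(effect = 250)
  coh <- simulate_cohort(sc$genome, sc$qtl, n = 2000, trait_params = tp,
                         seed = 102)
  d <- mean(coh$trait1[coh$carrier]) - mean(coh$trait1[!coh$carrier])
  expect_lt(abs(d - 250), 5)
  expect_lt(abs(cor(coh$carrier, coh$trait2)), 0.1)
  expect_equal(simulate_cohort(sc$genome, sc$qtl, 50, seed = 7),
               simulate_cohort(sc$genome, sc$qtl, 50, seed = 7))
})

test_that("cohort generation rejects bad sizes and dispersions", {
  sc <- asa_scenario()
  expect_error(simulate_cohort(sc$genome, sc$qtl, n = 3), "'n'")
  tp <- trait_preset_asa()
  tp$trait1$sd <- 0
  expect_error(simulate_cohort(sc$genome, sc$qtl, n = 50, trait_params = tp),
               "sd")
})

test_that("pool phenotype means reproduce the reference pool summaries", {
  # published pool summaries the preset emulates: AsA then fruit weight,
  # pools 1..4 (high/high, high/low, low/high, low/low)
  asa_mean <- c(385.9, 433.55, 100.15, 87.25)
  asa_sd <- c(59.5, 57.1, 41.12, 24.56)
  fw_mean <- c(96.6, 56.6, 95.65, 59.85)
  fw_sd <- c(10.85, 13.51, 15.13, 15.04)
  sc <- asa_scenario(effect = 316)  # stratum separation of the reference pools
  coh <- simulate_cohort(sc$genome, sc$qtl, n = 80, seed = 103)
  pd <- construct_pools(coh, 20)
  got_asa <- vapply(pd$members,
                    function(i) mean(coh$trait1[match(i, coh$id)]), 0)
  got_fw <- vapply(pd$members,
                   function(i) mean(coh$trait2[match(i, coh$id)]), 0)
  expect_true(all(abs(got_asa - asa_mean) < 2 * asa_sd))
  expect_true(all(abs(got_fw - fw_mean) < 2 * fw_sd))
})

test_that("pool construction is a disjoint, rank-based 2x2 allocation", {
  sc <- asa_scenario()
  coh <- simulate_cohort(sc$genome, sc$qtl, n = 200, seed = 104)
  pd <- construct_pools(coh, 20)
  ids <- unlist(pd$members)
  expect_length(ids, 80)
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(lengths(pd$members) == 20))

  # with a strong effect the high-trait1 pools contain only carriers
  carriers <- coh$id[coh$carrier]
  expect_true(all(c(pd$members$pool1, pd$members$pool2) %in% carriers))

  # exhaustive allocation of a 4-individual cohort
  coh4 <- simulate_cohort(sc$genome, sc$qtl, n = 4, seed = 105)
  pd4 <- construct_pools(coh4, 1)
  expect_setequal(unlist(pd4$members), coh4$id)

  expect_error(construct_pools(coh, 60), "disjoint pools")
})

test_that("pooled counts hit the expected donor frequency at the QTL", {
  sc <- asa_scenario(n_chrom = 1, chrom_length = 2e6, snps_per_chrom = 10,
                     qtl_chrom = "chr1", qtl_pos = 5e5, block_end = 1e6)
  tp <- trait_preset_asa()
  tp$family_sd <- 0
  coh <- simulate_cohort(sc$genome, sc$qtl, n = 200, trait_params = tp,
                         seed = 106)
  pd <- construct_pools(coh, 20)
  sy <- simulate_pool_counts(pd, coh, sc$genome, sc$qtl, depth_mean = 1e6,
                             depth_dist = "fixed", error_rate = 0, seed = 107)
  sites <- attr(sy, "sites")
  freq <- attr(sy, "freq")
  # all-carrier pool: frequency exactly 0.25 inside the block, and observed
  # read fraction within 1e-3 at depth 1e6
  expect_true(all(freq[sites$linked, "pool1"] == 0.25))
  alt_idx <- match(sites$alt, c("A", "T", "C", "G", "N", "del"))
  S <- length(sy$pos)
  alt1 <- sy$counts[cbind(seq_len(S), alt_idx, 1L)]
  dep1 <- rowSums(sy$counts[, , 1])
  expect_true(all(abs(alt1[sites$linked] / dep1[sites$linked] - 0.25) < 1e-3))
  # non-carrier pool: donor allele absent at linked sites when error-free
  alt3 <- sy$counts[cbind(seq_len(S), alt_idx, 3L)]
  expect_true(all(alt3[sites$linked] == 0))
})

test_that("pooled counts conserve depth, linkage and the seed contract", {
  fx <- scan_fixture(n_chrom = 2, snps_per_chrom = 30, seed = 108)
  sc <- fx$scenario
  sy1 <- simulate_pool_counts(fx$design, fx$cohort, sc$genome, sc$qtl,
                              depth_mean = 50, depth_dist = "fixed",
                              error_rate = 0.01, seed = 109)
  # depth conservation even with base errors redistributing reads
  expect_true(all(apply(sy1$counts, c(1, 3), sum) == 50))
  # linkage: pre-sampling donor frequency constant across the block per pool
  freq <- attr(sy1, "freq")
  linked <- attr(sy1, "sites")$linked
  expect_true(all(apply(freq[linked, , drop = FALSE], 2,
                        function(f) length(unique(f)) == 1)))
  # seed contract: byte-identical sync text
  sy2 <- simulate_pool_counts(fx$design, fx$cohort, sc$genome, sc$qtl,
                              depth_mean = 50, depth_dist = "fixed",
                              error_rate = 0.01, seed = 109)
  f1 <- tempfile(); f2 <- tempfile()
  write_sync(sy1, f1); write_sync(sy2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # QTL locus must be simulatable
  bad_qtl <- qtl_model(sc$qtl$chrom, 12345)
  expect_error(simulate_pool_counts(fx$design, fx$cohort, sc$genome, bad_qtl),
               "not among")
})

test_that("allelic-expression simulation separates carriers from non-carriers", {
  sc <- asa_scenario()
  nc <- simulate_ase_counts(sc$genome, carrier = FALSE, n_genes = 50,
                            error_rate = 0, seed = 110)
  expect_true(all(nc$proportion_b == 0))
  ca <- simulate_ase_counts(sc$genome, carrier = TRUE, n_genes = 50,
                            bias = 0.5, depth_mean = 1e5, error_rate = 0,
                            seed = 111)
  inside <- (ca$start + ca$end) / 2 <= 1e7
  expect_true(all(abs(ca$proportion_b[inside] - 0.5) < 0.01))
  # step at the introgression boundary
  ca2 <- simulate_ase_counts(sc$genome, carrier = TRUE, n_genes = 100,
                             bias = 0.5, depth_mean = 100, error_rate = 0,
                             seed = 112)
  in2 <- (ca2$start + ca2$end) / 2 <= 1e7
  expect_gt(mean(ca2$proportion_b[in2]) - mean(ca2$proportion_b[!in2]), 0.3)
  expect_equal(nrow(simulate_ase_counts(sc$genome, TRUE, 0)), 0)
})

test_that("metabolite table simulation has the requested fold structure", {
  m0 <- simulate_metabolite_table(50, 20, seed = 113)
  r0 <- apply(m0$areas, 1, function(x)
    mean(x[m0$group == "plus"]) / mean(x[m0$group == "minus"]))
  expect_lt(abs(median(r0) - 1), 0.1)

  m1 <- simulate_metabolite_table(20, 65, fold_changes = c("3" = 6.36),
                                  cv = 0.2, seed = 114)
  est <- mean(m1$areas[3, m1$group == "plus"]) /
    mean(m1$areas[3, m1$group == "minus"])
  expect_lt(abs(est - 6.36) / 6.36, 0.2)

  expect_identical(simulate_metabolite_table(5, 3, seed = 1),
                   simulate_metabolite_table(5, 3, seed = 1))
  expect_error(simulate_metabolite_table(5, 3, cv = 0), "cv")
  expect_error(simulate_metabolite_table(5, 1), "n_per_group")
})
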