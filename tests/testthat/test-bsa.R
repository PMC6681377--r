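test_that("SNP-index is the alternate read fraction", {
  expect_equal(snp_index(40, 0), 0)
  expect_equal(snp_index(30, 10), 0.25)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(-1, 3), ">= 0")
})

test_that("BC4x bulk frequencies honour the 0:0.25 expectation", {
  pm <- population_model("BC4x")
  for (bs in c(5, 20, 100)) {
    expect_equal(simulate_bulk_freq(pm, bs, linked = TRUE, bulk = "high"),
                 0.25)
    expect_equal(simulate_bulk_freq(pm, bs, linked = TRUE, bulk = "low"), 0)
  }
  # null expectation: E = 0.25 * seg = 0.125
  f <- simulate_bulk_freq(pm, 20, linked = FALSE, n = 1e5, seed = 127)
  expect_lt(abs(mean(f) - 0.125), 0.002)
  # RIL null mean 0.5; F2 null mean 0.5
  fr <- simulate_bulk_freq(population_model("RIL"), 20, n = 1e5, seed = 128)
  expect_lt(abs(mean(fr) - 0.5), 0.005)
  f2 <- simulate_bulk_freq(population_model("F2"), 20, n = 1e5, seed = 129)
  expect_lt(abs(mean(f2) - 0.5), 0.005)
  expect_error(population_model("BC9"), "arg")
  expect_error(simulate_bulk_freq(pm, 0), "bulk_size")
})

test_that("null delta distribution is centred with two-stage variance", {
  pm <- population_model("BC4x")
  nd <- simulate_null_delta(pm, 20, 40, reps = 10000, seed = 130)
  expect_lt(abs(mean(nd)), 0.01)

  # depth monotonicity of the spread
  nd10 <- simulate_null_delta(pm, 20, 10, reps = 10000, seed = 131)
  expect_lt(quantile(nd, 0.975), quantile(nd10, 0.975))

  # analytic two-stage variance: 2 * (Var_genotype + E[f(1-f)]/depth)
  var_g <- 0.25^2 * 0.25 / 20
  ef <- 0.125; vf <- var_g + ef^2
  var_read <- (ef - vf) / 40
  nd2 <- simulate_null_delta(pm, 20, 40, reps = 40000, seed = 132)
  expect_lt(abs(var(nd2) / (2 * (var_g + var_read)) - 1), 0.05)

  expect_error(simulate_null_delta(pm, 20, 0), "depth")
  expect_error(simulate_null_delta(pm, 20, 40, reps = 50), "reps")
})

test_that("threshold bands narrow with depth and calibrate rejection", {
  pm <- population_model("BC4x")
  tt <- threshold_table(pm, 20, depths = c(10, 20, 40, 80), reps = 4000,
                        seed = 133)
  width99 <- tt$bands$q99.5 - tt$bands$q0.5
  expect_true(all(diff(width99) < 0.01))  # non-increasing within MC error

  # empirical rejection at the 99% band on independent null sites
  band <- tt$bands[tt$bands$depth == 40, c("q0.5", "q99.5")]
  nd <- simulate_null_delta(pm, 20, 40, reps = 10000, seed = 134)
  rej <- mean(nd < band[[1]] | nd > band[[2]])
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.02)
})

test_that("tricube windowing matches a direct kernel evaluation", {
  rec <- data.frame(chrom = "chr1",
                    pos = c(1e5, 1.2e5, 4e5, 9e5, 9.4e5, 2.5e6),
                    delta = c(0.2, -0.1, 0.4, 0.05, 0.3, -0.2))
  w <- windowed_delta(rec, window = 1e6)
  # brute-force double loop
  h <- 5e5
  for (i in seq_len(nrow(rec))) {
    u <- abs(rec$pos - rec$pos[i]) / h
    wt <- ifelse(u < 1, (1 - u^3)^3, 0)
    expect_equal(w$delta_w[i], sum(wt * rec$delta) / sum(wt),
                 tolerance = 1e-12)
  }
  # isolated SNP keeps its own delta; constant field is preserved
  expect_equal(w$delta_w[6], -0.2)
  rec2 <- data.frame(chrom = "chr1", pos = c(1e5, 2e5, 3e5),
                     delta = rep(0.2, 3))
  expect_equal(windowed_delta(rec2)$delta_w, rep(0.2, 3))
  expect_error(windowed_delta(data.frame(chrom = "chr1", pos = c(2, 1),
                                         delta = 0)), "sorted")
})

test_that("bulk-label exchange negates deltas and reflects the calls", {
  fx <- scan_fixture(n_chrom = 3, snps_per_chrom = 80, seed = 135)
  b <- sync_to_bulks(fx$sync, fx$sites, "pool1", "pool3")
  bswap <- sync_to_bulks(fx$sync, fx$sites, "pool3", "pool1")
  expect_equal(bswap$delta, -b$delta)
  pm <- population_model("BC4x")
  thr <- threshold_table(pm, 20,
                         depths = unique(round((b$depth_high + b$depth_low) / 2)),
                         reps = 2000, seed = 136)
  cq <- call_qtl(b, thr, seed = 137)
  cqs <- call_qtl(bswap, thr, seed = 137)
  expect_equal(cqs$sites$delta_w, -cq$sites$delta_w)
  expect_equal(cqs$sites$p, cq$sites$p)
  expect_equal(cqs$intervals, cq$intervals)
})

test_that("windowed BSA recovers the suppressed-block QTL in both pairings", {
  fx <- scan_fixture(n_chrom = 6, snps_per_chrom = 100, seed = 138)
  pm <- population_model("BC4x")
  # linked expectation: mean block delta near the BC4x carrier frequency
  b13 <- sync_to_bulks(fx$sync, fx$sites, "pool1", "pool3")
  blk <- b13$chrom == "chr2" & b13$pos <= 1e7
  expect_lt(abs(mean(b13$delta[blk]) - 0.25), 0.02)
  thr <- threshold_table(pm, 20,
                         depths = unique(round((b13$depth_high + b13$depth_low) / 2)),
                         reps = 4000, seed = 139)
  cq13 <- call_qtl(b13, thr, seed = 140)
  expect_equal(nrow(cq13$intervals), 1L)
  expect_equal(cq13$intervals$chrom, "chr2")
  expect_true(cq13$intervals$start <= 7.6e6 && cq13$intervals$end >= 7.6e6)

  b24 <- sync_to_bulks(fx$sync, fx$sites, "pool2", "pool4")
  thr24 <- threshold_table(pm, 20,
                           depths = unique(round((b24$depth_high + b24$depth_low) / 2)),
                           reps = 4000, seed = 141)
  cq24 <- call_qtl(b24, thr24, seed = 142)
  expect_equal(nrow(cq24$intervals), 1L)
  expect_true(cq24$intervals$start <= 7.6e6 && cq24$intervals$end >= 7.6e6)
})

test_that("null-effect simulations yield no intervals at FDR 0.001", {
  pm <- population_model("BC4x")
  for (s in c(31, 32)) {
    fx <- scan_fixture(n_chrom = 6, snps_per_chrom = 60, effect = 0,
                       qtl_chrom = "chr3", seed = s)
    b <- sync_to_bulks(fx$sync, fx$sites, "pool1", "pool3")
    thr <- threshold_table(pm, 20,
                           depths = unique(round((b$depth_high + b$depth_low) / 2)),
                           reps = 4000, seed = s + 600)
    cq <- call_qtl(b, thr, seed = s + 700)
    expect_equal(nrow(cq$intervals), 0L)
  }
})

test_that("high-depth linked sites converge to the BC4x expectation", {
  # infinite-depth limit of the carrier-bulk SNP-index at a linked site
  pm <- population_model("BC4x")
  f <- simulate_bulk_freq(pm, 20, linked = TRUE, bulk = "high")
  set.seed(143)
  alt <- rbinom(1, 1e4, f)
  idx <- snp_index(1e4 - alt, alt)
  expect_lt(abs(idx - 0.25), 0.02)
})
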