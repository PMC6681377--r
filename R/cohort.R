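#' Default trait parameters for the high-ascorbate backcross scenario
#'
#' Trait 1 (fruit ascorbate, mg/100 g FW) is normal within genotype class:
#' non-carriers around 93.7 with SD 32.8; carriers add the QTL effect and use
#' a wider SD (58.3), reflecting the larger spread observed among high-AsA
#' pools. Trait 2 (fruit weight, g) is a single normal distribution,
#' independent of carrier status, around 77 g with SD 24 so that a median
#' split reproduces high/low pool means near 96 g and 58 g. Family effects
#' shift trait 1 by a normal deviate with SD `family_sd`.
#'
#' @return list of trait generation parameters.
#' @export
trait_preset_asa <- function() {
  list(trait1 = list(mean = 93.7, sd = 32.8, sd_carrier = 58.3),
       trait2 = list(mean = 77.2, sd = 24),
       family_sd = 20)
}

#' Simulate a segregating cohort
#'
#' Generates `n` individuals from a backcross-type population segregating for
#' a dominant major QTL. Carrier status is Bernoulli with probability
#' `qtl$seg_ratio`; trait 1 is normal within genotype class with the QTL
#' effect added to carriers; trait 2 is generated independently of carrier
#' status.
#'
#' @param genome a [genome_model].
#' @param qtl a [qtl_model].
#' @param n cohort size (>= 4).
#' @param trait_params as from [trait_preset_asa()].
#' @param n_families number of (paternal) families; individuals are assigned
#'   cyclically and each family receives a trait-1 shift drawn from
#'   `N(0, family_sd)`.
#' @param seed optional integer seed.
#' @return data.frame of class `cohort` with columns `id`, `family`,
#'   `carrier`, `trait1`, `trait2`.
#' @export
simulate_cohort <- function(genome, qtl, n, trait_params = trait_preset_asa(),
                            n_families = 11, seed = NULL) {
  if (!is.numeric(n) || n < 4) stop("'n' must be >= 4")
  tp <- trait_params
  sds <- c(tp$trait1$sd, tp$trait1$sd_carrier, tp$trait2$sd)
  if (any(sds <= 0)) stop("trait SDs ('sd', 'sd_carrier') must be positive")
  if (tp$family_sd < 0) stop("'family_sd' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  family <- rep_len(paste0("F", seq_len(n_families)), n)
  fam_eff <- stats::setNames(stats::rnorm(n_families, 0, tp$family_sd),
                             paste0("F", seq_len(n_families)))
  carrier <- stats::rbinom(n, 1L, qtl$seg_ratio) == 1L
  sd1 <- ifelse(carrier, tp$trait1$sd_carrier, tp$trait1$sd)
  trait1 <- tp$trait1$mean + fam_eff[family] + qtl$effect * carrier +
    stats::rnorm(n, 0, sd1)
  trait2 <- stats::rnorm(n, tp$trait2$mean, tp$trait2$sd)
  out <- data.frame(id = sprintf("ind%04d", seq_len(n)), family = family,
                    carrier = carrier, trait1 = as.numeric(trait1),
                    trait2 = trait2, stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Allocate phenotypic extremes to an orthogonal 2x2 pool design
#'
#' Ranks the cohort on trait 1, takes the top and bottom `2 * n_per_pool`
#' individuals as the high and low trait-1 strata, and splits each stratum by
#' trait-2 rank into high and low trait-2 pools. The result is four disjoint
#' pools forming a complete 2x2 design (pool 1 = high/high, 2 = high/low,
#' 3 = low/high, 4 = low/low), deterministic given the cohort (ties broken by
#' individual id).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param n_per_pool individuals per pool (default 20).
#' @return list of class `pool_design` with `pools` (data.frame `pool`,
#'   `trait1`, `trait2`) and `members` (named list of id vectors).
#' @export
construct_pools <- function(cohort, n_per_pool = 20) {
  need <- 4L * n_per_pool
  if (nrow(cohort) < need)
    stop("cohort of ", nrow(cohort), " cannot fill 4 disjoint pools of ",
         n_per_pool, ": trait1 high/low strata need ", need, " individuals")
  o1 <- order(-cohort$trait1, cohort$id)
  hi1 <- cohort[o1[seq_len(2L * n_per_pool)], ]
  lo1 <- cohort[rev(o1)[seq_len(2L * n_per_pool)], ]
  split2 <- function(x) {
    o2 <- order(-x$trait2, x$id)
    list(high = x$id[o2[seq_len(n_per_pool)]],
         low  = x$id[rev(o2)[seq_len(n_per_pool)]])
  }
  h <- split2(hi1); l <- split2(lo1)
  members <- list(pool1 = h$high, pool2 = h$low, pool3 = l$high, pool4 = l$low)
  pools <- data.frame(pool = names(members),
                      trait1 = c("high", "high", "low", "low"),
                      trait2 = c("high", "low", "high", "low"),
                      stringsAsFactors = FALSE)
  structure(list(pools = pools, members = members), class = "pool_design")
}
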