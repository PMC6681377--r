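#' Simulate a marker-validation genotype/phenotype table
#'
#' Generates a backcross validation panel: dosage 0/1 of the donor allele
#' segregating 1:1, family assignment with fixed symmetric family effects,
#' and a trait equal to baseline + effect x dosage + family shift + normal
#' noise. Family and residual SDs are derived from the requested variance
#' shares so that, in expectation, dosage, family and residual explain
#' `var_shares["dosage"]`, `var_shares["family"]` and the remainder of total
#' trait variance.
#'
#' @param n individuals (default 196, split evenly across families).
#' @param effect trait units added per donor allele (default 250).
#' @param var_shares named vector with elements `dosage` and `family`
#'   (defaults 0.78 and 0.10); shares must sum to < 1.
#' @param n_families number of families (default 2).
#' @param baseline non-carrier trait mean.
#' @param mislabel number of individuals whose recorded dosage is flipped
#'   (planted recombinants/scoring errors; default 0). Flipped indices are
#'   returned as attribute `mislabelled`.
#' @param seed optional integer seed.
#' @return data.frame with `id`, `dosage`, `family`, `trait`.
#' @export
simulate_marker_table <- function(n = 196, effect = 250,
                                  var_shares = c(dosage = 0.78, family = 0.10),
                                  n_families = 2, baseline = 95,
                                  mislabel = 0, seed = NULL) {
  if (sum(var_shares) >= 1) stop("variance shares must sum to < 1")
  if (!is.null(seed)) set.seed(seed)
  var_dosage <- 0.25 * effect^2            # 1:1 segregation of dosage {0,1}
  var_total <- var_dosage / var_shares[["dosage"]]
  family_sd <- sqrt(var_total * var_shares[["family"]])
  resid_sd <- sqrt(var_total * (1 - sum(var_shares)))
  fam <- rep_len(paste0("F", seq_len(n_families)), n)
  # fixed symmetric family effects with population SD = family_sd
  fam_eff <- family_sd * scale(seq_len(n_families))[, 1] *
    sqrt(n_families / (n_families - 1))
  dosage <- stats::rbinom(n, 1L, 0.5)
  trait <- baseline + effect * dosage +
    fam_eff[match(fam, paste0("F", seq_len(n_families)))] +
    stats::rnorm(n, 0, resid_sd)
  recorded <- dosage
  flipped <- integer(0)
  if (mislabel > 0) {
    flipped <- sample.int(n, mislabel)
    recorded[flipped] <- 1L - recorded[flipped]
  }
  out <- data.frame(id = sprintf("bc%04d", seq_len(n)), dosage = recorded,
                    family = fam, trait = trait, stringsAsFactors = FALSE)
  attr(out, "mislabelled") <- flipped
  attr(out, "true_dosage") <- dosage
  out
}

#' Simulate a metabolite feature table
#'
#' Log-normal feature areas for two sample groups, with selected features
#' multiplied by a fold change in the marker-positive group. The coefficient
#' of variation applies on the raw-area scale (`sdlog = sqrt(log(1 + cv^2))`).
#'
#' @param n_features number of features.
#' @param n_per_group samples per group (>= 2).
#' @param fold_changes named numeric vector: feature index (as character) or
#'   a plain numeric vector of length `n_features` of per-feature fold
#'   changes; unnamed features default to 1.
#' @param cv coefficient of variation of areas (> 0).
#' @param seed optional integer seed.
#' @return list with `areas` (features x samples matrix), `group` (factor
#'   `plus`/`minus` per sample) and `fold` (the true fold change per
#'   feature).
#' @export
simulate_metabolite_table <- function(n_features, n_per_group,
                                      fold_changes = NULL, cv = 0.2,
                                      seed = NULL) {
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  if (cv <= 0) stop("'cv' must be positive")
  if (!is.null(seed)) set.seed(seed)
  fold <- rep(1, n_features)
  if (!is.null(fold_changes)) {
    if (is.null(names(fold_changes))) {
      fold[seq_along(fold_changes)] <- fold_changes
    } else {
      fold[as.integer(names(fold_changes))] <- fold_changes
    }
  }
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- stats::runif(n_features, log(1e3), log(1e5))
  n <- 2 * n_per_group
  group <- factor(rep(c("plus", "minus"), each = n_per_group),
                  levels = c("plus", "minus"))
  areas <- matrix(stats::rlnorm(n_features * n, meanlog, sdlog),
                  n_features, n)
  areas[, group == "plus"] <- areas[, group == "plus"] * fold
  dimnames(areas) <- list(sprintf("feat%03d", seq_len(n_features)),
                          sprintf("s%03d", seq_len(n)))
  list(areas = areas, group = group, fold = fold)
}
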