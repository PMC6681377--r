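#' Two-way ANOVA of trait on marker dosage and family
#'
#' Sequential (type-I) decomposition of trait variance into marker dosage
#' (entered first by default, treated as a numeric allele count so the model
#' also yields a per-allele effect estimate), family, and residual.
#' Percent variance per term is `SS_term / SS_total * 100`.
#'
#' @param tab data.frame with columns `dosage` (0/1/2 donor-allele copies),
#'   `family`, `trait` (finite).
#' @param dosage_first enter dosage before family (default); set `FALSE` to
#'   reverse the sequential order.
#' @return object of class `anova2`: list with `table` (term, df, ss, pct,
#'   statistic, p), `effect` (trait units per donor allele),
#'   `percents_defined` (FALSE when the trait is constant) and the underlying
#'   `fit`.
#' @export
two_way_anova <- function(tab, dosage_first = TRUE) {
  stopifnot(all(c("dosage", "family", "trait") %in% names(tab)))
  if (!all(is.finite(tab$trait))) stop("trait values must be finite")
  if (!all(tab$dosage %in% 0:2)) stop("dosage must be 0, 1 or 2")
  fam <- factor(tab$family)
  if (any(table(fam) == 0) || nlevels(fam) < 2)
    stop("need at least 2 non-empty families")
  within_var <- tapply(tab$dosage, fam, stats::var)
  within_var[is.na(within_var)] <- 0  # singleton family
  if (all(within_var == 0))
    stop("dosage is constant within every family: ",
         "marker and family effects are confounded")
  d <- data.frame(trait = tab$trait, dosage = as.numeric(tab$dosage),
                  family = fam)
  fml <- if (dosage_first) trait ~ dosage + family else trait ~ family + dosage
  fit <- stats::lm(fml, data = d)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  total <- sum(ss)
  defined <- stats::var(d$trait) > 0
  res <- data.frame(term = rownames(an), df = an$Df, ss = ss,
                    pct = if (defined) 100 * ss / total else NA_real_,
                    statistic = an[["F value"]], p = an[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  structure(list(table = res, effect = unname(stats::coef(fit)["dosage"]),
                 percents_defined = defined, fit = fit),
            class = "anova2")
}

#' @export
print.anova2 <- function(x, ...) {
  print(x$table, digits = 4)
  cat("dosage effect estimate:", format(x$effect, digits = 5),
      "trait units per donor allele\n")
  invisible(x)
}

#' Flag putative recombinants from marker-trait residuals
#'
#' An individual is flagged when its studentised residual from the fitted
#' two-way model exceeds `z_cut` in absolute value AND its trait value falls
#' inside the observed trait range of the opposite dosage class (carriers,
#' dosage >= 1, versus non-carriers) — i.e. its phenotype belongs with the
#' other genotype class, the signature of a recombinant between marker and
#' QTL (or a scoring error).
#'
#' @param tab the data used to fit the model.
#' @param fit an [two_way_anova()] result on `tab`.
#' @param z_cut studentised-residual threshold (default 2.5).
#' @return integer row indices of flagged individuals (empty when none).
#' @export
detect_recombinants <- function(tab, fit, z_cut = 2.5) {
  stopifnot(inherits(fit, "anova2"))
  rs <- stats::rstudent(fit$fit)
  carrier <- tab$dosage >= 1
  # class ranges from non-outlying individuals, so a mislabelled record does
  # not stretch its own (wrong) class range
  base <- !is.na(rs) & abs(rs) <= z_cut
  rng <- function(x) if (any(x)) range(tab$trait[x]) else c(Inf, -Inf)
  r_car <- rng(carrier & base); r_non <- rng(!carrier & base)
  opp_lo <- ifelse(carrier, r_non[1], r_car[1])
  opp_hi <- ifelse(carrier, r_non[2], r_car[2])
  unname(which(abs(rs) > z_cut & tab$trait >= opp_lo & tab$trait <= opp_hi))
}

# round half away from zero at `digits` decimals (the convention used for
# reported ratios/fold changes); tiny epsilon guards binary representation
round_half_away <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Metabolite group contrast
#'
#' Compares feature areas between marker-positive and marker-negative sample
#' groups: group areas are arithmetic means of raw areas, the ratio is the
#' ratio of group means (not the mean of per-sample ratios), the fold change
#' is `log2(ratio)`, and the p-value comes from a two-sided Welch t-test on
#' log areas. Reported `ratio`/`log2fold` are also returned rounded to 2
#' decimals, halves away from zero.
#'
#' @param areas_plus,areas_minus positive feature areas for the two groups.
#' @return list with `mean_plus`, `mean_minus`, `ratio`, `log2fold`, `p`,
#'   and `printed` (2-dp rounded ratio and log2fold).
#' @export
metab_contrast <- function(areas_plus, areas_minus) {
  if (!length(areas_plus) || !length(areas_minus))
    stop("both groups must be non-empty")
  if (any(areas_plus <= 0) || any(areas_minus <= 0))
    stop("areas must be positive")
  mp <- mean(areas_plus); mm <- mean(areas_minus)
  ratio <- mp / mm
  l2 <- log2(ratio)
  p <- if (length(areas_plus) > 1 && length(areas_minus) > 1)
    stats::t.test(log(areas_plus), log(areas_minus))$p.value else NA_real_
  list(mean_plus = mp, mean_minus = mm, ratio = ratio, log2fold = l2, p = p,
       printed = c(ratio = round_half_away(ratio),
                   log2fold = round_half_away(l2)))
}

#' Ratio and log2 fold change from group areas
#'
#' The arithmetic used in reported metabolite tables: ratio of group mean
#' areas and its log2, rounded to 2 decimals (halves away from zero).
#' Vectorised over features.
#'
#' @param group_area_plus,group_area_minus group mean areas (> 0).
#' @return data.frame with `ratio` and `log2fold`.
#' @export
metab_ratio <- function(group_area_plus, group_area_minus) {
  if (any(group_area_plus <= 0) || any(group_area_minus <= 0))
    stop("group areas must be positive")
  r <- group_area_plus / group_area_minus
  data.frame(ratio = round_half_away(r), log2fold = round_half_away(log2(r)))
}
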