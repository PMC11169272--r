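#' Per-stratum paired-bootstrap reports
#'
#' Runs [paired_bootstrap()] inside each patient stratum (e.g. sex, age
#' band, stress type, CAD history). Strata lacking both classes are flagged
#' and skipped.
#'
#' @param predsets Prediction tibble (see [paired_bootstrap()]) that also
#'   carries the stratification column.
#' @param stratum_col Name of the column defining strata.
#' @param ... Passed to [paired_bootstrap()].
#' @return Tibble of per-draw metrics with a `stratum` column; skipped
#'   strata are recorded in the `skipped` attribute.
#' @export
subgroup_report <- function(predsets, stratum_col, ...) {
  strata <- unique(predsets[[stratum_col]])
  skipped <- character(0)
  res <- purrr::map_dfr(strata, function(s) {
    sub <- predsets[predsets[[stratum_col]] == s, ]
    if (length(unique(as.logical(sub$label))) < 2) {
      skipped <<- c(skipped, as.character(s))
      return(NULL)
    }
    dplyr::mutate(tibble::as_tibble(paired_bootstrap(sub, ...)),
                  stratum = as.character(s))
  })
  structure(res, skipped = skipped)
}

#' Two-sided Z-test on the between-stratum difference of AUROC gains
#'
#' Tests whether the performance increase of a method over a reference
#' differs between two strata, using the bootstrap means and standard
#' deviations of the per-stratum gains:
#' `Z = (gain_1 - gain_2) / sqrt(sd_1^2 + sd_2^2)`.
#'
#' @param gain1,gain2 Numeric vectors of per-draw gains (method minus
#'   reference) in the two strata.
#' @return Tibble with `z` and `p` (two-sided).
#' @export
interaction_test <- function(gain1, gain2) {
  s <- sqrt(sd(gain1)^2 + sd(gain2)^2)
  z <- if (s == 0) 0 else (mean(gain1) - mean(gain2)) / s
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare two bootstrap metric distributions
#'
#' One-sided Kolmogorov-Smirnov (is `dist_a` stochastically smaller than
#' `dist_b`?) or Welch's t-test, with Bonferroni correction for `m`
#' simultaneous hypotheses (`p_adj = min(1, m * p)`).
#'
#' @param dist_a,dist_b Numeric metric distributions (e.g. per-draw AUROC).
#' @param test `"ks_one_sided"` or `"welch_t"`.
#' @param m_corrections Number of hypotheses for Bonferroni (default 1).
#' @param alternative Passed to the underlying test (default: `dist_a`
#'   less than `dist_b`).
#' @return Tibble with `statistic`, `p`, `p_bonferroni`.
#' @export
compare_methods <- function(dist_a, dist_b, test = c("ks_one_sided", "welch_t"),
                            m_corrections = 1, alternative = "less") {
  test <- match.arg(test)
  if (length(dist_a) == 0 || length(dist_b) == 0) {
    stopf("distributions must be non-empty")
  }
  ht <- if (test == "ks_one_sided") {
    # ks.test alternative "greater": CDF of x lies above that of y,
    # i.e. x stochastically smaller
    suppressWarnings(ks.test(dist_a, dist_b,
                             alternative = if (alternative == "less") "greater" else "less"))
  } else {
    t.test(dist_a, dist_b, alternative = alternative, var.equal = FALSE)
  }
  p <- unname(ht$p.value)
  tibble::tibble(statistic = unname(ht$statistic), p = p,
                 p_bonferroni = min(1, m_corrections * p))
}

#' Fisher's exact test for a 2x2 table with Woolf-logit confidence interval
#'
#' Two-sided exact hypergeometric p-value (via [stats::fisher.test()]); the
#' odds ratio is the sample cross-product ratio with a Woolf (logit) 95%
#' confidence interval.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return Tibble with `odds_ratio`, `ci_lo`, `ci_hi`, `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) stopf("need a 2x2 count table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("table has an empty margin")
  }
  p <- fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / ifelse(tab == 0, 0.5, tab)))  # Woolf; 0.5 only for zero cells
  lo <- exp(log(or) - qnorm(0.975) * se)
  hi <- exp(log(or) + qnorm(0.975) * se)
  tibble::tibble(odds_ratio = or, ci_lo = lo, ci_hi = hi, p = p)
}
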