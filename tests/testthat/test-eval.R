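test_that("AUROC matches the all-pairs count with half-credit ties", {
  auroc_pairs <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(4, {
    for (i in 1:10) {
      n <- sample(10:200, 1)
      y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.35, 0.65))
      if (length(unique(y)) < 2) next
      s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
      expect_equal(metric_auroc(s, y), auroc_pairs(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUPRC is the average-precision step integral", {
  s <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(metric_auprc(s, y), mean(c(1 / 1, 2 / 3)))
  expect_equal(metric_auprc(c(1, 0.9), c(TRUE, TRUE)), 1)
})

test_that("net benefit has its closed-form identities", {
  withr::with_seed(8, {
    y <- sample(c(TRUE, FALSE), 400, replace = TRUE, prob = c(0.3, 0.7))
    prev <- mean(y)
    pts <- c(0.05, 0.15, 0.33, 0.6)
    expect_equal(net_benefit(rep(0, 400), y, pts), rep(0, 4))        # treat none
    expect_equal(net_benefit(rep(1, 400), y, pts),
                 prev - (1 - prev) * pts / (1 - pts))                # treat all
    expect_equal(net_benefit(as.numeric(y), y, pts), rep(prev, 4))   # perfect
  })
  # hand computation at prevalence 0.3, pt = 0.15
  y2 <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(net_benefit(rep(1, 10), y2, 0.15), 0.3 - 0.7 * (0.15 / 0.85),
               tolerance = 1e-12)
  expect_error(net_benefit(runif(5), c(TRUE, rep(FALSE, 4)), 1.2), "pt")
})

test_that("avoided interventions transform and its antisymmetry", {
  expect_equal(avoided_tests_per_100(0.2, 0.2, 0.1), 0)
  expect_equal(avoided_tests_per_100(0.12, 0.10, 0.10), 18)
  expect_equal(avoided_tests_per_100(0.1, 0.3, 0.2),
               -avoided_tests_per_100(0.3, 0.1, 0.2))
  expect_error(avoided_tests_per_100(0.1, 0.1, 0), "pt")
})

test_that("decision curves carry model, treat-all, treat-none and comparator", {
  withr::with_seed(9, {
    y <- runif(300) < 0.3
    s <- plogis(qlogis(0.3) + 2 * as.numeric(y) + rnorm(300))
    dc <- decision_curve(s, y, reference = rep(0.5, 300))
    expect_true(all(dc$nb_none == 0))
    expect_equal(dc$nb_all, mean(y) - (1 - mean(y)) * dc$pt / (1 - dc$pt))
    expect_true(all(c("nb_reference", "avoided_per_100") %in% names(dc)))
    expect_s3_class(ggplot2::autoplot(dc), "ggplot")
  })
})

test_that("rule-out metrics reproduce a hand-counted table", {
  s <- c(0.02, 0.04, 0.2, 0.8)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  r <- rule_out_metrics(s, y, 0.05)
  expect_equal(r$pct_below, 50)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$npv, 1)
  r0 <- rule_out_metrics(s, y, 1e-9)
  expect_equal(r0$pct_below, 0)
  expect_equal(r0$sensitivity, 1)
  expect_true(is.na(r0$npv))  # no patients below the cutoff
  rhi <- rule_out_metrics(s, y, 0.9)
  expect_equal(rhi$pct_below, 100)
  expect_equal(rhi$sensitivity, 0)
  rr <- rule_out_metrics(s, y, 0.05, reference = c(0.5, 0.5, 0.5, 0.5),
                         boot_draws = 5)
  expect_false(is.na(rr$avoided_pct))
  expect_error(rule_out_metrics(s, c(TRUE, TRUE, TRUE, TRUE), 0.05), "degenerate")
})

test_that("paired bootstrap uses identical patient subsets across methods", {
  withr::with_seed(10, {
    n <- 800
    y <- runif(n) < 0.3
    pred <- tibble::tibble(
      label = y,
      good = plogis(qlogis(0.3) + 1.5 * y + rnorm(n)),
      same = NA_real_,
      perfect = as.numeric(y),
      random = runif(n))
    pred$same <- pred$good
    bt <- paired_bootstrap(pred, draws = 25, seed = 2)
    idx <- attr(bt, "draw_indices")
    expect_length(idx, 25)
    # structural pairing: one index set per draw, shared by all methods
    expect_equal(nrow(bt), 25 * 4)
    wide <- tidyr::pivot_wider(tibble::as_tibble(bt)[c("draw", "method", "auroc")],
                               names_from = "method", values_from = "auroc")
    expect_equal(wide$good, wide$same)             # identical scores, identical draws
    expect_true(all(wide$perfect == 1))
    rnd <- mean(wide$random)
    expect_gt(rnd, 0.45); expect_lt(rnd, 0.55)
    expect_error(paired_bootstrap(tibble::tibble(label = rep(TRUE, 10), a = runif(10))),
                 "one class")
  })
})

test_that("calibration report has closed-form Brier values and honest bins", {
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(calibration_report(c(1, 0, 1, 0), y)$brier, 0)
  expect_equal(calibration_report(rep(0.5, 4), y)$brier, 0.25)
  withr::with_seed(12, {
    n <- 5000
    p <- runif(n)
    yy <- rbinom(n, 1, p) == 1
    cr <- calibration_report(p, yy, n_bins = 10)
    filled <- cr$bins[cr$bins$n > 0, ]
    expect_true(all(abs(filled$obs_freq - filled$mean_pred) < 0.05))
    expect_s3_class(ggplot2::autoplot(cr), "ggplot")
  })
})

test_that("method comparison tests and Bonferroni behave canonically", {
  x <- rnorm(50)
  same <- compare_methods(x, x, test = "ks_one_sided")
  expect_gt(same$p, 0.9)
  expect_equal(compare_methods(x, x + 5, test = "welch_t", m_corrections = 1)$p,
               compare_methods(x, x + 5, test = "welch_t", m_corrections = 1)$p_bonferroni)
  worse <- compare_methods(rnorm(50), rnorm(50) + 2, test = "welch_t",
                           m_corrections = 10)
  expect_equal(worse$p_bonferroni, min(1, worse$p * 10))
  expect_error(compare_methods(numeric(0), x), "non-empty")
})

test_that("Fisher's test reports the cross-product OR with a Woolf CI", {
  tab <- matrix(c(10, 3, 5, 12), 2)  # [[10,5],[3,12]] row-wise
  f <- fisher_exact_2x2(tab)
  expect_equal(f$odds_ratio, 8)
  expect_true(f$ci_lo < 8 && 8 < f$ci_hi)
  # oracle: exhaustive hypergeometric enumeration at these margins
  enum_p <- local({
    r1 <- 15; c1 <- 13; n <- 30
    supp <- max(0, c1 - (n - r1)):min(r1, c1)
    d <- dhyper(supp, r1, n - r1, c1)
    sum(d[d <= d[supp == 10] * (1 + 1e-7)])
  })
  expect_equal(f$p, enum_p, tolerance = 1e-9)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("subgroup reports skip degenerate strata and Z-test is calibrated", {
  withr::with_seed(13, {
    n <- 400
    y <- runif(n) < 0.3
    pred <- tibble::tibble(label = y, m = plogis(qlogis(0.3) + y + rnorm(n)),
                           grp = rep(c("a", "b"), each = n / 2))
    sub <- subgroup_report(pred, "grp", draws = 10, seed = 3)
    expect_setequal(unique(sub$stratum), c("a", "b"))
    # identical generating process in both strata: Z near 0, p large
    ga <- sub$auroc[sub$stratum == "a"] - 0.5
    gb <- sub$auroc[sub$stratum == "b"] - 0.5
    it <- interaction_test(ga, gb)
    expect_gt(it$p, 0.05)
    # programmed effect 5x the SD: decisive
    it2 <- interaction_test(rnorm(25, 0.10, 0.01), rnorm(25, 0.05, 0.01))
    expect_lt(it2$p, 0.01)
    # degenerate stratum is skipped and recorded
    pred$grp[pred$grp == "b"] <- "a"
    pred2 <- pred
    pred2$grp[1:10] <- "c"; pred2$label[1:10] <- TRUE
    sub2 <- subgroup_report(pred2, "grp", draws = 5, seed = 3)
    expect_equal(attr(sub2, "skipped"), "c")
  })
})
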