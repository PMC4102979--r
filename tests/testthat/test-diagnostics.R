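test_that("a score exactly at the cutoff is classified positive", {
  df <- tibble::tibble(score = c(22.5, 22.4), pathology = c("malignant", "benign"))
  ct <- confusion_table(df, score, cutoff = 22.5)
  expect_equal(ct$tp, 1)
  expect_equal(ct$tn, 1)
  expect_equal(ct$fp + ct$fn, 0)
})

test_that("confusion counts sum to n and degenerate inputs behave", {
  df <- tibble::tibble(score = rep(1, 5), pathology = rep("benign", 5))
  ct <- confusion_table(df, score, cutoff = 10)
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(0, 0, 0, 5))
  expect_error(confusion_table(df, score, cutoff = Inf),
               class = "romadx_domain_error")
  expect_error(as_confusion(-1, 0, 0, 3), class = "romadx_domain_error")
})

test_that("wilson interval matches the score-test inversion oracle", {
  cases <- expand.grid(n = c(1, 2, 5, 12, 31, 43, 50), frac = c(0, .25, .5, .8, 1))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]
    x <- round(cases$frac[i] * n)
    got <- wilson_ci(x, n)
    want <- wilson_brute(x, n)
    # the oracle quantizes to its grid: compare at absolute grid resolution
    expect_lt(abs(got$lower - want[1]), 2e-5)
    expect_lt(abs(got$upper - want[2]), 2e-5)
  }
  # exact boundary behaviour
  expect_equal(wilson_ci(0, 10)$lower, 0)
  expect_equal(wilson_ci(10, 10)$upper, 1)
  ci <- wilson_ci(3, 7)
  expect_true(ci$lower >= 0 && ci$upper <= 1 &&
                ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})

test_that("metric bookkeeping identities hold on unrounded values", {
  ct <- as_confusion(37, 18, 6, 38)
  n1 <- 43; n0 <- 56; n <- 99
  sens <- sensitivity(ct)$estimate
  spec <- specificity(ct)$estimate
  da <- diagnostic_accuracy(ct)$estimate
  expect_equal(sens * n1 / 100 + 6, 43, tolerance = 1e-13)
  expect_equal(da, (sens * n1 + spec * n0) / n, tolerance = 1e-14)
  lr <- likelihood_ratios(ct)
  dor <- diagnostic_odds(ct)
  expect_equal(dor$estimate,
               lr$estimate[lr$metric == "lr_positive"] /
                 lr$estimate[lr$metric == "lr_negative"],
               tolerance = 1e-12)
})

test_that("kappa is invariant under swapping (tp,tn) with (fp,fn) roles", {
  ct <- as_confusion(32, 2, 11, 54)
  swapped <- as_confusion(54, 11, 2, 32)
  expect_equal(cohens_kappa(ct)$estimate, cohens_kappa(swapped)$estimate,
               tolerance = 1e-12)
})

test_that("degenerate tables yield tagged results, not errors", {
  perfect <- as_confusion(20, 0, 0, 30)
  lr <- likelihood_ratios(perfect)
  expect_equal(lr$estimate[lr$metric == "lr_positive"], Inf)
  expect_equal(lr$estimate[lr$metric == "lr_negative"], 0)
  expect_match(lr$method[lr$metric == "lr_positive"], "undefined")
  expect_equal(cohens_kappa(perfect)$estimate, 1)
  expect_equal(diagnostic_odds(perfect)$estimate, Inf)

  chance <- as_confusion(25, 25, 25, 25)
  expect_equal(cohens_kappa(chance)$estimate, 0)
  expect_equal(diagnostic_odds(as_confusion(1, 1, 1, 1))$estimate, 1)

  # empty positive-call column: ppv undefined but nothing raises
  none_called <- as_confusion(0, 0, 10, 20)
  p <- ppv(none_called)
  expect_true(is.na(p$estimate))
  expect_match(p$method, "undefined")
})

test_that("continuity correction changes the DOR only when requested", {
  ct <- as_confusion(19, 0, 3, 9)
  expect_equal(diagnostic_odds(ct)$estimate, Inf)
  corrected <- diagnostic_odds(ct, correction = TRUE)
  expect_equal(corrected$estimate, (19.5 * 9.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_true(is.finite(corrected$conf.low))
})

test_that("evaluate_marker assembles the full metric suite", {
  df <- scores_df(pos = c(30, 25, 10), neg = c(5, 8, 24))
  ev <- evaluate_marker(df, score, cutoff = 20)
  metrics <- tidy(ev)
  expect_setequal(metrics$metric,
                  c("sensitivity", "specificity", "ppv", "npv",
                    "diagnostic_accuracy", "lr_positive", "lr_negative",
                    "diagnostic_odds", "cohens_kappa"))
  defined <- !is.na(metrics$conf.low)
  expect_true(all(metrics$conf.low[defined] <= metrics$estimate[defined] &
                    metrics$estimate[defined] <= metrics$conf.high[defined]))
  g <- glance(ev)
  expect_equal(g$n, 6L)
  expect_equal(g$prevalence, 0.5)
})
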