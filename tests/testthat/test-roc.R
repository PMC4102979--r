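test_that("roc curve handles separation, ties and endpoints", {
  df <- scores_df(pos = c(1, 2), neg = 0)
  cv <- roc_curve(df, score)
  # perfect separation: the curve passes through (fpr 0, sens 1) at cutoff 1
  hit <- dplyr::filter(cv, cutoff == 1)
  expect_equal(hit$sensitivity, 1)
  expect_equal(hit$specificity, 1)
  # endpoints present
  expect_equal(cv$sensitivity[1], 0)
  expect_equal(cv$sensitivity[nrow(cv)], 1)
  expect_equal(cv$specificity[nrow(cv)], 0)
  # monotone as cutoff decreases
  expect_true(all(diff(cv$sensitivity) >= 0))
  expect_true(all(diff(1 - cv$specificity) >= 0))

  # a score tied across classes: one point with a fractional step on both axes
  tied <- scores_df(pos = c(5, 9), neg = c(5, 1))
  cvt <- roc_curve(tied, score)
  at5 <- dplyr::filter(cvt, cutoff == 5)
  expect_equal(at5$sensitivity, 1)
  expect_equal(at5$specificity, 0.5)

  expect_error(roc_curve(scores_df(pos = 1, neg = numeric(0)), score),
               class = "romadx_domain_error")
})

test_that("auc equals the trapezoidal area under the roc curve", {
  withr::with_seed(21, {
    for (i in 1:20) {
      inst <- random_instance()
      df <- scores_df(inst$pos, inst$neg)
      cv <- roc_curve(df, score)
      fpr <- 1 - cv$specificity
      trap <- sum(diff(fpr) * (head(cv$sensitivity, -1) + cv$sensitivity[-1]) / 2)
      expect_equal(roc_auc(df, score)$auc, trap, tolerance = 1e-12)
    }
  })
})

test_that("auc equals brute-force all-pairs concordance and handles edge cases", {
  expect_equal(roc_auc(scores_df(pos = c(10, 20), neg = c(1, 2)), score)$auc, 1)
  expect_equal(roc_auc(scores_df(pos = rep(7, 5), neg = rep(7, 9)), score)$auc, 0.5)
  expect_equal(roc_auc(scores_df(pos = c(3, 5), neg = 4), score)$auc, 0.5)
  withr::with_seed(22, {
    for (i in 1:50) {
      inst <- random_instance()
      got <- roc_auc(scores_df(inst$pos, inst$neg), score)$auc
      expect_identical(got, auc_brute(inst$pos, inst$neg))
    }
  })
})

test_that("auc confidence intervals are sane and the point agrees with pROC", {
  withr::with_seed(23, {
    inst <- list(pos = rnorm(40, 1), neg = rnorm(50))
    df <- scores_df(inst$pos, inst$neg)
    hm <- roc_auc(df, score)
    expect_true(hm$conf.low <= hm$auc && hm$auc <= hm$conf.high)
    dl <- roc_auc(df, score, ci = "delong")
    expect_equal(dl$auc, hm$auc)
    skip_if_not_installed("pROC")
    ref <- pROC::roc(response = df$pathology, predictor = df$score,
                     levels = c("benign", "malignant"), direction = "<",
                     quiet = TRUE)
    expect_equal(hm$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(c(dl$conf.low, dl$conf.high), ref_ci[c(1, 3)],
                 tolerance = 1e-6)
  })
})

test_that("youden cutoff maximizes J over the midpoint candidate grid", {
  # separated classes: midpoint cutoff, perfect J
  res <- youden_cutoff(scores_df(pos = c(30, 40), neg = c(10, 20)), score)
  expect_equal(res$cutoff, 25)
  expect_equal(res$youden_j, 1)

  # all scores equal: no information, sentinel cutoff, J = 0
  flat <- youden_cutoff(scores_df(pos = rep(4, 3), neg = rep(4, 5)), score)
  expect_equal(flat$youden_j, 0)
  expect_true(is.infinite(flat$cutoff))

  # hand-checked interior optimum
  res2 <- youden_cutoff(scores_df(pos = c(20, 26, 30), neg = c(10, 21, 24)), score)
  expect_equal(res2$cutoff, 25)
  expect_equal(res2$youden_j, 2 / 3, tolerance = 1e-12)
  expect_equal(res2$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(res2$specificity, 1)

  withr::with_seed(24, {
    for (i in 1:50) {
      inst <- random_instance()
      got <- youden_cutoff(scores_df(inst$pos, inst$neg), score)
      expect_equal(got$youden_j, youden_brute(inst$pos, inst$neg),
                   tolerance = 1e-12)
      expect_equal(got$youden_j, got$sensitivity + got$specificity - 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("monotone score transforms move cutoffs but not AUC or max J", {
  withr::with_seed(25, {
    inst <- random_instance()
    df <- scores_df(inst$pos, inst$neg)
    tf <- dplyr::mutate(df, score = exp(score / 5) + 3)
    expect_equal(roc_auc(df, score)$auc, roc_auc(tf, score)$auc)
    expect_equal(youden_cutoff(df, score)$youden_j,
                 youden_cutoff(tf, score)$youden_j, tolerance = 1e-12)
  })
})

test_that("paired AUC comparison behaves under identity, signal and null", {
  co <- simulate_cohort(seed = 31) |> score_roma()
  same <- compare_auc(co, roma_percent, roma_percent)
  expect_equal(same$delta, 0)
  expect_equal(same$p.value, 1)

  # a perfectly separating score against pure noise at the study's class sizes
  withr::with_seed(32, {
    df <- tibble::tibble(
      pathology = rep(c("malignant", "benign"), c(43, 56)),
      perfect = c(rnorm(43, 10), rnorm(56, 0)),
      noise = rnorm(99)
    )
    res <- compare_auc(df, perfect, noise)
    expect_lt(res$p.value, 0.01)
  })

  # under the null, seeded replicates rarely reject
  withr::with_seed(33, {
    rejections <- vapply(1:40, function(i) {
      df <- tibble::tibble(
        pathology = rep(c("malignant", "benign"), each = 50),
        a = rnorm(100), b = rnorm(100)
      )
      compare_auc(df, a, b)$p.value < 0.05
    }, logical(1))
    expect_lte(mean(rejections), 0.15)
  })

  expect_error(compare_auc(tibble::tibble(pathology = "benign", a = 1, b = 1),
                           a, b),
               class = "romadx_domain_error")
})

test_that("delong statistic and p-value agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(34, {
    df <- tibble::tibble(
      pathology = rep(c("malignant", "benign"), c(43, 56)),
      a = c(rnorm(43, 1.2), rnorm(56)),
      b = c(rnorm(43, 0.6), rnorm(56))
    )
    got <- compare_auc(df, a, b)
    ra <- pROC::roc(df$pathology, df$a, levels = c("benign", "malignant"),
                    direction = "<", quiet = TRUE)
    rb <- pROC::roc(df$pathology, df$b, levels = c("benign", "malignant"),
                    direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
    expect_equal(abs(got$statistic), abs(unname(ref$statistic)),
                 tolerance = 1e-9)
  })
})

test_that("bootstrap CI of the AUC difference is seeded and reproducible", {
  co <- simulate_cohort(seed = 35) |> score_roma()
  b1 <- compare_auc(co, roma_percent, ca125, boot = 200, seed = 9)
  b2 <- compare_auc(co, roma_percent, ca125, boot = 200, seed = 9)
  expect_equal(b1$boot.conf.low, b2$boot.conf.low)
  expect_true(b1$boot.conf.low <= b1$boot.conf.high)
})
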