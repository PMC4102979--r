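test_that("default spec encodes the published group-level calibration", {
  spec <- cohort_spec()
  mp <- spec$marker_params
  get <- function(m, g, col) mp[[col]][mp$marker == m & mp$pathology == g]
  # distribution medians equal the published medians exactly
  expect_equal(exp(get("ca125", "benign", "meanlog")), 17)
  expect_equal(exp(get("ca125", "malignant", "meanlog")), 121)
  expect_equal(exp(get("he4", "benign", "meanlog")), 47)
  expect_equal(exp(get("he4", "malignant", "meanlog")), 114)
  # published ranges fall inside the central 99.7% truncation band
  cal <- romadx:::marker_calibration
  for (i in seq_len(nrow(cal))) {
    row <- mp[mp$marker == cal$marker[i] & mp$pathology == cal$pathology[i], ]
    # the benign HE4 band is the minimal one, so its edge coincides with
    # the printed minimum up to floating-point rounding
    expect_lte(row$lower, cal$range_min[i] * (1 + 1e-12))
    expect_gte(row$upper, cal$range_max[i] * (1 - 1e-12))
  }
  expect_equal(spec$stage_probs, c(4, 8, 22, 9) / 43)
  expect_equal(unname(spec$menopause_prob), c(9 / 56, 22 / 43))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(stage_probs = c(1, 1, 1, 2)),
               class = "romadx_domain_error")
  expect_error(cohort_spec(rho = 1.5), class = "romadx_domain_error")
  expect_error(cohort_spec(menopause_prob = c(benign = -0.1, malignant = 0.5)),
               class = "romadx_domain_error")
  expect_error(simulate_cohort(spec = list(n_benign = 3)),
               class = "romadx_domain_error")
})

test_that("generation is deterministic given a seed", {
  a <- simulate_cohort(seed = 123)
  b <- simulate_cohort(seed = 123)
  expect_identical(a, b)
  expect_identical(readr::format_csv(a), readr::format_csv(b))
  c <- simulate_cohort(seed = 124)
  expect_false(identical(a, c))
})

test_that("generated cohorts honour the design and pass validation", {
  co <- simulate_cohort(seed = 5)
  expect_equal(sum(co$pathology == "benign"), 56)
  expect_equal(sum(co$pathology == "malignant"), 43)
  expect_silent(validate_cohort(co))
  expect_true(all(is.na(co$stage[co$pathology == "benign"])))
  expect_true(all(co$stage[co$pathology == "malignant"] %in% 1:4))
  # truncation respected
  mp <- cohort_spec()$marker_params
  for (g in c("benign", "malignant")) {
    sub <- co[co$pathology == g, ]
    expect_true(all(sub$ca125 >= mp$lower[mp$marker == "ca125" & mp$pathology == g] &
                      sub$ca125 <= mp$upper[mp$marker == "ca125" & mp$pathology == g]))
  }
})

test_that("rho = 0 produces uncorrelated log-markers at Monte-Carlo tolerance", {
  co <- simulate_cohort(cohort_spec(n_benign = 10000, n_malignant = 0, rho = 0),
                        seed = 6)
  expect_lt(abs(cor(log(co$ca125), log(co$he4))), 0.03)
})

test_that("log-normal parameters are recovered from a large sample", {
  co <- simulate_cohort(cohort_spec(n_benign = 100000, n_malignant = 0),
                        seed = 7)
  spec <- cohort_spec()
  mp <- spec$marker_params
  for (m in c("ca125", "he4")) {
    mu <- mp$meanlog[mp$marker == m & mp$pathology == "benign"]
    sg <- mp$sdlog[mp$marker == m & mp$pathology == "benign"]
    expect_equal(mean(log(co[[m]])), mu, tolerance = 0.02)
    expect_equal(sd(log(co[[m]])), sg, tolerance = 0.02)
  }
})

test_that("marker summaries report exact sample statistics", {
  one <- tibble::tibble(id = "a", menopausal_status = "pre", ca125 = 12,
                        he4 = 50, pathology = "benign")
  s <- summarize_markers(one)
  row <- s[s$marker == "ca125" & s$pathology == "benign", ]
  expect_equal(row$mean, 12)
  expect_equal(row$median, 12)
  expect_true(is.na(row$sd))
  # empty group rows are NA-tagged
  mal <- s[s$marker == "ca125" & s$pathology == "malignant", ]
  expect_equal(mal$n, 0)
  expect_true(is.na(mal$mean))

  const <- tibble::tibble(id = c("a", "b"), menopausal_status = "pre",
                          ca125 = 30, he4 = 60,
                          pathology = c("benign", "benign"))
  expect_equal(summarize_markers(const)$sd[2], 0)
})

test_that("the default design supports a discriminating ROMA pipeline", {
  # light smoke version of the replicate study; the full-depth property runs
  # in the acceptance suite
  aucs <- vapply(1:20, function(i) {
    co <- score_roma(simulate_cohort(seed = 1000 + i))
    roc_auc(co, roma_percent)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.75)
  expect_lt(mean(aucs), 0.99)
})
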