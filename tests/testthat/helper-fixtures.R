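# Deterministic 99-patient fixture calibrated so that thresholding at the
# published cutoffs (CA125 >= 22.5, HE4 >= 73, ROMA >= 18.3) reproduces the
# published total-cohort confusion tables, the 9/22 post-menopause split, and
# the early/advanced stage confusion tables. Marker values are placed on
# known sides of each cutoff; ROMA landing is determined by the formulas.
fixture_cohort <- function() {
  mk <- function(n, status, ca125, he4, pathology) {
    tibble::tibble(
      pathology = pathology,
      menopausal_status = rep_len(status, n),
      ca125 = ca125, he4 = he4
    )
  }

  malignant <- dplyr::bind_rows(
    mk(29, c(rep("post", 19), rep("pre", 10)), 300, 300, "malignant"), # ca+ he+ roma+
    mk(3, "post", 500, 60, "malignant"),                               # ca+ he- roma+
    mk(5, "pre", 100, 30, "malignant"),                                # ca+ he- roma-
    mk(1, "pre", 10, 75, "malignant"),                                 # ca- he+ roma-
    mk(5, "pre", 10, 30, "malignant")                                  # ca- he- roma-
  )
  # ROMA-positive malignant rows are 1..32, negative 33..43. Stage layout:
  # early (4 x stage1 + 8 x stage2) holds 9 ROMA+ and 3 ROMA-; advanced
  # (22 x stage3 + 9 x stage4) holds 23 ROMA+ and 8 ROMA-.
  malignant$stage <- c(
    rep(1L, 3), rep(2L, 6), rep(3L, 16), rep(4L, 7),  # rows 1..32 (ROMA+)
    1L, 2L, 2L, rep(3L, 6), rep(4L, 2)                # rows 33..43 (ROMA-)
  )

  benign <- dplyr::bind_rows(
    mk(2, "post", 60, 90, "benign"),                  # ca+ he+ roma+
    mk(3, "pre", 23, 73, "benign"),                   # ca+ he+ roma-
    mk(13, "pre", 50, 20, "benign"),                  # ca+ he- roma-
    mk(38, c(rep("post", 7), rep("pre", 31)), 10, 30, "benign")
  )
  benign$stage <- NA_integer_

  out <- dplyr::bind_rows(malignant, benign)
  out$id <- sprintf("F%03d", seq_len(nrow(out)))
  out$age <- ifelse(out$menopausal_status == "post", 58, 38) +
    seq_len(nrow(out)) %% 7
  # symptom flags with the published group rates, laid out deterministically
  rate_flag <- function(n, k) c(rep(TRUE, k), rep(FALSE, n - k))
  out$distension <- c(rate_flag(43, 18), rate_flag(56, 7))
  out$weight_loss <- c(rate_flag(43, 3), rate_flag(56, 0))
  dplyr::select(out, id, age, menopausal_status, ca125, he4, pathology,
                stage, distension, weight_loss)
}

published_cutoffs <- c(ca125 = 22.5, he4 = 73, roma = 18.3)

# All-pairs concordance oracle for the empirical AUC (ties count one half).
auc_brute <- function(pos, neg) {
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  sum(cmp) / (length(pos) * length(neg))
}

# Exhaustive Youden search over the midpoint candidate grid; returns max J.
youden_brute <- function(pos, neg) {
  s <- sort(unique(c(pos, neg)))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  max(vapply(cand,
             function(c) mean(pos >= c) + mean(neg < c) - 1,
             numeric(1)))
}

# Score-test inversion oracle for the Wilson interval: the interval is the
# set of p with |phat - p| <= z sqrt(p(1-p)/n), found by grid search.
wilson_brute <- function(x, n, grid = seq(0, 1, by = 1e-5)) {
  phat <- x / n
  z <- qnorm(0.975)
  ok <- (phat - grid)^2 <= z^2 * grid * (1 - grid) / n
  range(grid[ok])
}

# Random small two-class score instance with ties (integer scores).
random_instance <- function(max_n = 50, max_score = 20) {
  n1 <- sample(1:max_n, 1)
  n0 <- sample(1:max_n, 1)
  list(pos = sample(0:max_score, n1, replace = TRUE),
       neg = sample(0:max_score, n0, replace = TRUE))
}

scores_df <- function(pos, neg) {
  tibble::tibble(
    score = c(pos, neg),
    pathology = rep(c("malignant", "benign"), c(length(pos), length(neg)))
  )
}
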