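# Split a score column into diseased / non-diseased score vectors.
split_scores <- function(data, score, truth) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ truth }})
  if (anyNA(s) || anyNA(y) || !all(y %in% c("benign", "malignant"))) {
    abort("scores must be complete and truth must be benign/malignant",
          class = "romadx_domain_error")
  }
  pos <- s[y == "malignant"]
  neg <- s[y == "benign"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be non-empty", class = "romadx_domain_error")
  }
  list(pos = pos, neg = neg)
}

#' Empirical ROC curve
#'
#' One operating point per distinct observed score (positive call at
#' `score >= cutoff`), plus the two trivial endpoints at cutoffs `Inf`
#' (sensitivity 0, specificity 1) and `-Inf` (sensitivity 1, specificity 0).
#' Tied scores across classes produce a single point with a fractional step
#' on both axes.
#'
#' @param data A data frame with one row per subject.
#' @param score Score column (tidy-eval).
#' @param truth Outcome column with values `"benign"`/`"malignant"`;
#'   defaults to `pathology`.
#' @return A tibble of class `roc_curve` with columns `cutoff`,
#'   `sensitivity`, `specificity` (fractions), ordered by decreasing cutoff,
#'   and attributes `n1`, `n0` (class sizes).
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> roc_curve(ca125) |> autoplot()
roc_curve <- function(data, score, truth = pathology) {
  cls <- split_scores(data, {{ score }}, {{ truth }})
  cutoffs <- c(Inf, sort(unique(c(cls$pos, cls$neg)), decreasing = TRUE), -Inf)
  sens <- vapply(cutoffs, function(c) mean(cls$pos >= c), numeric(1))
  spec <- vapply(cutoffs, function(c) mean(cls$neg < c), numeric(1))
  out <- tibble(cutoff = cutoffs, sensitivity = sens, specificity = spec)
  structure(out, class = c("roc_curve", class(out)),
            n1 = length(cls$pos), n0 = length(cls$neg))
}

# Empirical AUC on score vectors: Mann-Whitney statistic / (n1*n0), ties
# counted 1/2 via midranks (exact in floating point: midranks are dyadic).
auc_value <- function(pos, neg) {
  n1 <- length(pos)
  n0 <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components and variance of the empirical AUC.
delong_components <- function(pos, neg) {
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Empirical AUC with confidence interval
#'
#' The area under the empirical ROC curve, computed as the Mann-Whitney
#' U statistic divided by `n1 * n0` with ties counted one half — i.e. the
#' probability that a random malignant case outscores a random benign one.
#' The confidence interval uses the Hanley-McNeil closed form by default;
#' `ci = "delong"` uses the DeLong structural-component variance instead.
#' Bounds are clipped to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @param ci CI method, `"hanley-mcneil"` (default) or `"delong"`.
#' @param conf_level Confidence level.
#' @return A one-row tibble: `auc`, `conf.low`, `conf.high`, `method`,
#'   `n1`, `n0`.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> score_roma() |> roc_auc(roma_percent)
roc_auc <- function(data, score, truth = pathology,
                    ci = c("hanley-mcneil", "delong"), conf_level = 0.95) {
  ci <- match.arg(ci)
  cls <- split_scores(data, {{ score }}, {{ truth }})
  n1 <- length(cls$pos)
  n0 <- length(cls$neg)
  a <- auc_value(cls$pos, cls$neg)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci == "hanley-mcneil") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  } else {
    dc <- delong_components(cls$pos, cls$neg)
    se <- sqrt(var(dc$v10) / n1 + var(dc$v01) / n0)
  }
  tibble(auc = a,
         conf.low = max(0, a - z * se), conf.high = min(1, a + z * se),
         method = ci, n1 = n1, n0 = n0)
}

#' Youden-index optimal cutoff
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over candidate
#' cutoffs placed at the midpoints between consecutive distinct observed
#' scores, plus `-Inf`/`Inf` sentinels (positive call at `score >= cutoff`).
#' Ties in J are broken towards higher specificity, then towards the lower
#' cutoff; the result is deterministic.
#'
#' @inheritParams roc_curve
#' @return A one-row tibble: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity` (fractions), `n1`, `n0`.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> youden_cutoff(he4)
youden_cutoff <- function(data, score, truth = pathology) {
  cls <- split_scores(data, {{ score }}, {{ truth }})
  s <- sort(unique(c(cls$pos, cls$neg)))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(cand, function(c) mean(cls$pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(cls$neg < c), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -spec, cand)[1]
  tibble(cutoff = cand[best], youden_j = j[best],
         sensitivity = sens[best], specificity = spec[best],
         n1 = length(cls$pos), n0 = length(cls$neg))
}

#' Paired comparison of two marker AUCs (DeLong test)
#'
#' Compares the empirical AUCs of two scores measured on the same subjects
#' with the DeLong structural-component test; optionally adds a stratified
#' bootstrap percentile interval for the AUC difference.
#'
#' @inheritParams roc_curve
#' @param score_a,score_b Paired score columns (tidy-eval).
#' @param boot Number of bootstrap replicates for the CI of the difference;
#'   `0` (default) skips the bootstrap.
#' @param seed Optional integer seed for the bootstrap.
#' @param conf_level Confidence level for the bootstrap interval.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta`, `statistic`
#'   (z-value), `p.value`, `method`, and with `boot > 0` also
#'   `boot.conf.low`, `boot.conf.high`.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |>
#'   score_roma() |>
#'   compare_auc(roma_percent, ca125)
compare_auc <- function(data, score_a, score_b, truth = pathology,
                        boot = 0, seed = NULL, conf_level = 0.95) {
  a <- dplyr::pull(data, {{ score_a }})
  b <- dplyr::pull(data, {{ score_b }})
  y <- dplyr::pull(data, {{ truth }})
  if (length(a) != length(b) || length(a) != length(y)) {
    abort("scores must be paired on identical subjects",
          class = "romadx_domain_error")
  }
  if (anyNA(a) || anyNA(b) || !all(y %in% c("benign", "malignant"))) {
    abort("scores must be complete and truth must be benign/malignant",
          class = "romadx_domain_error")
  }
  mal <- y == "malignant"
  if (!any(mal) || all(mal)) {
    abort("both classes must be non-empty", class = "romadx_domain_error")
  }
  da <- delong_components(a[mal], a[!mal])
  db <- delong_components(b[mal], b[!mal])
  n1 <- sum(mal)
  n0 <- sum(!mal)
  delta <- da$auc - db$auc
  v <- var(da$v10 - db$v10) / n1 + var(da$v01 - db$v01) / n0
  if (v <= 0) {
    stat <- 0
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
  } else {
    stat <- delta / sqrt(v)
    p <- 2 * pnorm(-abs(stat))
  }
  out <- tibble(auc_a = da$auc, auc_b = db$auc, delta = delta,
                statistic = stat, p.value = p, method = "delong")
  if (boot > 0) {
    run <- function() {
      deltas <- vapply(seq_len(boot), function(i) {
        i1 <- sample(which(mal), n1, replace = TRUE)
        i0 <- sample(which(!mal), n0, replace = TRUE)
        auc_value(a[i1], a[i0]) - auc_value(b[i1], b[i0])
      }, numeric(1))
      unname(stats::quantile(
        deltas, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2), type = 7))
    }
    q <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    out$boot.conf.low <- q[1]
    out$boot.conf.high <- q[2]
  }
  out
}
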