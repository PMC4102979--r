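#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false positives,
#'   false/true negatives against the pathology reference standard).
#' @return A `confusion_table` object.
#' @seealso [confusion_table()] to build one from scores, and the metric
#'   functions [sensitivity()], [specificity()], [ppv()], [npv()],
#'   [diagnostic_accuracy()], [likelihood_ratios()], [diagnostic_odds()],
#'   [cohens_kappa()].
#' @export
#' @examples
#' as_confusion(tp = 32, fp = 2, fn = 11, tn = 54)
as_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers",
          class = "romadx_domain_error")
  }
  if (sum(counts) == 0) {
    abort("confusion table must contain at least one observation",
          class = "romadx_domain_error")
  }
  structure(
    list(tp = as.double(tp), fp = as.double(fp),
         fn = as.double(fn), tn = as.double(tn)),
    class = "confusion_table"
  )
}

#' Build a confusion table by thresholding a score
#'
#' Calls a record positive when its score is greater than *or equal to* the
#' cutoff (the cutoff itself classifies positive), and tabulates the calls
#' against the pathology outcome.
#'
#' @param data A data frame with one row per subject.
#' @param score Column holding the marker value (tidy-eval).
#' @param cutoff Positivity threshold (finite).
#' @param truth Column holding the reference outcome (tidy-eval); values must
#'   be `"benign"` or `"malignant"`. Defaults to `pathology`.
#' @return A `confusion_table` object.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> confusion_table(ca125, cutoff = 22.5)
confusion_table <- function(data, score, cutoff, truth = pathology) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ truth }})
  if (!is.finite(cutoff)) {
    abort("cutoff must be finite", class = "romadx_domain_error")
  }
  if (anyNA(s) || anyNA(y) || !all(y %in% c("benign", "malignant"))) {
    abort("scores must be complete and truth must be benign/malignant",
          class = "romadx_domain_error")
  }
  pos <- s >= cutoff
  mal <- y == "malignant"
  as_confusion(tp = sum(pos & mal), fp = sum(pos & !mal),
               fn = sum(!pos & mal), tn = sum(!pos & !mal))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Confusion table (rows = test, cols = pathology)\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("positive", "negative"),
                              c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the normal-approximation score test: the interval is the set of
#' proportions `p` for which `|x/n - p| <= z * sqrt(p(1-p)/n)`. Bounds are
#' always inside `[0, 1]`; for `x = 0` the lower bound is exactly 0 and for
#' `x = n` the upper bound is exactly 1.
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `lower`, `upper` on the
#'   proportion scale.
#' @export
#' @examples
#' wilson_ci(32, 43)  # 0.5976 - 0.8507
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (any(n <= 0) || any(x < 0) || any(x > n)) {
    abort("need 0 <= x <= n and n > 0", class = "romadx_domain_error")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble(estimate = p,
         lower = pmax(0, centre - half),
         upper = pmin(1, centre + half))
}

# One metric row. Percent metrics carry Wilson CIs; a zero denominator yields
# a tagged undefined row rather than an error so batch runs complete.
prop_metric <- function(name, x, n, conf_level) {
  if (n == 0) {
    return(tibble(metric = name, estimate = NA_real_,
                  conf.low = NA_real_, conf.high = NA_real_,
                  method = "undefined (empty denominator)", n = 0L))
  }
  ci <- wilson_ci(x, n, conf_level)
  tibble(metric = name, estimate = 100 * x / n,
         conf.low = 100 * ci$lower, conf.high = 100 * ci$upper,
         method = "wilson", n = as.integer(n))
}

#' @rdname diagnostic_metrics
#' @export
sensitivity <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  prop_metric("sensitivity", ct$tp, ct$tp + ct$fn, conf_level)
}

#' @rdname diagnostic_metrics
#' @export
specificity <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  prop_metric("specificity", ct$tn, ct$tn + ct$fp, conf_level)
}

#' @rdname diagnostic_metrics
#' @export
ppv <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  prop_metric("ppv", ct$tp, ct$tp + ct$fp, conf_level)
}

#' @rdname diagnostic_metrics
#' @export
npv <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  prop_metric("npv", ct$tn, ct$tn + ct$fn, conf_level)
}

#' Diagnostic test metrics from a confusion table
#'
#' Point estimates with 95% confidence intervals for the standard
#' diagnostic-performance suite. Proportions (sensitivity, specificity,
#' positive/negative predictive value, diagnostic accuracy) are reported in
#' percent with Wilson score intervals. Likelihood ratios use the Simel
#' log-transform interval and the diagnostic odds ratio the analogous log
#' method. All computation is on unrounded proportions; rounding happens only
#' in report rendering.
#'
#' Metrics whose denominator is empty (or, for ratios, whose defining cells
#' are zero) return a row tagged `"undefined (...)"` in `method` with an
#' `Inf` or `NA` estimate instead of raising, so stratified batch runs
#' complete.
#'
#' @param ct A [as_confusion()] object.
#' @param conf_level Confidence level, default 0.95.
#' @param correction Add 0.5 to every cell before computing the odds ratio
#'   (continuity correction); off by default.
#' @return A tibble with columns `metric`, `estimate`, `conf.low`,
#'   `conf.high`, `method`, `n`. `likelihood_ratios()` returns two rows
#'   (`lr_positive`, `lr_negative`).
#' @name diagnostic_metrics
#' @examples
#' ct <- as_confusion(32, 2, 11, 54)
#' sensitivity(ct)
#' likelihood_ratios(ct)
NULL

#' @rdname diagnostic_metrics
#' @export
diagnostic_accuracy <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  prop_metric("diagnostic_accuracy", ct$tp + ct$tn, n, conf_level)
}

#' @rdname diagnostic_metrics
#' @export
likelihood_ratios <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  n1 <- ct$tp + ct$fn
  n0 <- ct$fp + ct$tn
  if (n1 == 0 || n0 == 0) {
    return(tibble(metric = c("lr_positive", "lr_negative"),
                  estimate = NA_real_, conf.low = NA_real_,
                  conf.high = NA_real_,
                  method = "undefined (single-class input)",
                  n = as.integer(n1 + n0)))
  }
  sens <- ct$tp / n1
  spec <- ct$tn / n0

  lr_row <- function(name, est, se_ln, defined) {
    if (!defined) {
      tibble(metric = name, estimate = est, conf.low = NA_real_,
             conf.high = NA_real_,
             method = paste0("undefined (zero cell); reported as ",
                             format(est)),
             n = as.integer(n1 + n0))
    } else {
      tibble(metric = name, estimate = est,
             conf.low = est * exp(-z * se_ln),
             conf.high = est * exp(z * se_ln),
             method = "simel log", n = as.integer(n1 + n0))
    }
  }

  # LR+ = sens/(1-spec); SE(ln LR+) = sqrt((1-sens)/tp + spec/fp)
  lrp_defined <- ct$fp > 0 && ct$tp > 0
  lrp <- if (ct$fp == 0) Inf else sens / (1 - spec)
  se_p <- if (lrp_defined) sqrt((1 - sens) / ct$tp + spec / ct$fp) else NA_real_

  # LR- = (1-sens)/spec; SE(ln LR-) = sqrt(sens/fn + (1-spec)/tn)
  lrn_defined <- ct$tn > 0 && ct$fn > 0
  lrn <- if (ct$tn == 0) Inf else (1 - sens) / spec
  se_n <- if (lrn_defined) sqrt(sens / ct$fn + (1 - spec) / ct$tn) else NA_real_

  dplyr::bind_rows(
    lr_row("lr_positive", lrp, se_p, lrp_defined),
    lr_row("lr_negative", lrn, se_n, lrn_defined)
  )
}

#' @rdname diagnostic_metrics
#' @export
diagnostic_odds <- function(ct, conf_level = 0.95, correction = FALSE) {
  stopifnot(inherits(ct, "confusion_table"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  cells <- c(ct$tp, ct$fp, ct$fn, ct$tn)
  n <- sum(cells)
  if (correction) {
    cells <- cells + 0.5
  }
  if (cells[2] == 0 || cells[3] == 0) {
    return(tibble(metric = "diagnostic_odds", estimate = Inf,
                  conf.low = NA_real_, conf.high = NA_real_,
                  method = "undefined (zero fp*fn); reported as Inf",
                  n = as.integer(n)))
  }
  dor <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  if (cells[1] == 0 || cells[4] == 0) {
    return(tibble(metric = "diagnostic_odds", estimate = dor,
                  conf.low = NA_real_, conf.high = NA_real_,
                  method = "undefined CI (zero tp*tn)",
                  n = as.integer(n)))
  }
  se <- sqrt(sum(1 / cells))
  tibble(metric = "diagnostic_odds", estimate = dor,
         conf.low = dor * exp(-z * se), conf.high = dor * exp(z * se),
         method = if (correction) "log (0.5 correction)" else "log",
         n = as.integer(n))
}

#' @rdname diagnostic_metrics
#' @export
cohens_kappa <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  po <- (ct$tp + ct$tn) / n
  pe <- ((ct$tp + ct$fp) * (ct$tp + ct$fn) +
           (ct$fn + ct$tn) * (ct$fp + ct$tn)) / n^2
  if (pe >= 1) {
    return(tibble(metric = "cohens_kappa", estimate = NA_real_,
                  conf.low = NA_real_, conf.high = NA_real_,
                  method = "undefined (chance agreement = 1)",
                  n = as.integer(n)))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  tibble(metric = "cohens_kappa", estimate = kappa,
         conf.low = kappa - z * se, conf.high = kappa + z * se,
         method = "asymptotic", n = as.integer(n))
}

#' Evaluate a marker at a cutoff
#'
#' Thresholds a score column at a cutoff (positive at `score >= cutoff`),
#' builds the confusion table and computes the complete metric suite:
#' sensitivity, specificity, PPV, NPV, diagnostic accuracy, both likelihood
#' ratios, the diagnostic odds ratio and Cohen's kappa, each with its 95%
#' confidence interval.
#'
#' @inheritParams confusion_table
#' @param conf_level Confidence level for all intervals.
#' @return A `marker_eval` object; use [tidy()] for the metric tibble and
#'   [glance()] for a one-row summary.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |>
#'   score_roma() |>
#'   evaluate_marker(roma_percent, cutoff = 18.3) |>
#'   tidy()
evaluate_marker <- function(data, score, cutoff, truth = pathology,
                            conf_level = 0.95) {
  ct <- confusion_table(data, {{ score }}, cutoff, truth = {{ truth }})
  structure(
    list(confusion = ct,
         metrics = metric_suite(ct, conf_level),
         cutoff = cutoff,
         score = as_name(enquo(score)),
         conf_level = conf_level),
    class = "marker_eval"
  )
}

# The full metric table for one confusion table.
metric_suite <- function(ct, conf_level = 0.95) {
  dplyr::bind_rows(
    sensitivity(ct, conf_level),
    specificity(ct, conf_level),
    ppv(ct, conf_level),
    npv(ct, conf_level),
    diagnostic_accuracy(ct, conf_level),
    likelihood_ratios(ct, conf_level),
    diagnostic_odds(ct, conf_level),
    cohens_kappa(ct, conf_level)
  )
}

#' @export
print.marker_eval <- function(x, ...) {
  cat("Marker evaluation:", x$score, "at cutoff >=", x$cutoff, "\n")
  print(x$confusion)
  print(x$metrics, n = Inf)
  invisible(x)
}

#' @rdname evaluate_marker
#' @param x A `marker_eval` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.marker_eval <- function(x, ...) {
  x$metrics
}

#' @rdname evaluate_marker
#' @exportS3Method generics::glance
glance.marker_eval <- function(x, ...) {
  ct <- x$confusion
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  tibble(
    n = as.integer(n),
    n_malignant = as.integer(ct$tp + ct$fn),
    n_benign = as.integer(ct$fp + ct$tn),
    prevalence = (ct$tp + ct$fn) / n,
    cutoff = x$cutoff,
    accuracy = 100 * (ct$tp + ct$tn) / n
  )
}
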