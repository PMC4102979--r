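#' Mann-Whitney U test for two samples
#'
#' Rank-sum comparison of a continuous or ordinal variable between two
#' groups. Uses the exact null distribution when there are no ties and
#' `m * n <= 400`, otherwise the tie-corrected, continuity-corrected normal
#' approximation. The statistic reported is U for the first sample.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact test;
#'   `NULL` (default) chooses automatically as above.
#' @return A one-row tibble: `statistic` (U), `p.value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "romadx_domain_error")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) {
    exact <- !has_ties && length(x) * length(y) <= 400
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE)
  )
  tibble(statistic = unname(wt$statistic), p.value = min(1, wt$p.value),
         method = if (grepl("continuity", wt$method)) {
           "mann-whitney (normal approximation)"
         } else if (exact) "mann-whitney (exact)" else "mann-whitney (normal approximation)")
}

as_2x2 <- function(t) {
  m <- as.matrix(t)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(!is.finite(m))) {
    abort("need a 2x2 table of non-negative counts",
          class = "romadx_domain_error")
  }
  m
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected by default (no Yates continuity correction); the correction
#' is available by flag. A zero row or column margin makes the statistic
#' undefined and is reported as such rather than raising.
#'
#' @param t A 2x2 matrix of counts (rows = group, cols = feature level).
#' @param correct Apply the Yates continuity correction.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(49, 7, 25, 18), 2, 2, byrow = TRUE))
chi_square_2x2 <- function(t, correct = FALSE) {
  m <- as_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble(statistic = NA_real_, df = 1L, p.value = NA_real_,
                  method = "chi-square undefined (zero margin)"))
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble(statistic = unname(ct$statistic), df = 1L,
         p.value = unname(ct$p.value),
         method = if (correct) "chi-square (Yates)" else "chi-square (uncorrected)")
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables no more probable than the observed one (probability-mass
#' rule). A table with a zero margin carries no information and returns
#' p = 1.
#'
#' @param t A 2x2 matrix of counts.
#' @return A one-row tibble: `p.value`, `method`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(56, 0, 40, 3), 2, 2, byrow = TRUE))
fisher_exact_2x2 <- function(t) {
  m <- as_2x2(t)
  ft <- fisher.test(m)
  tibble(p.value = min(1, ft$p.value), method = "fisher exact (two-sided)")
}

#' Baseline comparison of benign and malignant groups
#'
#' Summarizes each requested variable per pathology group and tests for a
#' group difference: Mann-Whitney for numeric variables (summarized as
#' mean +/- SD and median (range)); chi-square (uncorrected) for binary
#' flags, switching to the Fisher exact test when any expected cell count
#' falls below `fisher_threshold`. Missing values are dropped per variable.
#'
#' @param data A cohort tibble with a `pathology` column.
#' @param vars Character vector of columns to compare; defaults to every
#'   numeric or logical column except identifiers, markers kept elsewhere
#'   (`ca125`, `he4`) and `stage`.
#' @param fisher_threshold Minimum expected count for the chi-square test.
#' @return A tibble with one row per variable: `variable`, formatted
#'   `benign`/`malignant`/`total` summaries, `test`, `statistic`, `p.value`.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> baseline_summary(vars = c("age", "distension"))
baseline_summary <- function(data, vars = NULL, fisher_threshold = 5) {
  data <- as_tibble(data)
  if (is.null(vars)) {
    candidates <- setdiff(names(data), c("id", "pathology", "stage"))
    vars <- candidates[vapply(data[candidates],
                              function(v) is.numeric(v) || is.logical(v),
                              logical(1))]
  }
  grp <- data$pathology
  num_summary <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return("-")
    sprintf("%.1f ± %.1f; %.1f (%.1f - %.1f)",
            mean(v), if (length(v) > 1) sd(v) else NA_real_,
            median(v), min(v), max(v))
  }
  bin_summary <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return("-")
    sprintf("%d (%.1f%%)", sum(v), 100 * mean(v))
  }
  purrr::map_dfr(vars, function(var) {
    v <- data[[var]]
    ok <- !is.na(v)
    vb <- v[ok & grp == "benign"]
    vm <- v[ok & grp == "malignant"]
    if (is.logical(v) || all(v[ok] %in% c(0, 1))) {
      tab <- matrix(c(sum(!vb), sum(vb), sum(!vm), sum(vm)), 2, 2,
                    byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < fisher_threshold)) {
        res <- fisher_exact_2x2(tab)
        tibble(variable = var, benign = bin_summary(vb),
               malignant = bin_summary(vm), total = bin_summary(v[ok]),
               test = res$method, statistic = NA_real_,
               p.value = res$p.value)
      } else {
        res <- chi_square_2x2(tab)
        tibble(variable = var, benign = bin_summary(vb),
               malignant = bin_summary(vm), total = bin_summary(v[ok]),
               test = res$method, statistic = res$statistic,
               p.value = res$p.value)
      }
    } else {
      if (length(vb) == 0 || length(vm) == 0) {
        return(tibble(variable = var, benign = num_summary(vb),
                      malignant = num_summary(vm), total = num_summary(v[ok]),
                      test = "skipped (empty group)", statistic = NA_real_,
                      p.value = NA_real_))
      }
      res <- mann_whitney(vb, vm)
      tibble(variable = var, benign = num_summary(vb),
             malignant = num_summary(vm), total = num_summary(v[ok]),
             test = res$method, statistic = res$statistic,
             p.value = res$p.value)
    }
  })
}

#' Display p-values the way clinical tables print them
#'
#' Three decimals, floored at `"< 0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.0787, 0.0004))
format_p <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p)))
}
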