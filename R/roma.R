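#' ROMA predictive index
#'
#' Linear predictor of the Risk of Ovarian Malignancy Algorithm, combining
#' the natural logarithms of serum HE4 and CA125 with menopause-specific
#' coefficients:
#' \deqn{PI_{pre}  = -12.0 + 2.38 \ln(HE4) + 0.0626 \ln(CA125)}
#' \deqn{PI_{post} = -8.09 + 1.04 \ln(HE4) + 0.732 \ln(CA125)}
#' Markers are used in their assay units (HE4 in pmol/L, CA125 in U/mL), with
#' no unit conversion.
#'
#' @param he4 Serum HE4 (pmol/L), positive.
#' @param ca125 Serum CA125 (U/mL), positive.
#' @param status Menopausal status, `"pre"` or `"post"` (recycled).
#' @return The predictive index, a dimensionless real vector.
#' @seealso [roma_percent()], [score_roma()]
#' @export
#' @examples
#' predictive_index(he4 = 100, ca125 = 100, status = "post")
predictive_index <- function(he4, ca125, status) {
  if (any(is.na(he4)) || any(is.na(ca125)) ||
      any(!is.finite(he4)) || any(!is.finite(ca125)) ||
      any(he4 <= 0) || any(ca125 <= 0)) {
    abort("he4 and ca125 must be positive finite numbers (ln must be defined)",
          class = "romadx_domain_error")
  }
  if (!all(status %in% c("pre", "post"))) {
    abort("status must be \"pre\" or \"post\"", class = "romadx_domain_error")
  }
  n <- max(length(he4), length(ca125), length(status))
  he4 <- rep_len(he4, n)
  ca125 <- rep_len(ca125, n)
  status <- rep_len(status, n)
  ifelse(status == "pre",
         -12.0 + 2.38 * log(he4) + 0.0626 * log(ca125),
         -8.09 + 1.04 * log(he4) + 0.732 * log(ca125))
}

#' ROMA percentage
#'
#' Logistic transform of the predictive index scaled to a percentage:
#' \eqn{ROMA = 100 \, e^{PI} / (1 + e^{PI})}. Computed in a numerically
#' stable piecewise form so large `|pi|` saturates towards 0 or 100 without
#' overflow and never yields `NaN`.
#'
#' @param pi Predictive index, any finite real vector.
#' @return ROMA in percent, strictly inside (0, 100) for finite input.
#' @export
#' @examples
#' roma_percent(0)           # 50
#' roma_percent(c(-40, 40))  # saturates, never NaN
roma_percent <- function(pi) {
  if (any(is.na(pi))) {
    abort("pi must not contain missing values", class = "romadx_domain_error")
  }
  # exp() only ever sees non-positive arguments
  ifelse(pi > 0,
         100 / (1 + exp(-pi)),
         100 * exp(pi) / (1 + exp(pi)))
}

#' Score a cohort with the ROMA index
#'
#' Appends `pi` (predictive index) and `roma_percent` columns to a cohort,
#' dispatching on each record's `menopausal_status`. Deterministic; a record
#' with a non-positive marker raises an error naming the patient id.
#'
#' @param data A validated cohort tibble with `ca125`, `he4` and
#'   `menopausal_status` columns.
#' @return `data` with `pi` and `roma_percent` columns appended.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> score_roma()
score_roma <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    return(dplyr::mutate(data, pi = numeric(0), roma_percent = numeric(0)))
  }
  bad <- which(is.na(data$ca125) | is.na(data$he4) |
                 data$ca125 <= 0 | data$he4 <= 0)
  if (length(bad) > 0) {
    ids <- if ("id" %in% names(data)) data$id[bad] else bad
    abort(paste0("non-positive or missing marker for patient(s): ",
                 paste(ids, collapse = ", ")),
          class = "romadx_domain_error")
  }
  dplyr::mutate(
    data,
    pi = predictive_index(.data$he4, .data$ca125, .data$menopausal_status),
    roma_percent = roma_percent(.data$pi)
  )
}
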