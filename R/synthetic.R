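# Published group-level marker summaries the generator is calibrated to:
# median and observed range (min, max) per marker and pathology group, from a
# 99-patient surgical case-control series (56 benign / 43 malignant).
marker_calibration <- tibble::tibble(
  marker = c("ca125", "ca125", "he4", "he4"),
  pathology = c("benign", "malignant", "benign", "malignant"),
  median = c(17, 121, 47, 114),
  range_min = c(2, 3, 5, 26),
  range_max = c(140, 7169, 97, 1500)
)

#' Specification for a synthetic adnexal-mass cohort
#'
#' Defines the generative model used by [simulate_cohort()]. Marker
#' marginals are truncated log-normals: `meanlog = log(median)` so the
#' distribution median matches the published group median exactly, and
#' `sdlog = (log(max) - log(min)) / 4.5`, which places the published
#' extremes at about +/- 2.25 SD — where the extremes of a sample of ~50 are
#' expected — inside the +/- 3 SD (central 99.7%) truncation band. When the
#' log-median is off-centre in the published log-range (benign HE4), `sdlog`
#' is enlarged to the minimum that still keeps the whole published range
#' inside the truncation band. Within a
#' pathology group, `log(CA125)` and `log(HE4)` share one correlation `rho`.
#' Menopausal status is Bernoulli per group, FIGO stage categorical over
#' 1-4 (malignant only), age truncated normal, and symptom flags independent
#' Bernoullis at the published group rates.
#'
#' @param n_benign,n_malignant Group sizes (defaults 56 and 43).
#' @param menopause_prob Named probabilities of post-menopausal status,
#'   `c(benign = , malignant = )`; defaults 9/56 and 22/43.
#' @param marker_params A tibble with columns `marker`, `pathology`,
#'   `meanlog`, `sdlog`, `lower`, `upper` (truncation bounds on the natural
#'   scale); defaults are derived from the published medians and ranges.
#' @param rho Log-scale correlation between CA125 and HE4 within a group.
#' @param stage_probs Probabilities over FIGO stages 1-4; defaults
#'   `(4, 8, 22, 9) / 43`.
#' @param age_params List with `benign`/`malignant` mean and sd plus
#'   truncation bounds for age in years.
#' @param symptom_probs Named list of per-group Bernoulli rates for the
#'   symptom flags.
#' @return A `cohort_spec` object.
#' @export
#' @examples
#' cohort_spec(rho = 0)
cohort_spec <- function(n_benign = 56,
                        n_malignant = 43,
                        menopause_prob = c(benign = 9 / 56,
                                           malignant = 22 / 43),
                        marker_params = NULL,
                        rho = 0.3,
                        stage_probs = c(4, 8, 22, 9) / 43,
                        age_params = list(
                          benign = c(mean = 39, sd = 14),
                          malignant = c(mean = 51, sd = 16),
                          bounds = c(17, 79)
                        ),
                        symptom_probs = list(
                          vaginal_bleeding = c(benign = 13 / 56, malignant = 10 / 43),
                          pain = c(benign = 32 / 56, malignant = 21 / 43),
                          distension = c(benign = 7 / 56, malignant = 18 / 43),
                          weight_loss = c(benign = 0 / 56, malignant = 3 / 43)
                        )) {
  if (is.null(marker_params)) {
    marker_params <- dplyr::mutate(
      marker_calibration,
      meanlog = log(.data$median),
      sdlog = pmax(
        (log(.data$range_max) - log(.data$range_min)) / 4.5,
        pmax(.data$meanlog - log(.data$range_min),
             log(.data$range_max) - .data$meanlog) / 3
      ),
      lower = exp(.data$meanlog - 3 * .data$sdlog),
      upper = exp(.data$meanlog + 3 * .data$sdlog)
    )
    marker_params <- dplyr::select(marker_params, "marker", "pathology",
                                   "meanlog", "sdlog", "lower", "upper")
  }
  spec <- structure(
    list(n_benign = n_benign, n_malignant = n_malignant,
         menopause_prob = menopause_prob, marker_params = marker_params,
         rho = rho, stage_probs = stage_probs, age_params = age_params,
         symptom_probs = symptom_probs),
    class = "cohort_spec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  ok <- function(cond, msg) {
    if (!cond) abort(paste0("invalid cohort_spec: ", msg),
                     class = "romadx_domain_error")
  }
  ok(spec$n_benign >= 0 && spec$n_malignant >= 0 &&
       spec$n_benign + spec$n_malignant > 0, "group sizes must be >= 0, n > 0")
  ok(all(spec$menopause_prob >= 0 & spec$menopause_prob <= 1),
     "menopause probabilities must be in [0, 1]")
  ok(abs(sum(spec$stage_probs) - 1) < 1e-8 && all(spec$stage_probs >= 0),
     "stage probabilities must be non-negative and sum to 1")
  ok(abs(spec$rho) <= 1, "rho must be in [-1, 1]")
  mp <- spec$marker_params
  ok(all(c("marker", "pathology", "meanlog", "sdlog", "lower", "upper") %in%
           names(mp)), "marker_params is missing columns")
  ok(all(mp$lower > 0 & mp$upper > mp$lower & mp$sdlog > 0),
     "marker truncation ranges must be positive and ordered")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_benign, "benign /", x$n_malignant,
      "malignant\n")
  cat("post-menopause prob:",
      sprintf("benign %.3f, malignant %.3f", x$menopause_prob[["benign"]],
              x$menopause_prob[["malignant"]]), "\n")
  cat("log-scale marker correlation rho =", x$rho, "\n")
  print(as_tibble(x$marker_params))
  invisible(x)
}

# Correlated truncated log-normal draws for one pathology group.
draw_markers <- function(n, params, rho) {
  p_ca <- params[params$marker == "ca125", ]
  p_he <- params[params$marker == "he4", ]
  out_ca <- numeric(n)
  out_he <- numeric(n)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0) {
    m <- length(todo)
    z1 <- rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
    ca <- exp(p_ca$meanlog + p_ca$sdlog * z1)
    he <- exp(p_he$meanlog + p_he$sdlog * z2)
    keep <- ca >= p_ca$lower & ca <= p_ca$upper &
      he >= p_he$lower & he <= p_he$upper
    out_ca[todo[keep]] <- ca[keep]
    out_he[todo[keep]] <- he[keep]
    todo <- todo[!keep]
    tries <- tries + 1L
    if (tries > 1000L) {
      abort("truncation bounds reject almost all draws; widen the range",
            class = "romadx_domain_error")
    }
  }
  tibble(ca125 = out_ca, he4 = out_he)
}

draw_age <- function(n, mean, sd, bounds) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    a <- rnorm(length(todo), mean, sd)
    keep <- a >= bounds[1] & a <= bounds[2]
    out[todo[keep]] <- a[keep]
    todo <- todo[!keep]
  }
  round(out)
}

#' Generate a synthetic adnexal-mass cohort
#'
#' Draws a patient-level cohort from a [cohort_spec()]. Deterministic for a
#' given seed: the same seed and spec reproduce the cohort exactly. The
#' output satisfies every cohort invariant and is consumable by the whole
#' pipeline ([score_roma()], [run_roma_analysis()], ...).
#'
#' @param spec A [cohort_spec()]; the default emulates the published
#'   99-patient series.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param n_benign,n_malignant Convenience overrides of the spec's group
#'   sizes.
#' @return A cohort tibble: `id`, `age`, `menopausal_status`, `ca125`,
#'   `he4`, `pathology`, `stage` (NA for benign), and logical symptom flags.
#' @export
#' @examples
#' simulate_cohort(seed = 7) |> cohort_counts()
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            n_benign = NULL, n_malignant = NULL) {
  if (!inherits(spec, "cohort_spec")) {
    abort("spec must be a cohort_spec object", class = "romadx_domain_error")
  }
  if (!is.null(n_benign)) spec$n_benign <- n_benign
  if (!is.null(n_malignant)) spec$n_malignant <- n_malignant
  validate_spec(spec)
  gen <- function() {
    groups <- purrr::map_dfr(c("benign", "malignant"), function(g) {
      n <- if (g == "benign") spec$n_benign else spec$n_malignant
      if (n == 0) return(NULL)
      markers <- draw_markers(
        n, spec$marker_params[spec$marker_params$pathology == g, ], spec$rho)
      ap <- spec$age_params[[g]]
      symptoms <- purrr::map_dfc(spec$symptom_probs, function(p) {
        as.logical(rbinom(n, 1, p[[g]]))
      })
      dplyr::bind_cols(
        tibble(
          pathology = g,
          age = draw_age(n, ap[["mean"]], ap[["sd"]],
                         spec$age_params$bounds),
          menopausal_status = ifelse(
            runif(n) < spec$menopause_prob[[g]], "post", "pre"),
          stage = if (g == "malignant") {
            sample(1:4, n, replace = TRUE, prob = spec$stage_probs)
          } else {
            NA_integer_
          }
        ),
        markers, symptoms
      )
    })
    groups$id <- sprintf("P%04d", seq_len(nrow(groups)))
    dplyr::select(groups, "id", "age", "menopausal_status", "ca125", "he4",
                  "pathology", "stage", dplyr::everything())
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  validate_cohort(out)
}

#' Marker summary by pathology group
#'
#' Sample statistics per marker and group in the layout clinical papers
#' print: mean +/- SD, median, range. SD is `NA` for groups of one; an empty
#' group yields a row of `NA`s.
#'
#' @param data A cohort tibble.
#' @param markers Marker columns to summarize.
#' @return A tibble: `marker`, `pathology` (including `"total"`), `n`,
#'   `mean`, `sd`, `median`, `min`, `max`.
#' @export
#' @examples
#' simulate_cohort(seed = 1) |> summarize_markers()
summarize_markers <- function(data, markers = c("ca125", "he4")) {
  data <- as_tibble(data)
  purrr::map_dfr(markers, function(m) {
    purrr::map_dfr(c("total", "benign", "malignant"), function(g) {
      v <- if (g == "total") data[[m]] else data[[m]][data$pathology == g]
      v <- v[!is.na(v)]
      n <- length(v)
      tibble(marker = m, pathology = g, n = n,
             mean = if (n > 0) mean(v) else NA_real_,
             sd = if (n > 1) sd(v) else NA_real_,
             median = if (n > 0) median(v) else NA_real_,
             min = if (n > 0) min(v) else NA_real_,
             max = if (n > 0) max(v) else NA_real_)
    })
  })
}
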