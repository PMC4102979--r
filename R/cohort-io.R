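#' Read and validate a patient cohort from CSV
#'
#' Reads a comma-separated, UTF-8 patient table with a header row and returns
#' a validated cohort tibble. The canonical columns are `id`, `age`,
#' `menopausal_status` (`"pre"`/`"post"`), `ca125` (U/mL), `he4` (pmol/L),
#' `pathology` (`"benign"`/`"malignant"`) and, for malignant cases, `stage`
#' (FIGO 1-4). Source files with different headers are mapped via `col_map`.
#' Optional symptom flags (`vaginal_bleeding`, `pain`, `distension`,
#' `weight_loss`) and demographic columns are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the headers used in the file, e.g.
#'   `c(ca125 = "CA125_U_mL", pathology = "histology")`.
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(simulate_cohort(seed = 1), f, row.names = FALSE)
#' cohort <- read_cohort(f)
#' dplyr::count(cohort, pathology)
read_cohort <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: '", path, "'"), class = "romadx_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(data))
    if (length(missing_src) > 0) {
      abort(
        paste0("columns named in `col_map` not present in file: ",
               paste(missing_src, collapse = ", ")),
        class = "romadx_schema_error"
      )
    }
    data <- dplyr::rename(data, !!!setNames(unname(col_map), names(col_map)))
  }
  validate_cohort(data)
}

required_cohort_cols <- c("id", "menopausal_status", "ca125", "he4", "pathology")

#' Validate a cohort table
#'
#' Checks the invariants the downstream analysis relies on and either returns
#' the data as a tibble or raises a classed error whose message lists every
#' offending row. Invariants: unique non-missing ids; `menopausal_status` in
#' `{"pre","post"}`; `pathology` in `{"benign","malignant"}`; `ca125 > 0` and
#' `he4 > 0` (their logarithms must be defined); `stage`, when present, is an
#' integer in 1-4 and only given for malignant records.
#'
#' @param data A data frame of patient records.
#' @return `data` as a tibble, invisibly usable in a pipe.
#' @export
validate_cohort <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(required_cohort_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cohort is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "romadx_schema_error"
    )
  }

  problems <- character()
  row_problem <- function(rows, what) {
    if (length(rows) > 0) {
      sprintf("row %s: %s", paste(rows, collapse = ", "), what)
    } else {
      character()
    }
  }

  if (anyNA(data$id)) {
    problems <- c(problems, row_problem(which(is.na(data$id)), "missing id"))
  }
  dup <- duplicated(data$id) & !is.na(data$id)
  problems <- c(problems, row_problem(which(dup), "duplicate id"))

  bad_status <- !data$menopausal_status %in% c("pre", "post")
  problems <- c(problems,
                row_problem(which(bad_status),
                            "menopausal_status must be \"pre\" or \"post\""))
  bad_path <- !data$pathology %in% c("benign", "malignant")
  problems <- c(problems,
                row_problem(which(bad_path),
                            "pathology must be \"benign\" or \"malignant\""))

  for (marker in c("ca125", "he4")) {
    v <- data[[marker]]
    bad <- is.na(v) | !is.finite(v) | v <= 0
    problems <- c(problems,
                  row_problem(which(bad),
                              paste0(marker, " must be a positive finite number")))
  }

  if ("stage" %in% names(data)) {
    st <- data$stage
    has_stage <- !is.na(st)
    bad_range <- has_stage & (!st %in% 1:4)
    problems <- c(problems, row_problem(which(bad_range), "stage must be in 1-4"))
    benign_staged <- has_stage & data$pathology %in% "benign"
    problems <- c(problems,
                  row_problem(which(benign_staged),
                              "stage given for a benign record"))
  }

  if (length(problems) > 0) {
    abort(
      paste0("invalid cohort:\n", paste0("  - ", problems, collapse = "\n")),
      class = "romadx_validation_error",
      problems = problems
    )
  }
  data
}

#' Subset a cohort to an analysis stratum
#'
#' The analysis runs on the whole cohort and on menopausal and tumour-stage
#' subsets. Menopausal strata subset all records by `menopausal_status`.
#' Stage strata keep the malignant cases of the requested stage band
#' (early = FIGO 1-2, advanced = FIGO 3-4) and retain *all* benign records as
#' the negative class, so specificity is computed against the full benign
#' group in both.
#'
#' @param data A validated cohort tibble.
#' @param stratum One of `"total"`, `"premenopause"`, `"postmenopause"`,
#'   `"early_stage"`, `"advanced_stage"`.
#' @return The sub-cohort as a tibble.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' nrow(stratify(cohort, "postmenopause"))
stratify <- function(data,
                     stratum = c("total", "premenopause", "postmenopause",
                                 "early_stage", "advanced_stage")) {
  stratum <- match.arg(stratum)
  if (stratum == "total") {
    return(as_tibble(data))
  }
  if (stratum %in% c("premenopause", "postmenopause")) {
    want <- if (stratum == "premenopause") "pre" else "post"
    return(dplyr::filter(data, .data$menopausal_status == want))
  }
  # stage strata
  if (!"stage" %in% names(data) ||
      all(is.na(data$stage[data$pathology == "malignant"]))) {
    abort(paste0("stage stratum '", stratum,
                 "' requested but the cohort has no stage data"),
          class = "romadx_validation_error")
  }
  stages <- if (stratum == "early_stage") 1:2 else 3:4
  dplyr::filter(
    data,
    .data$pathology == "benign" |
      (.data$pathology == "malignant" & .data$stage %in% stages)
  )
}

#' Tabulate cohort composition
#'
#' Counts records by pathology and menopausal status, the margins every
#' stratified analysis is built on.
#'
#' @param data A cohort tibble.
#' @return A tibble with columns `pathology`, `menopausal_status`, `n`.
#' @export
cohort_counts <- function(data) {
  dplyr::count(as_tibble(data), .data$pathology, .data$menopausal_status,
               name = "n")
}

#' Flag implausible menopausal-status entries (QC helper)
#'
#' Menopausal status is an input column, never inferred from age; this helper
#' only flags records coded `"pre"` at or above an age threshold so they can
#' be reviewed upstream.
#'
#' @param data A cohort tibble.
#' @param age_threshold Age (years) above which `"pre"` is suspicious.
#' @return The rows flagged, as a tibble.
#' @export
flag_menopause_qc <- function(data, age_threshold = 55) {
  if (!"age" %in% names(data)) {
    return(as_tibble(data)[0, ])
  }
  dplyr::filter(as_tibble(data),
                !is.na(.data$age),
                .data$age >= age_threshold,
                .data$menopausal_status == "pre")
}
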