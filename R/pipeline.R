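marker_columns <- c(ca125 = "ca125", he4 = "he4", roma = "roma_percent")

#' Run the full stratified marker analysis
#'
#' End-to-end driver: scores the cohort with the ROMA index, then for every
#' requested stratum and marker finds (or applies) a cutoff, builds the
#' confusion table, computes the complete diagnostic metric suite and the
#' AUC, and pairwise-compares marker AUCs on the whole cohort. Stage strata
#' (early = FIGO 1-2, advanced = 3-4, each against all benign controls)
#' evaluate the ROMA index at the cutoff used for the total stratum.
#'
#' @param cohort A validated cohort tibble (see [validate_cohort()]).
#' @param cutoffs Either `NULL` (default) to optimize a Youden cutoff per
#'   stratum and marker, or a named list/vector of fixed cutoffs,
#'   e.g. `c(ca125 = 22.5, he4 = 73, roma = 18.3)`, applied in every
#'   stratum.
#' @param strata Menopausal strata to run; stage strata are controlled by
#'   `stage_strata`.
#' @param stage_strata Evaluate ROMA in the early/advanced stage strata
#'   (skipped automatically when the cohort has no stage data).
#' @param markers Markers to evaluate; `"roma"` refers to the computed
#'   `roma_percent` column.
#' @param conf_level Confidence level for every interval.
#' @param compare Run pairwise DeLong AUC comparisons on the total stratum.
#' @param boot Bootstrap replicates for the AUC-difference CI (0 = none).
#' @param seed Integer seed recorded in the run log and used for any
#'   bootstrap.
#' @return A `roma_report` object: a list of tibbles (`cutoffs`,
#'   `confusion`, `metrics`, `auc`, `comparisons`, `marker_summary`) plus
#'   the scored cohort and a `meta` run log (seed, config hash, package
#'   version). Use [tidy()], [glance()], [autoplot()] and [write_report()].
#' @export
#' @examples
#' report <- simulate_cohort(seed = 42) |> run_roma_analysis(seed = 42)
#' tidy(report)
run_roma_analysis <- function(cohort,
                              cutoffs = NULL,
                              strata = c("total", "premenopause",
                                         "postmenopause"),
                              stage_strata = TRUE,
                              markers = c("ca125", "he4", "roma"),
                              conf_level = 0.95,
                              compare = TRUE,
                              boot = 0,
                              seed = NULL) {
  cohort <- validate_cohort(cohort)
  markers <- match.arg(markers, several.ok = TRUE)
  if (!is.null(cutoffs)) {
    cutoffs <- as.list(cutoffs)
    missing_cut <- setdiff(markers, names(cutoffs))
    if (length(missing_cut) > 0) {
      abort(paste0("no fixed cutoff given for marker(s): ",
                   paste(missing_cut, collapse = ", ")),
            class = "romadx_domain_error")
    }
    if (any(unlist(cutoffs[markers]) <= 0)) {
      abort("fixed cutoffs must be positive", class = "romadx_domain_error")
    }
  }
  scored <- score_roma(cohort)

  eval_one <- function(sub, stratum, marker, cutoff_fixed) {
    col <- marker_columns[[marker]]
    withCallingHandlers(
      {
        if (is.null(cutoff_fixed)) {
          yc <- youden_cutoff(sub, !!rlang::sym(col))
          cut <- yc$cutoff
          policy <- "youden"
          j <- yc$youden_j
        } else {
          cut <- cutoff_fixed
          policy <- "fixed"
          j <- NA_real_
        }
        ev <- evaluate_marker(sub, !!rlang::sym(col), cutoff = cut,
                              conf_level = conf_level)
        a <- roc_auc(sub, !!rlang::sym(col), conf_level = conf_level)
        ct <- ev$confusion
        list(
          cutoffs = tibble(stratum = stratum, marker = marker,
                           cutoff = cut, policy = policy, youden_j = j),
          confusion = tibble(stratum = stratum, marker = marker,
                             tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn),
          metrics = dplyr::mutate(ev$metrics, stratum = stratum,
                                  marker = marker, cutoff = cut,
                                  .before = 1),
          auc = dplyr::mutate(a, stratum = stratum, marker = marker,
                              .before = 1)
        )
      },
      error = function(e) {
        abort(paste0("analysis failed in stratum '", stratum,
                     "', marker '", marker, "': ", conditionMessage(e)),
              class = "romadx_pipeline_error", parent = e)
      }
    )
  }

  results <- list()
  for (stratum in strata) {
    sub <- stratify(scored, stratum)
    for (marker in markers) {
      results[[paste(stratum, marker)]] <-
        eval_one(sub, stratum, marker,
                 if (is.null(cutoffs)) NULL else cutoffs[[marker]])
    }
  }

  run_stages <- stage_strata && "stage" %in% names(scored) &&
    any(!is.na(scored$stage[scored$pathology == "malignant"])) &&
    "roma" %in% markers
  if (run_stages) {
    total_cut <- if (is.null(cutoffs)) {
      youden_cutoff(scored, .data$roma_percent)$cutoff
    } else {
      cutoffs[["roma"]]
    }
    for (stratum in c("early_stage", "advanced_stage")) {
      sub <- stratify(scored, stratum)
      if (any(sub$pathology == "malignant")) {
        results[[paste(stratum, "roma")]] <-
          eval_one(sub, stratum, "roma", total_cut)
      }
    }
  }

  pick <- function(field) purrr::map_dfr(results, field)
  comparisons <- NULL
  if (compare && length(markers) > 1) {
    pairs <- utils::combn(markers, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(p) {
      dplyr::mutate(
        compare_auc(scored,
                    !!rlang::sym(marker_columns[[p[1]]]),
                    !!rlang::sym(marker_columns[[p[2]]]),
                    boot = boot, seed = seed, conf_level = conf_level),
        stratum = "total", marker_a = p[1], marker_b = p[2], .before = 1)
    })
  }

  config <- list(cutoffs = cutoffs, strata = strata,
                 stage_strata = stage_strata, markers = markers,
                 conf_level = conf_level, compare = compare, boot = boot,
                 seed = seed)
  structure(
    list(
      cohort = scored,
      counts = cohort_counts(scored),
      marker_summary = summarize_markers(
        scored, unname(marker_columns[markers])),
      cutoffs = pick("cutoffs"),
      confusion = pick("confusion"),
      metrics = pick("metrics"),
      auc = pick("auc"),
      comparisons = comparisons,
      meta = tibble(
        package = "romadx",
        version = as.character(packageVersion("romadx")),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        config_hash = rlang::hash(config),
        n = nrow(cohort),
        n_benign = sum(cohort$pathology == "benign"),
        n_malignant = sum(cohort$pathology == "malignant")
      )
    ),
    class = "roma_report"
  )
}

#' @export
print.roma_report <- function(x, ...) {
  cat("ROMA analysis report —", x$meta$n, "patients (",
      x$meta$n_benign, "benign /", x$meta$n_malignant, "malignant )\n")
  cat("Cutoffs:\n")
  print(x$cutoffs, n = Inf)
  cat("AUC:\n")
  print(x$auc, n = Inf)
  invisible(x)
}

#' @rdname run_roma_analysis
#' @param x A `roma_report` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.roma_report <- function(x, ...) {
  x$metrics
}

#' @rdname run_roma_analysis
#' @exportS3Method generics::glance
glance.roma_report <- function(x, ...) {
  total_roma <- dplyr::filter(x$auc, .data$stratum == "total",
                              .data$marker == "roma")
  tibble(
    n = x$meta$n,
    n_benign = x$meta$n_benign,
    n_malignant = x$meta$n_malignant,
    roma_auc = if (nrow(total_roma) == 1) total_roma$auc else NA_real_,
    seed = x$meta$seed,
    config_hash = x$meta$config_hash
  )
}

# Replace non-finite values by NA so JSON and TSV renderings agree.
sanitize_df <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric),
    function(v) ifelse(is.finite(v) | is.na(v), v, NA_real_)
  ))
}

percent_metrics <- c("sensitivity", "specificity", "ppv", "npv",
                     "diagnostic_accuracy")

# Paper-style rounded rendering of the metrics table: percent metrics to one
# decimal, ratio-scale metrics and kappa to two, CIs to two. Input may be the
# in-memory tibble or the data frame re-read from report.json.
render_metrics <- function(metrics) {
  metrics <- sanitize_df(as_tibble(metrics))
  fmt <- function(v, digits) ifelse(is.na(v), "-", sprintf(paste0("%.", digits, "f"), v))
  dplyr::transmute(
    metrics,
    stratum = .data$stratum, marker = .data$marker,
    cutoff = fmt(.data$cutoff, 2), metric = .data$metric,
    estimate = ifelse(.data$metric %in% percent_metrics,
                      fmt(.data$estimate, 1), fmt(.data$estimate, 2)),
    conf.low = fmt(.data$conf.low, 2), conf.high = fmt(.data$conf.high, 2),
    method = .data$method
  )
}

#' Write a deterministic report bundle
#'
#' Serializes a [run_roma_analysis()] report to a directory:
#' `report.json` with unrounded values (non-finite values become `null`),
#' and TSV tables (`metrics.tsv` with paper-style rounding, plus
#' `confusion.tsv`, `cutoffs.tsv`, `auc.tsv`, `comparisons.tsv`,
#' `marker_summary.tsv`, `run_log.tsv`). Output contains no timestamps:
#' identical report objects produce byte-identical bundles.
#'
#' @param report A `roma_report`.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
#' @examples
#' report <- simulate_cohort(seed = 42) |> run_roma_analysis(seed = 42)
#' write_report(report, tempfile())
write_report <- function(report, dir) {
  stopifnot(inherits(report, "roma_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put_tsv <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }

  json <- list(
    meta = report$meta,
    counts = report$counts,
    cutoffs = report$cutoffs,
    confusion = report$confusion,
    metrics = sanitize_df(report$metrics),
    auc = report$auc,
    comparisons = if (is.null(report$comparisons)) NULL else
      sanitize_df(report$comparisons),
    marker_summary = report$marker_summary
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(json[!vapply(json, is.null, logical(1))], json_path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  paths <- c(paths, json_path)

  put_tsv(render_metrics(report$metrics), "metrics.tsv")
  put_tsv(report$confusion, "confusion.tsv")
  put_tsv(dplyr::mutate(report$cutoffs,
                        dplyr::across(dplyr::where(is.numeric),
                                      function(v) round(v, 4))),
          "cutoffs.tsv")
  put_tsv(dplyr::mutate(report$auc,
                        dplyr::across(dplyr::where(is.numeric),
                                      function(v) round(v, 4))),
          "auc.tsv")
  if (!is.null(report$comparisons)) {
    put_tsv(dplyr::mutate(sanitize_df(report$comparisons),
                          dplyr::across(dplyr::where(is.numeric),
                                        function(v) round(v, 4))),
            "comparisons.tsv")
  }
  put_tsv(dplyr::mutate(report$marker_summary,
                        dplyr::across(dplyr::where(is.numeric),
                                      function(v) round(v, 2))),
          "marker_summary.tsv")
  put_tsv(report$meta, "run_log.tsv")
  invisible(paths)
}

#' @rdname roc_curve
#' @param object A `roc_curve` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "Empirical ROC curve") +
    ggplot2::theme_minimal()
}

#' ROC curves for every marker in a report
#'
#' @param object A `roma_report`.
#' @param stratum Stratum whose curves to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roma_report <- function(object, stratum = "total", ...) {
  sub <- stratify(object$cohort, stratum)
  markers <- unique(object$auc$marker)
  curves <- purrr::map_dfr(markers, function(m) {
    cv <- roc_curve(sub, !!rlang::sym(marker_columns[[m]]))
    dplyr::mutate(as_tibble(cv), marker = m)
  })
  aucs <- dplyr::filter(object$auc, .data$stratum == !!stratum)
  labels <- setNames(sprintf("%s (AUC %.3f)", aucs$marker, aucs$auc),
                     aucs$marker)
  ggplot2::ggplot(curves, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity,
                                       colour = .data$marker)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_colour_discrete(labels = labels, name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = paste("ROC curves,", stratum, "stratum")) +
    ggplot2::theme_minimal()
}
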