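#' Serialize / read a risk model
#'
#' JSON document with fields `intercept, beta_igf1, beta_sepsis, outcome_def,
#' fitted_on_n, converged`.
#'
#' @param model A `rop_logistic` model.
#' @param path JSON file path.
#' @return `path` (write) or a `rop_logistic` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rop_logistic"))
  jsonlite::write_json(
    list(intercept = model$intercept, beta_igf1 = model$beta_igf1,
         beta_sepsis = model$beta_sepsis, outcome_def = model$outcome_def,
         fitted_on_n = model$fitted_on_n, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  logistic_model(intercept = doc$intercept, beta_igf1 = doc$beta_igf1,
                 beta_sepsis = doc$beta_sepsis,
                 converged = isTRUE(doc$converged),
                 outcome_def = doc$outcome_def %||% "any_rop",
                 fitted_on_n = doc$fitted_on_n %||% NA_integer_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Serialize / read cohort generation parameters
#'
#' JSON config document whose keys are exactly the [cohort_params()] field
#' names; the generative risk model is nested under `rop_model`.
#'
#' @param params A `cohort_params` object.
#' @param path JSON file path.
#' @return `path` (write) or a `cohort_params` (read).
#' @export
write_params <- function(params, path) {
  doc <- unclass(params)
  # named vectors become JSON objects, not bare arrays, so names survive
  for (f in c("igf1_w3_mean_by_risk", "sepsis_rate_by_risk",
              "pct_increase_mean_by_grade")) {
    doc[[f]] <- as.list(doc[[f]])
  }
  doc$rop_model <- list(intercept = params$rop_model$intercept,
                        beta_igf1 = params$rop_model$beta_igf1,
                        beta_sepsis = params$rop_model$beta_sepsis)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- logistic_model(intercept = doc$rop_model$intercept,
                          beta_igf1 = doc$rop_model$beta_igf1,
                          beta_sepsis = doc$rop_model$beta_sepsis)
  cohort_params(
    n = doc$n, ga_range_weeks = doc$ga_range_weeks,
    bw_range_g = doc$bw_range_g, high_risk_frac = doc$high_risk_frac,
    igf1_w3_mean_by_risk = unlist(doc$igf1_w3_mean_by_risk),
    igf1_w3_sd = doc$igf1_w3_sd,
    sepsis_rate_by_risk = unlist(doc$sepsis_rate_by_risk),
    rop_model = model, p_proliferative = doc$p_proliferative,
    pct_increase_mean_by_grade = unlist(doc$pct_increase_mean_by_grade),
    pct_increase_sd = doc$pct_increase_sd,
    ga_bw_coupling = doc$ga_bw_coupling,
    week5_missing_rate = doc$week5_missing_rate,
    seed = doc$seed)
}

#' Simulate a cohort and write it with provenance
#'
#' Generates the cohort, writes `cohort.csv` plus a `cohort_params.json`
#' provenance sidecar (parameters, seed, package version) into `out_dir`.
#'
#' @param params A [cohort_params()] object.
#' @param out_dir Output directory (created if needed).
#' @return Named paths, invisibly.
#' @export
run_simulate <- function(params, out_dir) {
  validate_cohort_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(params)
  cohort_path <- file.path(out_dir, "cohort.csv")
  params_path <- file.path(out_dir, "cohort_params.json")
  write_cohort(cohort, cohort_path)
  doc_params <- params
  write_params(doc_params, params_path)
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(seed = params$seed, n = params$n,
         package = "ropscreen",
         version = as.character(utils::packageVersion("ropscreen"))),
    prov, auto_unbox = TRUE)
  invisible(c(cohort = cohort_path, params = params_path,
              provenance = prov))
}

#' Validate the screening rule against outcomes
#'
#' Two input modes (exactly one): a cohort (stratified with `model` and
#' `config`, tabulated against its own outcomes) or printed 2x2 counts
#' (`counts = c(tp=, fp=, fn=, tn=)`) for reproducing published tables
#' without patient-level data.
#'
#' @param cohort Optional cohort data frame.
#' @param counts Optional named count vector `c(tp, fp, fn, tn)`.
#' @param model `rop_logistic` model (cohort mode).
#' @param config [rule_config()] (cohort mode; default validated variant).
#' @param out_dir Optional directory for `validation_summary.csv` and
#'   `validation_report.txt`.
#' @return List with `table` ([contingency_2x2()]), `summary`
#'   (diagnostic summary tibble), `fractions` ([screening_fractions()]
#'   including the mandatory tier in cohort mode as attribute `"counts"`),
#'   and `report` (text lines).
#' @export
run_validate <- function(cohort = NULL, counts = NULL, model = NULL,
                         config = rule_config("validated"),
                         out_dir = NULL) {
  if (is.null(cohort) == is.null(counts)) {
    stop("run_validate: supply exactly one of 'cohort' or 'counts'",
         call. = FALSE)
  }
  tier_counts <- NULL
  if (!is.null(counts)) {
    need <- c("tp", "fp", "fn", "tn")
    if (!all(need %in% names(counts))) {
      stop("run_validate: counts must be named tp, fp, fn, tn",
           call. = FALSE)
    }
    tab <- contingency_2x2(counts[["tp"]], counts[["fp"]], counts[["fn"]],
                           counts[["tn"]])
  } else {
    validate_cohort(cohort)
    decisions <- stratify_cohort(cohort, model, config)
    tier_counts <- attr(decisions, "counts")
    tab <- build_table(decisions, cohort)
  }
  summary <- summarize_table(tab)
  n_total <- tab$tp + tab$fp + tab$fn + tab$tn
  fractions <- screening_fractions(n_total, tab$tp + tab$fp)
  if (!is.null(tier_counts)) attr(fractions, "counts") <- tier_counts
  report <- c(
    sprintf("screening validation on %d triaged infants (tp=%d fp=%d fn=%d tn=%d)",
            n_total, tab$tp, tab$fp, tab$fn, tab$tn),
    format_diagnostic_report(summary))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(summary, file.path(out_dir, "validation_summary.csv"))
    writeLines(report, file.path(out_dir, "validation_report.txt"))
  }
  list(table = tab, summary = summary, fractions = fractions,
       report = report)
}

#' Per-grade IGF1 trajectory report
#'
#' Emits the per-grade trajectory summary ([summarize_by_grade()]) including
#' the five-number summaries needed to redraw the percentage-increase box
#' plot, plus the across-grade one-way ANOVA.
#'
#' @param cohort Cohort data frame.
#' @param out_dir Optional directory for `trajectory_summary.csv`.
#' @return List with `summary` (per-grade tibble), `anova` (`TestResult` or
#'   NULL when fewer than two grades have enough data), and `message`.
#' @export
run_trajectory <- function(cohort, out_dir = NULL) {
  validate_cohort(cohort)
  summary <- summarize_by_grade(cohort)
  available <- summary$available
  if (!any(available)) {
    return(list(summary = summary, anova = NULL,
                message = paste("no ROP grade has >= 2 complete week-3/",
                                "week-5 trajectories; nothing to summarise",
                                sep = "")))
  }
  anova <- NULL
  if (sum(available) >= 2) {
    groups <- lapply(ROP_GRADES[available], function(g) {
      keep <- cohort$rop_grade == g & !is.na(cohort$igf1_w5)
      pct_increase(cohort$igf1_w3[keep], cohort$igf1_w5[keep])
    })
    if (length(unique(unlist(groups))) > 1) anova <- anova_oneway(groups)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(summary, file.path(out_dir, "trajectory_summary.csv"))
  }
  list(summary = summary, anova = anova,
       message = sprintf("%d grade(s) summarised", sum(available)))
}
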