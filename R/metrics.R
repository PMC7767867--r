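#' Round half-up
#'
#' Decimal rounding with halves away from zero (9.375 -> 9.4 at one
#' decimal), matching the display convention of clinical tables, unlike
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # tiny fuzz absorbs binary representation error (e.g. 80.6499999...95)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Closed form via beta quantiles: lower \eqn{= B(\alpha/2; k, n-k+1)}
#' (0 when k = 0), upper \eqn{= B(1-\alpha/2; k+1, n-k)} (1 when k = n).
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  alpha <- 1 - conf_level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' 2x2 screening-vs-outcome contingency table
#'
#' Rows are the risk tier (high vs low), columns the observed ROP outcome:
#' `tp` high-risk with ROP, `fp` high-risk without, `fn` low-risk with ROP,
#' `tn` low-risk without.
#'
#' @param tp,fp,fn,tn Non-negative integer counts, total >= 1.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("contingency_2x2: counts must be non-negative integers",
         call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("contingency_2x2: table must contain at least one observation",
         call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("high_risk", "low_risk"),
                              c("ROP", "no ROP")))
  print(m)
  invisible(x)
}

#' Build the validation 2x2 table from decisions and outcomes
#'
#' Mandatory-tier infants are excluded: the validation concerns only infants
#' above the mandatory thresholds, triaged by predicted probability. ROP is
#' defined as any grade other than `none`.
#'
#' @param decisions Decision tibble from [stratify_cohort()] (needs
#'   `infant_id`, `tier`).
#' @param outcomes Data frame with `infant_id` and `rop_grade` (a cohort
#'   works directly).
#' @return A [contingency_2x2()].
#' @export
build_table <- function(decisions, outcomes) {
  missing_ids <- setdiff(decisions$infant_id, outcomes$infant_id)
  if (length(missing_ids) > 0) {
    stop("build_table: no outcome for infant_id(s) ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...", call. = FALSE)
  }
  keep <- decisions$tier %in% c("high_risk", "low_risk")
  dec <- decisions[keep, , drop = FALSE]
  if (nrow(dec) == 0) {
    stop("build_table: no non-mandatory infants to tabulate", call. = FALSE)
  }
  grade <- outcomes$rop_grade[match(dec$infant_id, outcomes$infant_id)]
  rop <- grade != "none"
  high <- dec$tier == "high_risk"
  contingency_2x2(tp = sum(high & rop), fp = sum(high & !rop),
                  fn = sum(!high & rop), tn = sum(!high & !rop))
}

metric_row <- function(metric, k, n, conf_level) {
  if (n == 0) {
    return(tibble::tibble(metric = metric, numerator = NA_integer_,
                          denominator = 0L, estimate = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          percent_display = NA_real_, defined = FALSE))
  }
  ci <- clopper_pearson(k, n, conf_level)
  est <- k / n
  tibble::tibble(metric = metric, numerator = as.integer(k),
                 denominator = as.integer(n), estimate = est,
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                 percent_display = round_half_up(100 * est, 1),
                 defined = TRUE)
}

#' Diagnostic accuracy summary of a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
#' NPV tn/(tn+fn), each with an exact Clopper-Pearson confidence interval
#' and a display value in percent rounded half-up to one decimal. A metric
#' whose denominator is zero is returned as undefined (`defined = FALSE`),
#' not an error.
#'
#' @param table A [contingency_2x2()].
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A `diagnostic_summary`: tibble with one row per metric
#'   (sensitivity, specificity, ppv, npv, high_risk_fraction,
#'   low_risk_fraction) and columns `numerator, denominator, estimate,
#'   ci_lower, ci_upper, percent_display, defined`.
#' @export
summarize_table <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  n_total <- table$tp + table$fp + table$fn + table$tn
  n_high <- table$tp + table$fp
  out <- rbind(
    metric_row("sensitivity", table$tp, table$tp + table$fn, conf_level),
    metric_row("specificity", table$tn, table$tn + table$fp, conf_level),
    metric_row("ppv", table$tp, table$tp + table$fp, conf_level),
    metric_row("npv", table$tn, table$tn + table$fn, conf_level),
    metric_row("high_risk_fraction", n_high, n_total, conf_level),
    metric_row("low_risk_fraction", n_total - n_high, n_total, conf_level)
  )
  class(out) <- c("diagnostic_summary", class(out))
  out
}

#' Screened and excluded fractions
#'
#' Fractions of the triaged population deemed high risk (screened serially)
#' and low risk (excluded from serial screening); they are exact complements
#' before display rounding.
#'
#' @param n_total Total triaged infants (>= 1).
#' @param n_high_risk High-risk infants, `0 <= n_high_risk <= n_total`.
#' @return Tibble with `tier`, `n`, `fraction`, `percent_display`.
#' @export
screening_fractions <- function(n_total, n_high_risk) {
  if (n_total < 1 || n_high_risk < 0 || n_high_risk > n_total ||
      n_total != floor(n_total) || n_high_risk != floor(n_high_risk)) {
    stop("screening_fractions: need 0 <= n_high_risk <= n_total, n_total >= 1",
         call. = FALSE)
  }
  high <- n_high_risk / n_total
  low <- (n_total - n_high_risk) / n_total
  tibble::tibble(
    tier = c("high_risk", "low_risk"),
    n = c(n_high_risk, n_total - n_high_risk),
    fraction = c(high, low),
    percent_display = round_half_up(100 * c(high, low), 1)
  )
}

#' Render a diagnostic summary as aligned text
#'
#' @param summary A `diagnostic_summary` from [summarize_table()].
#' @return Character vector of report lines, invisibly printed.
#' @export
format_diagnostic_report <- function(summary) {
  lines <- c(sprintf("%-20s %9s %18s", "metric", "percent", "95% CI (exact)"),
             vapply(seq_len(nrow(summary)), function(i) {
               r <- summary[i, ]
               if (!r$defined) {
                 sprintf("%-20s %9s %18s", r$metric, "undef.", "-")
               } else {
                 sprintf("%-20s %8.1f%% %8.1f - %6.1f%%", r$metric,
                         r$percent_display, 100 * r$ci_lower,
                         100 * r$ci_upper)
               }
             }, character(1)))
  lines
}
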