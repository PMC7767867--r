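#' Week-3 to week-5 IGF1 percentage increase
#'
#' \eqn{100 (IGF1_{5w} - IGF1_{3w}) / IGF1_{3w}}; negative when levels fall.
#' Scale-invariant: multiplying both measurements by the same positive factor
#' leaves it unchanged.
#'
#' @param igf1_w3,igf1_w5 Week-3 and week-5 IGF1, ng/ml, both > 0.
#'   Vectorised; `igf1_w5` may be NA (propagated).
#' @return Percentage increase.
#' @export
pct_increase <- function(igf1_w3, igf1_w5) {
  if (any(!is.finite(igf1_w3) | igf1_w3 <= 0)) {
    stop("pct_increase: igf1_w3 must be finite and > 0", call. = FALSE)
  }
  if (any(igf1_w5 <= 0, na.rm = TRUE)) {
    stop("pct_increase: igf1_w5 must be > 0", call. = FALSE)
  }
  100 * (igf1_w5 - igf1_w3) / igf1_w3
}

#' IGF1 trajectory summary by ROP grade
#'
#' For each ROP grade, the mean percentage increase with a symmetric
#' t-interval (mean +/- t(0.975, n-1) * s / sqrt(n)) and quartiles by linear
#' interpolation (the five-number summary behind a box plot). Infants
#' lacking the week-5 measurement are excluded and counted; a grade with
#' fewer than two complete records is marked unavailable rather than
#' summarised.
#'
#' @param cohort Cohort data frame with `igf1_w3`, `igf1_w5`, `rop_grade`.
#' @param conf_level Confidence level for the mean interval (default 0.95).
#' @return Tibble with one row per grade: `grade, n, n_missing_w5,
#'   mean_pct_increase, ci_lower, ci_upper, min, q1, median, q3, max,
#'   available`.
#' @export
summarize_by_grade <- function(cohort, conf_level = 0.95) {
  rows <- lapply(ROP_GRADES, function(g) {
    in_grade <- cohort$rop_grade == g
    complete <- in_grade & !is.na(cohort$igf1_w5)
    n <- sum(complete)
    n_missing <- sum(in_grade) - n
    if (n < 2) {
      return(tibble::tibble(
        grade = g, n = n, n_missing_w5 = n_missing,
        mean_pct_increase = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_, min = NA_real_, q1 = NA_real_,
        median = NA_real_, q3 = NA_real_, max = NA_real_,
        available = FALSE))
    }
    d <- pct_increase(cohort$igf1_w3[complete], cohort$igf1_w5[complete])
    m <- mean(d)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(d) / sqrt(n)
    q <- stats::quantile(d, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                         type = 7)
    tibble::tibble(
      grade = g, n = n, n_missing_w5 = n_missing,
      mean_pct_increase = m, ci_lower = m - half, ci_upper = m + half,
      min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
      available = TRUE)
  })
  do.call(rbind, rows)
}
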