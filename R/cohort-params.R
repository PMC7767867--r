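#' ROP grade levels
#'
#' Ordered severity levels used throughout the package: no retinopathy,
#' non-proliferative disease, proliferative disease.
#' @export
ROP_GRADES <- c("none", "non_proliferative", "proliferative")

#' Logistic ROP risk model
#'
#' Container for the probability-of-ROP model
#' \eqn{P(ROP) = logit^{-1}(\beta_0 + \beta_1 \cdot IGF1_{3w} + \beta_2 \cdot sepsis)}.
#' The original study's probability-curve coefficients were never published;
#' models of this class are either fitted from data ([fit_logistic()]) or
#' reconstructed by calibration ([calibrate_rop_model()]).
#'
#' @param intercept Intercept on the log-odds scale.
#' @param beta_igf1 Log-odds change per ng/ml of week-3 IGF1 (negative:
#'   lower IGF1 means higher risk).
#' @param beta_sepsis Log-odds change for sepsis during the first 3 weeks.
#' @param converged Logical convergence flag (TRUE for hand-specified models).
#' @param n_iter IRLS iteration count (0 for hand-specified models).
#' @param loglik Log-likelihood at the optimum, if fitted.
#' @param se Optional named standard errors of the three coefficients.
#' @param outcome_def Outcome definition the model targets:
#'   `"any_rop"` or `"proliferative_only"`.
#' @param fitted_on_n Number of records the model was fitted on, if any.
#' @param separation Logical; TRUE when fitting detected (quasi-)complete
#'   separation.
#' @return An object of class `rop_logistic`.
#' @export
logistic_model <- function(intercept, beta_igf1, beta_sepsis,
                           converged = TRUE, n_iter = 0L, loglik = NA_real_,
                           se = NULL, outcome_def = "any_rop",
                           fitted_on_n = NA_integer_, separation = FALSE) {
  coefs <- c(intercept = intercept, beta_igf1 = beta_igf1,
             beta_sepsis = beta_sepsis)
  if (isTRUE(converged) && !all(is.finite(coefs))) {
    stop("logistic_model: all coefficients must be finite when converged",
         call. = FALSE)
  }
  structure(
    list(intercept = intercept, beta_igf1 = beta_igf1,
         beta_sepsis = beta_sepsis, converged = converged,
         n_iter = as.integer(n_iter), loglik = loglik, se = se,
         outcome_def = outcome_def, fitted_on_n = fitted_on_n,
         separation = separation),
    class = "rop_logistic"
  )
}

#' @export
print.rop_logistic <- function(x, ...) {
  cat("Logistic ROP risk model (P(ROP) ~ IGF1 week 3 + sepsis <= 3w)\n")
  cat(sprintf("  intercept:   %+.6f\n", x$intercept))
  cat(sprintf("  beta_igf1:   %+.6f  (log-odds per ng/ml)\n", x$beta_igf1))
  cat(sprintf("  beta_sepsis: %+.6f\n", x$beta_sepsis))
  cat(sprintf("  converged: %s after %d iterations", x$converged, x$n_iter))
  if (isTRUE(x$separation)) cat("  [separation detected]")
  cat("\n")
  invisible(x)
}

# CDF of a normal truncated below at `lower`.
ptruncnorm_lower <- function(q, mean, sd, lower) {
  if (all(sd == 0)) return(as.numeric(q >= pmax(mean, lower)))
  a <- stats::pnorm((lower - mean) / sd)
  pmin(1, pmax(0, (stats::pnorm((q - mean) / sd) - a) / (1 - a)))
}

#' Calibrate a reference risk model to a target high-risk fraction
#'
#' The study never printed the probability-curve coefficients, only that
#' 20.9% of the validation cohort exceeded the 30% probability cut-off.
#' This reconstructs a reference model: the slopes are fixed and the
#' intercept is solved (by `uniroot` on the analytic mixture distribution of
#' the linear predictor implied by `params`) so that the expected fraction of
#' infants with predicted probability above `probability_cutoff` equals
#' `target_high_risk`. The result is a *reconstruction*, not a published
#' parameter set.
#'
#' @param params A [cohort_params()] object supplying the IGF1/sepsis mixture
#'   (its `rop_model` field is ignored).
#' @param beta_igf1,beta_sepsis Fixed slopes of the reconstruction.
#' @param probability_cutoff High-risk probability threshold (default 0.30).
#' @param target_high_risk Target expected high-risk fraction
#'   (default 0.209, the prospective cohort's 32/153).
#' @return A `rop_logistic` model.
#' @export
calibrate_rop_model <- function(params, beta_igf1 = -0.15, beta_sepsis = 1.5,
                                probability_cutoff = 0.30,
                                target_high_risk = 0.209) {
  stopifnot(beta_igf1 < 0)
  cut_logit <- stats::qlogis(probability_cutoff)
  w_high <- params$high_risk_frac
  strata <- data.frame(
    w = c((1 - w_high) * (1 - params$sepsis_rate_by_risk[["low"]]),
          (1 - w_high) * params$sepsis_rate_by_risk[["low"]],
          w_high * (1 - params$sepsis_rate_by_risk[["high"]]),
          w_high * params$sepsis_rate_by_risk[["high"]]),
    mean = c(params$igf1_w3_mean_by_risk[["low"]],
             params$igf1_w3_mean_by_risk[["low"]],
             params$igf1_w3_mean_by_risk[["high"]],
             params$igf1_w3_mean_by_risk[["high"]]),
    sepsis = c(0, 1, 0, 1)
  )
  # P(high risk) = P(b0 + b1*igf1 + b2*sepsis > logit(cut)); b1 < 0 flips to
  # an IGF1 lower-tail probability within each (stratum, sepsis) cell.
  expected_fraction <- function(b0) {
    thr <- (cut_logit - b0 - beta_sepsis * strata$sepsis) / beta_igf1
    sum(strata$w * ptruncnorm_lower(thr, strata$mean, params$igf1_w3_sd,
                                    lower = 1))
  }
  b0 <- stats::uniroot(function(b0) expected_fraction(b0) - target_high_risk,
                       interval = c(-30, 30), tol = 1e-10)$root
  logistic_model(intercept = b0, beta_igf1 = beta_igf1,
                 beta_sepsis = beta_sepsis)
}

#' Parameters governing synthetic cohort generation
#'
#' Defaults state the validation cohort of the source study: infants of
#' 30-32 weeks gestation and 1,250-1,500 g, a latent high-risk stratum of
#' 20.9% with week-3 IGF1 means of 51 (low-risk) vs 30.48 ng/ml (high-risk),
#' sepsis prevalence 6.6% vs 15.6%, and mean week-3 to week-5 IGF1 percentage
#' increases of 14.10 / 21.47 / 28.97% for no-ROP / non-proliferative /
#' proliferative grades. Standard deviations are not printed in the source
#' and default to 15 ng/ml (IGF1) and 30 percentage points (increase).
#'
#' @param n Cohort size (>= 1).
#' @param ga_range_weeks Gestational-age range in decimal weeks, `c(min, max)`.
#' @param bw_range_g Birth-weight range in grams, `c(min, max)`.
#' @param high_risk_frac Latent high-risk stratum fraction in (0, 1).
#' @param igf1_w3_mean_by_risk Named pair `c(low = , high = )` of week-3 IGF1
#'   means, ng/ml.
#' @param igf1_w3_sd Common IGF1 standard deviation, ng/ml (> 0); draws are
#'   truncated below at 1 ng/ml.
#' @param sepsis_rate_by_risk Named pair `c(low = , high = )` of sepsis
#'   probabilities in \[0, 1\].
#' @param rop_model `rop_logistic` generative truth for
#'   P(ROP | IGF1, sepsis); `NULL` (default) calibrates a reference model
#'   with [calibrate_rop_model()].
#' @param p_proliferative P(proliferative | ROP) in \[0, 1\]; the validation
#'   cohort contained no proliferative cases, so this is configurable with
#'   default 0.2 so all three grades occur.
#' @param pct_increase_mean_by_grade Named triple
#'   `c(none = , non_proliferative = , proliferative = )` of mean week-3 to
#'   week-5 percentage increases.
#' @param pct_increase_sd Common SD of the percentage increase (> 0); draws
#'   are truncated below so week-5 IGF1 stays positive.
#' @param ga_bw_coupling Weight placed on gestational age when positioning
#'   birth weight inside its range, in \[0, 1\] (0 = independent; default 0.3
#'   gives the mild positive GA-weight correlation seen in such cohorts).
#' @param week5_missing_rate Probability a record lacks the week-5 IGF1
#'   measurement, in \[0, 1\] (default 0).
#' @param seed Integer seed; identical parameters give bit-identical cohorts.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n = 153L,
                          ga_range_weeks = c(30, 32),
                          bw_range_g = c(1250, 1500),
                          high_risk_frac = 0.209,
                          igf1_w3_mean_by_risk = c(low = 51, high = 30.48),
                          igf1_w3_sd = 15,
                          sepsis_rate_by_risk = c(low = 0.066, high = 0.156),
                          rop_model = NULL,
                          p_proliferative = 0.2,
                          pct_increase_mean_by_grade = c(
                            none = 14.10, non_proliferative = 21.47,
                            proliferative = 28.97),
                          pct_increase_sd = 30,
                          ga_bw_coupling = 0.3,
                          week5_missing_rate = 0,
                          seed = 1L) {
  params <- structure(
    list(n = n, ga_range_weeks = ga_range_weeks, bw_range_g = bw_range_g,
         high_risk_frac = high_risk_frac,
         igf1_w3_mean_by_risk = igf1_w3_mean_by_risk,
         igf1_w3_sd = igf1_w3_sd,
         sepsis_rate_by_risk = sepsis_rate_by_risk,
         rop_model = rop_model, p_proliferative = p_proliferative,
         pct_increase_mean_by_grade = pct_increase_mean_by_grade,
         pct_increase_sd = pct_increase_sd,
         ga_bw_coupling = ga_bw_coupling,
         week5_missing_rate = week5_missing_rate,
         seed = seed),
    class = "cohort_params"
  )
  validate_cohort_params(params)
  if (is.null(params$rop_model)) {
    params$rop_model <- calibrate_rop_model(params)
  }
  params
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid cohort_params: field '%s' %s", field, msg),
       call. = FALSE)
}

check_named_pair <- function(x, field, names_needed) {
  if (length(x) != length(names_needed) ||
      !all(names_needed %in% names(x))) {
    fail_field(field, sprintf("must be a named vector with names %s",
                              paste(names_needed, collapse = ", ")))
  }
  if (!all(is.finite(x))) fail_field(field, "must be finite")
}

#' Validate cohort generation parameters
#'
#' Checks every invariant of [cohort_params()]; errors name the offending
#' field.
#' @param params A `cohort_params` object (or bare list with the same fields).
#' @return `params`, invisibly, if valid.
#' @export
validate_cohort_params <- function(params) {
  p <- params
  if (!is.numeric(p$n) || length(p$n) != 1 || is.na(p$n) || p$n < 1 ||
      p$n != floor(p$n)) {
    fail_field("n", "must be a single integer >= 1")
  }
  for (f in c("ga_range_weeks", "bw_range_g")) {
    r <- p[[f]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] <= 0 || r[1] >= r[2]) {
      fail_field(f, "must be c(min, max) with 0 < min < max")
    }
  }
  if (!is.finite(p$high_risk_frac) || p$high_risk_frac < 0 ||
      p$high_risk_frac > 1) {
    fail_field("high_risk_frac", "must be in [0, 1]")
  }
  check_named_pair(p$igf1_w3_mean_by_risk, "igf1_w3_mean_by_risk",
                   c("low", "high"))
  if (any(p$igf1_w3_mean_by_risk <= 0)) {
    fail_field("igf1_w3_mean_by_risk", "means must be > 0")
  }
  if (!is.finite(p$igf1_w3_sd) || p$igf1_w3_sd < 0) {
    fail_field("igf1_w3_sd", "must be >= 0")
  }
  check_named_pair(p$sepsis_rate_by_risk, "sepsis_rate_by_risk",
                   c("low", "high"))
  if (any(p$sepsis_rate_by_risk < 0 | p$sepsis_rate_by_risk > 1)) {
    fail_field("sepsis_rate_by_risk", "rates must be in [0, 1]")
  }
  if (!is.null(p$rop_model) && !inherits(p$rop_model, "rop_logistic")) {
    fail_field("rop_model", "must be a rop_logistic model or NULL")
  }
  if (!is.finite(p$p_proliferative) || p$p_proliferative < 0 ||
      p$p_proliferative > 1) {
    fail_field("p_proliferative", "must be in [0, 1]")
  }
  check_named_pair(p$pct_increase_mean_by_grade, "pct_increase_mean_by_grade",
                   ROP_GRADES)
  if (!is.finite(p$pct_increase_sd) || p$pct_increase_sd < 0) {
    fail_field("pct_increase_sd", "must be >= 0")
  }
  if (!is.finite(p$ga_bw_coupling) || p$ga_bw_coupling < 0 ||
      p$ga_bw_coupling > 1) {
    fail_field("ga_bw_coupling", "must be in [0, 1]")
  }
  if (!is.finite(p$week5_missing_rate) || p$week5_missing_rate < 0 ||
      p$week5_missing_rate > 1) {
    fail_field("week5_missing_rate", "must be in [0, 1]")
  }
  if (!is.numeric(p$seed) || length(p$seed) != 1 || is.na(p$seed) ||
      p$seed != floor(p$seed)) {
    fail_field("seed", "must be a single integer")
  }
  invisible(params)
}
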