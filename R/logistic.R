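logistic_loglik <- function(y, eta) {
  # log(1 + exp(eta)) computed stably as max(eta, 0) + log1p(exp(-|eta|))
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Fit the logistic ROP risk model by IRLS
#'
#' Maximum-likelihood logistic regression of the ROP outcome on week-3 IGF1
#' and the sepsis flag, by iteratively reweighted least squares from an
#' all-zero start. Convergence is declared when the largest absolute
#' coefficient update falls below `tol` (default 1e-8) within `max_iter`
#' (default 100) iterations; the weighted normal equations carry a 1e-8
#' ridge for numerical safety, and steps are halved whenever a full Newton
#' step would decrease the log-likelihood, so the log-likelihood is
#' non-decreasing across iterations.
#'
#' Perfect separation is reported via the `separation` / `converged` flags
#' rather than returned as silently diverged coefficients.
#'
#' @param cohort Cohort data frame with `igf1_w3`, `sepsis_w3`, `rop_grade`.
#' @param outcome_def `"any_rop"` (ROP of any grade) or
#'   `"proliferative_only"`.
#' @param tol,max_iter Convergence controls.
#' @return A `rop_logistic` model with coefficients, standard errors
#'   (`$se`), covariance (`$vcov`), `loglik`, the per-iteration
#'   log-likelihood trace (`$loglik_trace`), and convergence flags.
#' @export
fit_logistic <- function(cohort, outcome_def = c("any_rop",
                                                 "proliferative_only"),
                         tol = 1e-8, max_iter = 100L) {
  outcome_def <- match.arg(outcome_def)
  if (nrow(cohort) < 10) {
    stop("fit_logistic: need at least 10 records", call. = FALSE)
  }
  y <- if (outcome_def == "any_rop") {
    as.numeric(cohort$rop_grade != "none")
  } else {
    as.numeric(cohort$rop_grade == "proliferative")
  }
  if (length(unique(y)) < 2) {
    stop("fit_logistic: outcome has a single class; both classes required",
         call. = FALSE)
  }
  X <- cbind(1, cohort$igf1_w3, cohort$sepsis_w3)
  beta <- c(0, 0, 0)
  eta <- drop(X %*% beta)
  ll <- logistic_loglik(y, eta)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    XtWX <- crossprod(X, X * w) + diag(1e-8, ncol(X))
    delta <- drop(solve(XtWX, crossprod(X, y - mu)))
    # step-halving keeps the log-likelihood monotone
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- logistic_loglik(y, drop(X %*% beta_new))
      if (ll_new >= ll - 1e-12 || step < 2^-30) break
      step <- step / 2
    }
    beta <- drop(beta_new)
    eta <- drop(X %*% beta)
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(eta)
  # perfect separation: fit did not settle yet thresholding the fitted
  # probabilities classifies the outcome without error
  separation <- !converged && all((mu > 0.5) == (y == 1))
  vcov <- tryCatch(solve(crossprod(X, X * pmax(mu * (1 - mu),
                                               .Machine$double.eps))),
                   error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- c("intercept", "beta_igf1", "beta_sepsis")
  model <- logistic_model(intercept = beta[1], beta_igf1 = beta[2],
                          beta_sepsis = beta[3],
                          converged = converged, n_iter = iter, loglik = ll,
                          se = se, outcome_def = outcome_def,
                          fitted_on_n = nrow(cohort),
                          separation = separation)
  model$vcov <- vcov
  model$loglik_trace <- ll_trace
  if (separation) {
    warning("fit_logistic: (quasi-)complete separation detected; ",
            "coefficients are not maximum-likelihood estimates",
            call. = FALSE)
  }
  model
}

#' Predicted ROP probability
#'
#' \eqn{1 / (1 + exp(-(\beta_0 + \beta_1 IGF1 + \beta_2 sepsis)))},
#' strictly inside (0, 1). Vectorised over infants.
#'
#' @param model A converged `rop_logistic` model.
#' @param igf1_w3 Week-3 IGF1, ng/ml (> 0).
#' @param sepsis_w3 0/1 sepsis flag.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(model, igf1_w3, sepsis_w3) {
  if (!inherits(model, "rop_logistic")) {
    stop("predict_probability: model must be a rop_logistic", call. = FALSE)
  }
  if (!isTRUE(model$converged)) {
    stop("predict_probability: model did not converge", call. = FALSE)
  }
  if (any(!is.finite(igf1_w3)) || any(igf1_w3 <= 0)) {
    stop("predict_probability: igf1_w3 must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(sepsis_w3)) || !all(sepsis_w3 %in% c(0, 1))) {
    stop("predict_probability: sepsis_w3 must be 0 or 1", call. = FALSE)
  }
  eta <- model$intercept + model$beta_igf1 * igf1_w3 +
    model$beta_sepsis * sepsis_w3
  p <- stats::plogis(eta)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Week-3 IGF1 threshold classification
#'
#' The single-biomarker discriminator: an infant is at risk when week-3 IGF1
#' is strictly below the cut-off (default 30 ng/ml).
#'
#' @param igf1_w3 Week-3 IGF1, ng/ml (> 0). Vectorised.
#' @param cutoff Cut-off in ng/ml.
#' @return Character vector, `"at_risk"` or `"not_at_risk"`.
#' @export
igf1_threshold_classify <- function(igf1_w3, cutoff = 30) {
  if (any(!is.finite(igf1_w3)) || any(igf1_w3 <= 0)) {
    stop("igf1_threshold_classify: igf1_w3 must be finite and > 0",
         call. = FALSE)
  }
  ifelse(igf1_w3 < cutoff, "at_risk", "not_at_risk")
}

#' Empirical ROC curve and AUC
#'
#' Sweeps all distinct score values as thresholds (ties grouped at one
#' threshold), computing true- and false-positive rates for the classifier
#' "score >= threshold", and the area under the curve by the trapezoidal
#' rule. With tied scores the trapezoid over the tie segment credits half,
#' so the AUC equals the Mann-Whitney statistic
#' \eqn{\sum [s_+ > s_-] + 0.5 [s_+ = s_-] / (n_+ n_-)} exactly.
#'
#' @param scores Numeric risk scores, finite.
#' @param labels Binary outcomes (0/1 or logical); both classes required.
#' @return An object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr` (each starting at the (0,0) corner and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) {
    stop("roc_curve: labels must be binary", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("roc_curve: scores must be finite", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve: both outcome classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(thresholds = c(Inf, s[last_of_tie]), tpr = tpr, fpr = fpr,
         auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}
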