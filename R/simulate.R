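# Draws from a normal truncated below at `lower` by inverse-CDF so a single
# runif() stream drives the stage deterministically.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (all(sd == 0)) return(rep_len(pmax(mean, lower), n))
  a <- stats::pnorm((lower - mean) / sd)
  u <- stats::runif(n, min = a, max = 1)
  q <- mean + sd * stats::qnorm(u)
  pmax(q, lower)  # guard against qnorm(1-eps) rounding below the bound
}

# One sub-seed per generation stage, all derived from params$seed up front,
# so adding draws inside one stage never perturbs another stage's stream.
stage_seeds <- function(seed, n_stages = 6L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_stages)
}

#' Generate a synthetic pre-term cohort
#'
#' Samples `params$n` infants: a latent risk stratum (high with probability
#' `high_risk_frac`), gestational age and birth weight uniform in their
#' configured ranges (weight mildly coupled to gestational age), sepsis as a
#' stratum-conditional Bernoulli flag, week-3 IGF1 from a stratum-conditional
#' normal truncated at 1 ng/ml, the ROP outcome from the logistic
#' `params$rop_model` given each infant's IGF1 and sepsis (proliferative
#' with probability `p_proliferative` among ROP cases), and week-5 IGF1 via
#' a grade-conditional percentage increase (see [assign_week5_igf1()]).
#'
#' Identical `params` (including `seed`) give bit-identical cohorts.
#'
#' @param params A [cohort_params()] object.
#' @return A `rop_cohort`: a [tibble::tibble()] of `InfantRecord` rows with
#'   columns `infant_id, ga_weeks, birth_weight_g, length_cm, head_circ_cm,
#'   igf1_w3, igf1_w5, sepsis_w3, rop_grade, risk_stratum`, carrying `params`
#'   as attribute `"params"` for provenance.
#' @export
generate_cohort <- function(params) {
  validate_cohort_params(params)
  if (is.null(params$rop_model)) {
    stop("invalid cohort_params: field 'rop_model' is NULL", call. = FALSE)
  }
  n <- as.integer(params$n)
  ss <- stage_seeds(params$seed)

  set.seed(ss[1])  # stratum + anthropometrics
  stratum <- ifelse(stats::runif(n) < params$high_risk_frac, "high", "low")
  ga <- stats::runif(n, params$ga_range_weeks[1], params$ga_range_weeks[2])
  ga_pos <- (ga - params$ga_range_weeks[1]) / diff(params$ga_range_weeks)
  bw_pos <- params$ga_bw_coupling * ga_pos +
    (1 - params$ga_bw_coupling) * stats::runif(n)
  bw <- params$bw_range_g[1] + bw_pos * diff(params$bw_range_g)
  length_cm <- rtruncnorm_lower(n, mean = 34 + 2.1 * ga_pos * 4, sd = 1.5,
                                lower = 20)
  head_cm <- rtruncnorm_lower(n, mean = 27 + 0.8 * ga_pos * 4, sd = 1.0,
                              lower = 15)

  set.seed(ss[2])  # sepsis in the first 3 weeks
  sepsis <- stats::rbinom(n, 1L,
                          unname(params$sepsis_rate_by_risk[stratum]))

  set.seed(ss[3])  # week-3 IGF1, truncated at 1 ng/ml
  igf1_w3 <- rtruncnorm_lower(n,
                              mean = unname(params$igf1_w3_mean_by_risk[stratum]),
                              sd = params$igf1_w3_sd, lower = 1)

  set.seed(ss[4])  # ROP outcome from the generative risk model
  p_rop <- predict_probability(params$rop_model, igf1_w3, sepsis)
  rop <- stats::rbinom(n, 1L, p_rop)
  prolif <- stats::rbinom(n, 1L, params$p_proliferative)
  grade <- ifelse(rop == 1L,
                  ifelse(prolif == 1L, "proliferative", "non_proliferative"),
                  "none")

  cohort <- tibble::tibble(
    infant_id = sprintf("inf%05d", seq_len(n)),
    ga_weeks = ga,
    birth_weight_g = bw,
    length_cm = length_cm,
    head_circ_cm = head_cm,
    igf1_w3 = igf1_w3,
    igf1_w5 = NA_real_,
    sepsis_w3 = as.integer(sepsis),
    rop_grade = grade,
    risk_stratum = stratum
  )

  set.seed(ss[5])  # week-5 IGF1 trajectory
  cohort <- assign_week5_igf1(cohort, params)

  if (params$week5_missing_rate > 0) {
    set.seed(ss[6])
    miss <- stats::runif(n) < params$week5_missing_rate
    cohort$igf1_w5[miss] <- NA_real_
  }

  attr(cohort, "params") <- params
  class(cohort) <- c("rop_cohort", class(cohort))
  cohort
}

#' Assign week-5 IGF1 from a grade-conditional percentage increase
#'
#' Draws the week-3 to week-5 percentage increase
#' \eqn{\Delta \sim N(\mu_{grade}, \sigma)} (means
#' `pct_increase_mean_by_grade`, sd `pct_increase_sd`), truncated below at
#' just above -100% so that week-5 IGF1 stays positive, and sets
#' `igf1_w5 = igf1_w3 * (1 + \Delta / 100)`.
#'
#' Uses the current RNG state; [generate_cohort()] seeds it as its own stage.
#'
#' @param records One or more `InfantRecord` rows (data frame with at least
#'   `igf1_w3` and `rop_grade`).
#' @param params A [cohort_params()] object.
#' @return `records` with `igf1_w5` filled in.
#' @export
assign_week5_igf1 <- function(records, params) {
  if (any(!is.finite(records$igf1_w3) | records$igf1_w3 <= 0)) {
    stop("assign_week5_igf1: igf1_w3 must be > 0 for all records",
         call. = FALSE)
  }
  if (!all(records$rop_grade %in% ROP_GRADES)) {
    stop("assign_week5_igf1: unknown rop_grade value", call. = FALSE)
  }
  mu <- unname(params$pct_increase_mean_by_grade[records$rop_grade])
  delta <- if (params$pct_increase_sd == 0) {
    mu
  } else {
    rtruncnorm_lower(nrow(records), mean = mu, sd = params$pct_increase_sd,
                     lower = -100 + 1e-9)
  }
  records$igf1_w5 <- records$igf1_w3 * (1 + delta / 100)
  records
}
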