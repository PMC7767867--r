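#' Screening rule configuration
#'
#' The two-tier decision rule: infants below the mandatory gestational-age
#' *or* birth-weight threshold receive standard serial examinations; all
#' others are triaged by the model-predicted ROP probability, screened only
#' when it strictly exceeds `probability_cutoff`, and low-risk infants get a
#' single confirmation exam at `low_risk_exam_pma_weeks` postmenstrual age.
#'
#' Variants: `"validated"` mandates screening below 30 + 0 weeks and/or
#' 1,250 g (the prospectively validated rule); `"extended"` below 28 + 0
#' weeks and/or 1,100 g (the proposed further restriction); `"aap"` applies
#' the American Academy of Pediatrics baseline via [aap_rule()] with no
#' probability triage. Explicit threshold arguments override the variant
#' defaults.
#'
#' @param variant `"validated"`, `"extended"` or `"aap"`.
#' @param mandatory_ga_weeks Mandatory-screening GA threshold, decimal weeks
#'   (strict `<`).
#' @param mandatory_bw_g Mandatory-screening birth-weight threshold, grams
#'   (strict `<`).
#' @param probability_cutoff High-risk probability cut-off in (0, 1)
#'   (strict `>`).
#' @param low_risk_exam_pma_weeks Postmenstrual age of the single low-risk
#'   confirmation exam, weeks.
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(variant = c("validated", "extended", "aap"),
                        mandatory_ga_weeks = NULL, mandatory_bw_g = NULL,
                        probability_cutoff = 0.30,
                        low_risk_exam_pma_weeks = 40) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
                     validated = c(ga = 30.0, bw = 1250),
                     extended = c(ga = 28.0, bw = 1100),
                     aap = c(ga = NA_real_, bw = NA_real_))
  if (is.null(mandatory_ga_weeks)) mandatory_ga_weeks <- defaults[["ga"]]
  if (is.null(mandatory_bw_g)) mandatory_bw_g <- defaults[["bw"]]
  if (variant != "aap" &&
      (!is.finite(mandatory_ga_weeks) || mandatory_ga_weeks <= 0 ||
       !is.finite(mandatory_bw_g) || mandatory_bw_g <= 0)) {
    stop("rule_config: mandatory thresholds must be positive", call. = FALSE)
  }
  if (!is.finite(probability_cutoff) || probability_cutoff <= 0 ||
      probability_cutoff >= 1) {
    stop("rule_config: probability_cutoff must be in (0, 1)", call. = FALSE)
  }
  if (!is.finite(low_risk_exam_pma_weeks) || low_risk_exam_pma_weeks <= 0) {
    stop("rule_config: low_risk_exam_pma_weeks must be positive",
         call. = FALSE)
  }
  structure(
    list(variant = variant, mandatory_ga_weeks = mandatory_ga_weeks,
         mandatory_bw_g = mandatory_bw_g,
         probability_cutoff = probability_cutoff,
         low_risk_exam_pma_weeks = low_risk_exam_pma_weeks),
    class = "rule_config"
  )
}

#' Parse gestational age given as weeks + days
#'
#' `"30+0"` means exactly 30 weeks 0 days and converts to `30 + 0/7` decimal
#' weeks.
#'
#' @param x Character vector of `"W+D"` strings (or plain numbers).
#' @return Decimal weeks.
#' @export
parse_ga_weeks <- function(x) {
  vapply(as.character(x), function(s) {
    if (grepl("^\\s*\\d+\\s*\\+\\s*\\d+\\s*$", s)) {
      parts <- as.numeric(strsplit(s, "+", fixed = TRUE)[[1]])
      parts[1] + parts[2] / 7
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("parse_ga_weeks: cannot parse '", s, "'",
                         call. = FALSE)
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Stratify infants into screening tiers
#'
#' Pure decision function. Tier is `mandatory` when gestational age is
#' strictly below `mandatory_ga_weeks` *or* birth weight strictly below
#' `mandatory_bw_g` ("and/or" read as inclusive-or). Otherwise the
#' model-predicted ROP probability decides: `high_risk` (serial exams) when
#' it strictly exceeds `probability_cutoff`, else `low_risk` with a single
#' confirmation exam at `low_risk_exam_pma_weeks`. Under the `"aap"` variant
#' the AAP baseline ([aap_rule()]) decides `mandatory` vs `low_risk` with no
#' probability triage.
#'
#' @param records One or more infant records (data frame); an optional 0/1
#'   `unstable` column feeds the AAP variant (default 0).
#' @param model A converged `rop_logistic` model (may be `NULL` for the
#'   `"aap"` variant).
#' @param config A [rule_config()].
#' @return A tibble of `ScreeningDecision` rows: `infant_id`, `tier`,
#'   `screen` (0/1), `probability` (NA for the mandatory tier),
#'   `confirmation_exam_pma_weeks` (present iff `low_risk`).
#' @export
stratify <- function(records, model, config) {
  stopifnot(inherits(config, "rule_config"))
  n <- nrow(records)
  unstable <- if ("unstable" %in% names(records)) {
    as.integer(records$unstable)
  } else {
    rep(0L, n)
  }
  if (config$variant == "aap") {
    screen <- aap_rule(records, unstable)
    tier <- ifelse(screen, "mandatory", "low_risk")
    probability <- rep(NA_real_, n)
  } else {
    mandatory <- records$ga_weeks < config$mandatory_ga_weeks |
      records$birth_weight_g < config$mandatory_bw_g
    probability <- rep(NA_real_, n)
    if (any(!mandatory)) {
      probability[!mandatory] <- predict_probability(
        model, records$igf1_w3[!mandatory], records$sepsis_w3[!mandatory])
    }
    tier <- ifelse(mandatory, "mandatory",
                   ifelse(probability > config$probability_cutoff,
                          "high_risk", "low_risk"))
  }
  screen <- tier %in% c("mandatory", "high_risk")
  tibble::tibble(
    infant_id = records$infant_id,
    tier = tier,
    screen = as.integer(screen),
    probability = probability,
    confirmation_exam_pma_weeks = ifelse(tier == "low_risk",
                                         config$low_risk_exam_pma_weeks,
                                         NA_real_)
  )
}

#' Stratify a whole cohort
#'
#' Applies [stratify()] row-wise (order-preserving) and attaches tier counts
#' as the `"counts"` attribute (`mandatory`, `high_risk`, `low_risk`).
#'
#' @inheritParams stratify
#' @param cohort Cohort data frame.
#' @return Tibble of decisions with a `"counts"` attribute.
#' @export
stratify_cohort <- function(cohort, model, config) {
  decisions <- stratify(cohort, model, config)
  counts <- c(mandatory = sum(decisions$tier == "mandatory"),
              high_risk = sum(decisions$tier == "high_risk"),
              low_risk = sum(decisions$tier == "low_risk"))
  attr(decisions, "counts") <- counts
  decisions
}

#' American Academy of Pediatrics baseline screening rule
#'
#' Screen when birth weight is at most 1,500 g or gestational age at most 30
#' weeks (non-strict, per the printed "<=" thresholds), or when weight is in
#' (1,500, 2,000] g with gestational age above 30 weeks and an unstable
#' clinical course.
#'
#' @param records Infant records (data frame with `birth_weight_g`,
#'   `ga_weeks`), or a numeric vector of birth weights if `ga_weeks` given.
#' @param unstable 0/1 indicator of unstable clinical evolution or
#'   respiratory support (recycled).
#' @param ga_weeks Gestational ages when `records` is a bare weight vector.
#' @return Logical vector: serial screening indicated.
#' @export
aap_rule <- function(records, unstable = 0L, ga_weeks = NULL) {
  if (is.data.frame(records)) {
    bw <- records$birth_weight_g
    ga <- records$ga_weeks
  } else {
    bw <- records
    ga <- ga_weeks
  }
  unstable <- as.logical(rep_len(unstable, length(bw)))
  (bw <= 1500 | ga <= 30) |
    (bw > 1500 & bw <= 2000 & ga > 30 & unstable)
}
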