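# Hand-built cohort rows for unit tests.
make_cohort_df <- function(n = 4,
                           ga_weeks = rep(31, n),
                           birth_weight_g = rep(1400, n),
                           igf1_w3 = rep(40, n),
                           igf1_w5 = rep(50, n),
                           sepsis_w3 = rep(0L, n),
                           rop_grade = rep("none", n)) {
  tibble::tibble(
    infant_id = sprintf("t%03d", seq_len(n)),
    ga_weeks = ga_weeks,
    birth_weight_g = birth_weight_g,
    length_cm = rep(41, n),
    head_circ_cm = rep(29, n),
    igf1_w3 = igf1_w3,
    igf1_w5 = igf1_w5,
    sepsis_w3 = as.integer(sepsis_w3),
    rop_grade = rop_grade
  )
}

# Cohort as a bare data frame (provenance attribute dropped) for equality
# comparisons.
plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "params") <- NULL
  x
}

# Intercept-only model whose predicted probability is exactly `p` in double
# precision (plogis(qlogis(p)) can land one ulp off; search neighbours).
exact_prob_intercept <- function(p) {
  cands <- qlogis(p) + (-500:500) * 2^-53
  hit <- cands[plogis(cands) == p]
  if (length(hit) > 0) return(hit[1])
  # fall back to the largest intercept not exceeding p, keeping the
  # comparison semantics ("exceeds") intact
  below <- cands[plogis(cands) <= p]
  below[which.max(plogis(below))]
}

constant_prob_model <- function(p) {
  logistic_model(intercept = exact_prob_intercept(p), beta_igf1 = 0,
                 beta_sepsis = 0)
}

# Mean of a normal(mean, sd) truncated below at `lower` (closed form), the
# generator's actual configured IGF1 law.
truncnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

# Full-enumeration two-sided Mann-Whitney p-value: every choose(n, n_a)
# assignment of the pooled values to group A.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  offset <- na * (na + 1) / 2
  u_obs <- sum(r[seq_len(na)]) - offset
  u_all <- utils::combn(seq_along(pooled), na,
                        FUN = function(idx) sum(r[idx]) - offset)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# Pairwise-comparison AUC oracle: P(score_pos > score_neg) + 0.5 P(equal).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}
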