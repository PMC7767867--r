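test_that("parameter validation rejects degenerate settings, naming the field", {
  expect_error(cohort_params(n = 0), "'n'")
  expect_error(cohort_params(igf1_w3_sd = -1), "'igf1_w3_sd'")
  expect_error(cohort_params(sepsis_rate_by_risk = c(low = 0.1, high = 1.5)),
               "'sepsis_rate_by_risk'")
  expect_error(cohort_params(ga_range_weeks = c(32, 30)),
               "'ga_range_weeks'")
  expect_error(cohort_params(bw_range_g = c(1400, 1400)), "'bw_range_g'")
  expect_error(cohort_params(p_proliferative = 2), "'p_proliferative'")
  expect_error(cohort_params(high_risk_frac = -0.1), "'high_risk_frac'")
  expect_error(cohort_params(pct_increase_mean_by_grade = c(a = 1)),
               "'pct_increase_mean_by_grade'")
})

test_that("identical parameters give bit-identical cohorts", {
  p <- cohort_params(n = 500, seed = 7, week5_missing_rate = 0.1)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(plain_df(c1), plain_df(c2))
  c3 <- generate_cohort(cohort_params(n = 500, seed = 8,
                                      week5_missing_rate = 0.1))
  expect_false(identical(c1$igf1_w3, c3$igf1_w3))
})

test_that("all generated records satisfy the infant-record invariants", {
  p <- cohort_params(n = 2000, seed = 11, week5_missing_rate = 0.05)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 2000)
  expect_false(anyDuplicated(co$infant_id) > 0)
  expect_true(all(co$ga_weeks > 0))
  expect_true(all(co$birth_weight_g > 0))
  expect_true(all(co$igf1_w3 > 0))
  expect_true(all(co$igf1_w5 > 0, na.rm = TRUE))
  expect_true(all(co$sepsis_w3 %in% c(0L, 1L)))
  expect_true(all(co$rop_grade %in% ROP_GRADES))
  expect_true(all(co$ga_weeks >= p$ga_range_weeks[1] &
                    co$ga_weeks <= p$ga_range_weeks[2]))
  expect_true(all(co$birth_weight_g >= p$bw_range_g[1] &
                    co$birth_weight_g <= p$bw_range_g[2]))
  expect_silent(validate_cohort(co))
})

test_that("covariate-free risk model gives ~50% ROP incidence", {
  null_model <- logistic_model(intercept = qlogis(0.5), beta_igf1 = 0,
                               beta_sepsis = 0)
  co <- generate_cohort(cohort_params(n = 10000, rop_model = null_model,
                                      seed = 3))
  frac <- mean(co$rop_grade != "none")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("stratum-conditional IGF1 means and sepsis rates match the configured generative law", {
  p <- cohort_params(n = 10000, seed = 5)
  co <- generate_cohort(p)
  for (s in c("low", "high")) {
    x <- co$igf1_w3[co$risk_stratum == s]
    target <- truncnorm_mean(p$igf1_w3_mean_by_risk[[s]], p$igf1_w3_sd,
                             lower = 1)
    expect_lt(abs(mean(x) - target), 3 * sd(x) / sqrt(length(x)))
    sep <- co$sepsis_w3[co$risk_stratum == s]
    rate <- p$sepsis_rate_by_risk[[s]]
    expect_lt(abs(mean(sep) - rate),
              3 * sqrt(rate * (1 - rate) / length(sep)))
  }
  # latent stratum mixing fraction
  expect_lt(abs(mean(co$risk_stratum == "high") - p$high_risk_frac),
            3 * sqrt(p$high_risk_frac * (1 - p$high_risk_frac) / 10000))
})

test_that("empirical ROP incidence matches model-predicted probabilities per IGF1 x sepsis cell", {
  p <- cohort_params(n = 10000, seed = 13)
  co <- generate_cohort(p)
  pred <- predict_probability(p$rop_model, co$igf1_w3, co$sepsis_w3)
  rop <- as.numeric(co$rop_grade != "none")
  bin <- cut(co$igf1_w3, breaks = quantile(co$igf1_w3, 0:5 / 5),
             include.lowest = TRUE, labels = FALSE)
  for (b in 1:5) {
    for (s in 0:1) {
      cell <- bin == b & co$sepsis_w3 == s
      n_cell <- sum(cell)
      if (n_cell < 30) next
      pbar <- mean(pred[cell])
      se <- sqrt(sum(pred[cell] * (1 - pred[cell]))) / n_cell
      expect_lt(abs(mean(rop[cell]) - pbar), qnorm(0.995) * se + 1e-12)
    }
  }
})

test_that("ROP incidence is non-increasing across IGF1 quintiles", {
  co <- generate_cohort(cohort_params(n = 10000, seed = 2))
  bin <- cut(co$igf1_w3, breaks = quantile(co$igf1_w3, 0:5 / 5),
             include.lowest = TRUE, labels = FALSE)
  inc <- tapply(co$rop_grade != "none", bin, mean)
  expect_true(all(diff(inc) <= 0))
})

test_that("week-5 assignment follows the grade-conditional percentage increase", {
  # zero mean and spread: identity
  p0 <- cohort_params(n = 5, pct_increase_mean_by_grade = c(
    none = 0, non_proliferative = 0, proliferative = 0), pct_increase_sd = 0)
  rec <- make_cohort_df(5, igf1_w3 = c(10, 20, 30, 40, 55),
                        igf1_w5 = rep(NA_real_, 5))
  out <- assign_week5_igf1(rec, p0)
  expect_equal(out$igf1_w5, out$igf1_w3)

  # proliferative grade, mean 28.97%, no spread: direct arithmetic
  p1 <- cohort_params(n = 1, pct_increase_sd = 0)
  rec1 <- make_cohort_df(1, igf1_w3 = 30, igf1_w5 = NA_real_,
                         rop_grade = "proliferative")
  expect_equal(assign_week5_igf1(rec1, p1)$igf1_w5, 38.691)

  # generator self-consistency: sample mean increase within 3 SE
  p2 <- cohort_params(n = 10000, seed = 21)
  rec2 <- make_cohort_df(10000, igf1_w3 = rep(40, 10000),
                         igf1_w5 = rep(NA_real_, 10000))
  set.seed(99)
  out2 <- assign_week5_igf1(rec2, p2)
  delta <- pct_increase(out2$igf1_w3, out2$igf1_w5)
  expect_lt(abs(mean(delta) - 14.10), 3 * sd(delta) / sqrt(10000))

  expect_error(assign_week5_igf1(make_cohort_df(1, igf1_w3 = 0), p1),
               "igf1_w3")
})

test_that("cohort CSV round-trips at full precision", {
  p <- cohort_params(n = 200, seed = 17, week5_missing_rate = 0.1)
  co <- generate_cohort(p)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(plain_df(back)[names(co)], plain_df(co), tolerance = 0)

  # empty cohort: header-only file, round-trips to zero rows
  empty <- co[0, ]
  path2 <- tempfile(fileext = ".csv")
  write_cohort(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(nrow(read_cohort(path2)), 0L)
})

test_that("malformed cohort files are rejected with located errors", {
  co <- make_cohort_df(3)
  path <- tempfile(fileext = ".csv")

  bad <- co
  bad$igf1_w3[2] <- -5
  readr::write_csv(bad, path, na = "")
  expect_error(read_cohort(path), "igf1_w3 at row 2")

  readr::write_csv(co[, setdiff(names(co), "igf1_w3")], path, na = "")
  expect_error(read_cohort(path), "missing mandatory column.*igf1_w3")

  extra <- co
  extra$oxygen_days <- 1
  readr::write_csv(extra, path, na = "")
  expect_error(read_cohort(path), "unknown column")

  expect_error(write_cohort(bad, tempfile()), "igf1_w3 at row 2")
})
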