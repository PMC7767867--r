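test_that("percentage increase is the relative week-3 to week-5 change", {
  expect_equal(pct_increase(30, 30), 0)
  expect_equal(pct_increase(40, 50), 25)
  expect_equal(pct_increase(50, 40), -20)
  expect_true(is.na(pct_increase(30, NA)))
  # scale invariance
  set.seed(5)
  w3 <- runif(50, 10, 80)
  w5 <- runif(50, 10, 80)
  for (k in c(0.5, 3, 117)) {
    expect_equal(pct_increase(k * w3, k * w5), pct_increase(w3, w5),
                 tolerance = 1e-12)
  }
  expect_error(pct_increase(0, 10), "igf1_w3")
  expect_error(pct_increase(-2, 10), "igf1_w3")
  expect_error(pct_increase(10, -1), "igf1_w5")
})

test_that("per-grade summaries match closed-form t-intervals and quartiles", {
  # identical increases: zero-width interval, equal quartiles
  co <- make_cohort_df(4, igf1_w3 = rep(40, 4), igf1_w5 = rep(50, 4))
  s <- summarize_by_grade(co)
  none <- s[s$grade == "none", ]
  expect_equal(none$mean_pct_increase, 25)
  expect_equal(none$ci_lower, 25)
  expect_equal(none$ci_upper, 25)
  expect_equal(c(none$q1, none$median, none$q3), c(25, 25, 25))

  # two-record grade {0%, 10%}: closed-form t(1 df) interval
  co2 <- make_cohort_df(2, igf1_w3 = c(10, 10), igf1_w5 = c(10, 11))
  s2 <- summarize_by_grade(co2)[1, ]
  half <- qt(0.975, 1) * sd(c(0, 10)) / sqrt(2)
  expect_equal(s2$mean_pct_increase, 5)
  expect_equal(s2$ci_lower, 5 - half, tolerance = 1e-12)
  expect_equal(s2$ci_upper, 5 + half, tolerance = 1e-12)
  expect_equal(s2$median, 5)

  # a grade with < 2 complete records is marked unavailable, not fabricated
  co3 <- make_cohort_df(3, igf1_w5 = c(50, NA, NA),
                        rop_grade = c("none", "none", "proliferative"))
  s3 <- summarize_by_grade(co3)
  expect_false(s3$available[s3$grade == "proliferative"])
  expect_true(is.na(s3$mean_pct_increase[s3$grade == "proliferative"]))
  expect_equal(s3$n_missing_w5[s3$grade == "none"], 1L)
  expect_false(s3$available[s3$grade == "none"])  # only 1 complete record
})

test_that("grade-conditional trajectory means are recovered from simulation", {
  p <- cohort_params(n = 6000, seed = 23, p_proliferative = 0.5)
  co <- generate_cohort(p)
  s <- summarize_by_grade(co)
  for (g in ROP_GRADES) {
    row <- s[s$grade == g, ]
    expect_true(row$available)
    d <- pct_increase(co$igf1_w3[co$rop_grade == g],
                      co$igf1_w5[co$rop_grade == g])
    target <- p$pct_increase_mean_by_grade[[g]]
    expect_lt(abs(row$mean_pct_increase - target),
              3 * sd(d) / sqrt(row$n))
    expect_true(row$q1 <= row$median && row$median <= row$q3)
    expect_true(row$ci_lower <= row$mean_pct_increase &&
                  row$mean_pct_increase <= row$ci_upper)
  }
})

test_that("identical groups compare as indistinguishable", {
  r <- compare_groups(c(1, 2, 3), c(1, 2, 3), mode = "mann_whitney_u")
  expect_equal(r$p_value, 1)
  expect_equal(r$note, "exact")
  deg <- compare_groups(c(2, 2), c(2, 2, 2))
  expect_equal(deg$test_name, "undefined")
  expect_true(is.na(deg$p_value))
})

test_that("exact Mann-Whitney matches the textbook example and enumeration", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), mode = "mann_whitney_u")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 assignments as extreme

  set.seed(77)
  for (sizes in list(c(3, 5), c(4, 4), c(2, 6), c(6, 6))) {
    a <- rnorm(sizes[1])
    b <- rnorm(sizes[2])
    mine <- compare_groups(a, b, mode = "mann_whitney_u")
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, enumerate_mw_p(a, b), tolerance = 1e-12)
  }

  # ties force the enumeration path; enumeration oracle still applies
  a <- c(1, 2, 2, 3)
  b <- c(2, 3, 3, 4, 4)
  r_tie <- compare_groups(a, b, mode = "mann_whitney_u")
  expect_equal(r_tie$note, "exact")
  expect_equal(r_tie$p_value, enumerate_mw_p(a, b), tolerance = 1e-12)
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal approximation", {
  set.seed(88)
  a <- round(rnorm(40), 1)
  b <- round(rnorm(35, 0.2), 1)
  mine <- compare_groups(a, b, mode = "mann_whitney_u")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_match(mine$note, "normal approximation")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("t tests delegate to the reference implementation and detect large shifts", {
  set.seed(99)
  a <- rnorm(200)
  b <- rnorm(200, 1)  # one-sd location shift
  for (mode in c("welch_t", "mann_whitney_u")) {
    expect_lt(compare_groups(a, b, mode = mode)$p_value, 0.001)
  }
  rs <- compare_groups(a, b, mode = "student_t")
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(rs$statistic, unname(ref$statistic))
  expect_equal(rs$df, unname(ref$parameter))
  expect_equal(rs$p_value, ref$p.value)
})

test_that("the automatic mode gate picks t for normal and rank test for skewed data", {
  set.seed(111)
  expect_equal(compare_groups(rnorm(60), rnorm(60), mode = "auto")$test_name,
               "welch_t")
  expect_equal(compare_groups(rexp(60), rexp(60), mode = "auto")$test_name,
               "mann_whitney_u")
})

test_that("chi-square matches Pearson's definition and the reference implementation", {
  r <- chi_square_2xk(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(123)
  tab <- matrix(rpois(6, 20) + 1, 2, 3)
  mine <- chi_square_2xk(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  tab2 <- matrix(c(12, 5, 7, 15), 2)
  yates <- chi_square_2xk(tab2, correct = TRUE)
  ref2 <- chisq.test(tab2, correct = TRUE)
  expect_equal(yates$statistic, unname(ref2$statistic), tolerance = 1e-12)

  # ROP-by-tier association from the prospective table is significant
  rop_tab <- matrix(c(3, 29, 0, 121), 2, byrow = TRUE)
  expect_lte(suppressWarnings(chi_square_2xk(rop_tab))$p_value, 0.05)

  expect_error(chi_square_2xk(matrix(c(0, 0, 5, 5), 2)), "sums")
  expect_error(chi_square_2xk(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("one-way ANOVA satisfies F = t^2 at k = 2 and matches the reference", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r0 <- anova_oneway(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  set.seed(31)
  a <- rnorm(15)
  b <- rnorm(12, 0.5)
  fr <- anova_oneway(list(a, b))
  tr <- compare_groups(a, b, mode = "student_t")
  expect_equal(fr$statistic, tr$statistic^2, tolerance = 1e-10)
  expect_equal(fr$p_value, tr$p_value, tolerance = 1e-10)

  g <- list(rnorm(10), rnorm(12, 0.3), rnorm(9, 0.6))
  mine <- anova_oneway(g)
  ref <- oneway.test(values ~ grp,
                     data = data.frame(values = unlist(g),
                                       grp = rep(seq_along(g),
                                                 lengths(g))),
                     var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)

  expect_error(anova_oneway(list(1:3)), "2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "2 values")
})
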