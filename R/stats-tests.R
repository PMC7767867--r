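test_result <- function(test_name, statistic, df = NA_real_, df2 = NA_real_,
                        p_value = NA_real_, note = NA_character_) {
  tibble::tibble(test_name = test_name, statistic = statistic, df = df,
                 df2 = df2, p_value = p_value, note = note)
}

# Mann-Whitney U of a vs b with midrank tie handling:
# U = sum over pairs [a > b] + 0.5 [a == b].
mann_whitney_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact two-sided Mann-Whitney p-value.
# Without ties the exact null distribution is the Wilcoxon distribution
# (identical to enumerating all choose(n, n_a) group assignments); with ties
# the assignments are enumerated directly while feasible.
mann_whitney_exact_p <- function(a, b, max_enum = 2e5) {
  na <- length(a)
  nb <- length(b)
  u <- mann_whitney_u_stat(a, b)
  pooled <- c(a, b)
  if (!any(duplicated(pooled))) {
    p_low <- stats::pwilcox(u, na, nb)
    p_high <- 1 - stats::pwilcox(u - 1, na, nb)
    return(min(1, 2 * min(p_low, p_high)))
  }
  if (choose(na + nb, na) > max_enum) return(NA_real_)
  r <- rank(pooled)
  offset <- na * (na + 1) / 2
  u_all <- utils::combn(r, na, FUN = function(z) sum(z) - offset)
  eps <- 1e-9
  p_low <- mean(u_all <= u + eps)
  p_high <- mean(u_all >= u - eps)
  min(1, 2 * min(p_low, p_high))
}

# Tie-corrected normal approximation with continuity correction.
mann_whitney_approx_p <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  u <- mann_whitney_u_stat(a, b)
  ties <- table(c(a, b))
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(NA_real_)
  z <- (u - na * nb / 2)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Two-group comparison (t-test or Mann-Whitney U)
#'
#' `mode = "auto"` applies a per-group Shapiro-Wilk normality gate at
#' alpha = 0.05: when both groups pass, a t-test is used (Welch by default,
#' matching unequal group sizes), otherwise the Mann-Whitney U test. The
#' Mann-Whitney path is exact (full-enumeration null distribution) when the
#' smaller group has at most 8 observations, and a tie- and
#' continuity-corrected normal approximation otherwise. All p-values are
#' two-sided.
#'
#' @param values_a,values_b Numeric samples (n >= 2 per group; n >= 1 for
#'   Mann-Whitney).
#' @param mode `"auto"`, `"student_t"`, `"welch_t"` or `"mann_whitney_u"`.
#' @return A `TestResult` tibble row: `test_name, statistic, df, df2,
#'   p_value, note`. Degenerate input (all pooled values identical) yields
#'   an undefined result (`p_value = NA`) with an explanatory note.
#' @export
compare_groups <- function(values_a, values_b,
                           mode = c("auto", "student_t", "welch_t",
                                    "mann_whitney_u")) {
  mode <- match.arg(mode)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  min_n <- if (mode == "mann_whitney_u") 1L else 2L
  if (length(a) < min_n || length(b) < min_n) {
    stop(sprintf("compare_groups: each group needs >= %d observations",
                 min_n), call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1) {
    return(test_result("undefined", NA_real_,
                       note = "all pooled values identical"))
  }
  if (mode == "auto") {
    normal <- function(x) {
      if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
      if (length(x) > 5000) {
        # Shapiro-Wilk is defined for n <= 5000; gate on a deterministic
        # subsample of evenly spaced order statistics
        x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
      }
      stats::shapiro.test(x)$p.value >= 0.05
    }
    mode <- if (normal(a) && normal(b)) "welch_t" else "mann_whitney_u"
  }
  if (mode %in% c("student_t", "welch_t")) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(test_result(mode, NA_real_,
                         note = "zero variance in both groups"))
    }
    fit <- stats::t.test(a, b, var.equal = (mode == "student_t"))
    return(test_result(mode, unname(fit$statistic),
                       df = unname(fit$parameter),
                       p_value = fit$p.value))
  }
  u <- mann_whitney_u_stat(a, b)
  if (min(length(a), length(b)) <= 8) {
    p <- mann_whitney_exact_p(a, b)
    if (!is.na(p)) {
      return(test_result("mann_whitney_u", u, p_value = p, note = "exact"))
    }
    note <- "normal approximation (tie enumeration infeasible)"
  } else {
    note <- "normal approximation"
  }
  test_result("mann_whitney_u", u, p_value = mann_whitney_approx_p(a, b),
              note = note)
}

#' Pearson chi-square test on a 2 x k (or r x k) count table
#'
#' Pearson statistic with (r-1)(k-1) degrees of freedom; `correct = TRUE`
#' applies the Yates continuity correction on 2 x 2 tables.
#'
#' @param counts Matrix of non-negative counts, all row and column sums > 0.
#' @param correct Apply Yates continuity correction (2 x 2 only).
#' @return A `TestResult` tibble row.
#' @export
chi_square_2xk <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("chi_square_2xk: counts must be non-negative and finite",
         call. = FALSE)
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("chi_square_2xk: need at least a 2 x 2 table", call. = FALSE)
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chi_square_2xk: all row and column sums must be positive",
         call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(counts)
  dev <- abs(counts - expected)
  if (correct && all(dim(counts) == c(2, 2))) {
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  test_result("chi_square", stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test across k groups: F with (k-1, N-k) degrees
#' of freedom. Identical group means (zero between-group sum of squares)
#' give F = 0, p = 1, including the fully degenerate all-identical case.
#'
#' @param groups List of numeric vectors, >= 2 groups with >= 2 values each.
#' @return A `TestResult` tibble row (`df` = between, `df2` = within).
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, 1L) < 2)) {
    stop("anova_oneway: need >= 2 groups with >= 2 values each",
         call. = FALSE)
  }
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  n_tot <- sum(ns)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n_tot - k
  if (ssb == 0) {
    return(test_result("anova_f", 0, df = df1, df2 = df2, p_value = 1))
  }
  if (ssw == 0) {
    return(test_result("anova_f", Inf, df = df1, df2 = df2, p_value = 0,
                       note = "zero within-group variance"))
  }
  f <- (ssb / df1) / (ssw / df2)
  test_result("anova_f", f, df = df1, df2 = df2,
              p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}
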