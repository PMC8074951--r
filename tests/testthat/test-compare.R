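summary_row <- function(pid, label, year, variable, mean, n = 10L) {
  tibble::tibble(participant_id = pid, period_label = label,
                 year = as.integer(year), variable = variable,
                 mean_per_day = mean, n_valid_days = n)
}

test_that("pairs are the participant intersection with b-minus-a diffs", {
  s <- dplyr::bind_rows(
    summary_row(c("p1", "p2", "p3"), "March", 2019, "steps",
                c(8000, 9000, 7000)),
    summary_row(c("p2", "p3", "p4"), "March 13-31", 2020, "steps",
                c(8500, 6800, 9100))
  )
  pairs <- build_pairs(s, "steps", "March", 2019, "March 13-31", 2020)
  expect_identical(pairs$participant_id, c("p2", "p3"))
  expect_identical(pairs$diff, c(-500, -200))
  # disjoint participants cannot be paired
  s2 <- dplyr::bind_rows(
    summary_row("p1", "March", 2019, "steps", 8000),
    summary_row("p9", "March 13-31", 2020, "steps", 8500)
  )
  expect_error(build_pairs(s2, "steps", "March", 2019,
                           "March 13-31", 2020), "insufficient pairs")
})

test_that("paired t matches its closed form", {
  fit <- paired_t(c(1, 2, 3))
  expect_equal(fit$estimate, 2)
  expect_equal(fit$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(fit$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(fit$p, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-12)
  expect_equal(fit$p, 0.0741799, tolerance = 1e-6)
  expect_identical(fit$df, 2)
  # the estimate lies inside its own 95% CI
  expect_true(fit$ci_lo < fit$estimate && fit$estimate < fit$ci_hi)
  expect_equal(fit$ci_lo, 2 - qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
})

test_that("paired t is symmetric and permutation invariant", {
  expect_equal(paired_t(c(-1, 1))$p, 1)
  expect_equal(paired_t(c(-1, 1))$estimate, 0)
  d <- c(3.2, -1.5, 0.4, 2.2, 5.1, -0.3)
  base <- paired_t(d)
  perm <- paired_t(rev(d))
  expect_equal(perm$p, base$p)
  expect_equal(perm$estimate, base$estimate)
  flip <- paired_t(-d)
  expect_equal(flip$p, base$p)
  expect_equal(flip$estimate, -base$estimate)
  shift <- paired_t(d + 10)
  expect_equal(shift$estimate, base$estimate + 10)
  expect_true(shift$p < base$p)  # farther from H0: mean = 0
})

test_that("degenerate zero-variance differences are flagged, not fatal", {
  fit <- paired_t(rep(2, 5))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p))
  wfit <- wilcoxon_signed_rank(rep(0, 5))
  expect_true(wfit$degenerate)
  expect_true(is.na(wfit$p))
})

test_that("signed-rank exact p matches hand enumeration", {
  # all-positive signs among the 2^3 equally likely patterns
  fit <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_identical(fit$method, "exact")
  expect_equal(fit$p, 0.25)
  expect_equal(fit$estimate, 2)
  # tied magnitudes, perfect symmetry
  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p, 1)
  # zeros dropped: effective n = 1
  fit3 <- wilcoxon_signed_rank(c(0, 0, 5))
  expect_identical(fit3$n_effective, 1L)
  expect_equal(fit3$p, 1)
  # median and IQR are computed on the raw differences, zeros included
  expect_equal(fit3$estimate, 0)
  expect_equal(c(fit3$iqr_lo, fit3$iqr_hi), c(0, 2.5))
})

test_that("signed-rank p agrees with the sign-assignment oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:11, 1)
    d <- round(rnorm(n, sd = 3), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p,
                 brute_force_signed_rank_p(d), tolerance = 1e-12)
  }
  # including ties and zeros
  cases <- list(c(1, 1, -1, 2), c(0, 2, -2, 3, 3), c(-4, 4, 4, -1, 0, 2))
  for (d in cases) {
    expect_equal(wilcoxon_signed_rank(d)$p,
                 brute_force_signed_rank_p(d), tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank(d, zero_method = "pratt")$p,
                 brute_force_signed_rank_p(d, zero_method = "pratt"),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank exact p matches the reference implementation on
           tie-free data", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    d <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(d)$p,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample approximation stays close to the exact law", {
  set.seed(13)
  d <- rnorm(30, mean = 0.3)
  exact <- wilcoxon_signed_rank(d, exact_max_n = 50)
  approx <- wilcoxon_signed_rank(d, exact_max_n = 25)
  expect_identical(exact$method, "exact")
  expect_identical(approx$method, "approx")
  expect_equal(approx$p, exact$p, tolerance = 0.05)
})

test_that("the normality gate behaves like Shapiro-Wilk at its level", {
  expect_error(assess_normality(c(1, 2)), "at least 3")
  flat <- assess_normality(rep(1, 10))
  expect_false(flat)
  expect_true(attr(flat, "degenerate"))
  set.seed(17)
  normal_pass <- mean(vapply(1:300, function(i) {
    assess_normality(rnorm(100))
  }, logical(1)))
  expect_gt(normal_pass, 0.90)
  expect_lt(normal_pass, 0.99)
  skew_fail <- mean(vapply(1:300, function(i) {
    !assess_normality(rexp(100) - 1)
  }, logical(1)))
  expect_gt(skew_fail, 0.95)
})

test_that("comparisons dispatch on the configured test or normality", {
  set.seed(19)
  n <- 40
  pid <- sprintf("p%02d", 1:n)
  s <- dplyr::bind_rows(
    summary_row(pid, "March", 2019, "mvpa", rnorm(n, 30, 5)),
    summary_row(pid, "March 13-31", 2020, "mvpa", rnorm(n, 32, 5)),
    summary_row(pid, "March", 2019, "steps", rnorm(n, 8000, 500)),
    summary_row(pid, "March 13-31", 2020, "steps", rnorm(n, 7500, 500))
  )
  res <- run_comparison(s, "mvpa", "March", 2019, "March 13-31", 2020)
  expect_identical(res$test, "wilcoxon")  # shipped per-variable default
  res2 <- run_comparison(s, "steps", "March", 2019, "March 13-31", 2020)
  expect_identical(res2$test, "paired_t")
  # auto mode consults the normality of the differences
  auto <- trackdays_config(test_override = c(mvpa = "auto"))
  res3 <- run_comparison(s, "mvpa", "March", 2019, "March 13-31", 2020,
                         config = auto)
  d <- build_pairs(s, "mvpa", "March", 2019, "March 13-31", 2020)$diff
  expect_identical(res3$test,
                   if (assess_normality(d)) "paired_t" else "wilcoxon")
})

test_that("comparing a period with itself is degenerate", {
  s <- summary_row(c("p1", "p2", "p3"), "May", 2019, "steps",
                   c(1, 2, 3))
  res <- run_comparison(s, "steps", "May", 2019, "May", 2019)
  expect_true(res$degenerate)
  expect_identical(res$estimate, 0)
  expect_true(is.na(res$p))
})

test_that("the full report covers 13 contrasts for 3 variables", {
  cohort <- generate_cohort(small_cohort_config(), seed = 23)
  fv <- filter_valid(cohort)
  s <- standard_summaries(fv$valid_days)
  rep <- full_report(s)
  expect_identical(nrow(rep), 39L)
  expect_identical(length(unique(rep$comparison_label)), 13L)
  expect_setequal(unique(rep$variable), c("steps", "aee", "mvpa"))
  expect_true(all(rep$n_pairs <= 10))
  expect_true(all(rep$test[rep$variable == "mvpa"] == "wilcoxon"))
})

test_that("missing periods drop their rows with a warning", {
  cohort <- generate_cohort(small_cohort_config(), seed = 23)
  cohort <- cohort[format(cohort$date, "%m") != "12", ]  # no December
  fv <- filter_valid(cohort)
  s <- standard_summaries(fv$valid_days)
  w <- capture_warnings(rep <- full_report(s))
  expect_true(any(grepl("omitting December", w)))
  expect_false("December" %in% rep$comparison_label)
  expect_identical(length(unique(rep$comparison_label)), 12L)
})

test_that("optional Holm correction only reduces significance calls", {
  cohort <- generate_cohort(small_cohort_config(), seed = 29)
  s <- standard_summaries(filter_valid(cohort)$valid_days)
  plain <- full_report(s)
  holm <- full_report(s, trackdays_config(p_adjust = "holm"))
  expect_true(all(holm$p_adjusted >= holm$p, na.rm = TRUE))
  expect_lte(sum(holm$significant, na.rm = TRUE),
             sum(plain$significant, na.rm = TRUE))
})
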