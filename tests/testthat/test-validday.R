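test_that("MVPA is the sum of moderate and vigorous minutes", {
  rec <- make_records(
    make_record("p1", "fitbit", "2019-05-01", steps = 1, mpa = 8, vpa = 3),
    make_record("p1", "fitbit", "2019-05-02", steps = 1, mpa = 0, vpa = 0),
    make_record("p1", "apple", "2019-05-03", steps = 1),        # no mpa/vpa
    make_record("p1", "fitbit", "2019-05-04", steps = 1, mpa = 5) # vpa absent
  )
  expect_identical(compute_mvpa(rec), c(11, 0, NA, NA))
})

test_that("each provider maps to its published valid-day rule", {
  kinds <- vapply(providers(), function(p) rule_for(p)$kind, character(1))
  expect_identical(
    unname(kinds[c("apple", "fitbit", "googlefit", "oura", "withings")]),
    rep("step_floor", 5)
  )
  expect_identical(unname(kinds[c("garmin", "samsung")]),
                   rep("wear_sum", 2))
  expect_identical(unname(kinds["polar"]), "nonwear_cap")
  expect_identical(rule_for("fitbit")$threshold, 150)
  expect_identical(rule_for("garmin")$threshold, 600)
  expect_identical(rule_for("polar")$threshold, 840)
  expect_error(rule_for("unknown"), "unknown provider")
  # thresholds are configurable
  cfg <- trackdays_config(step_floor = 1000, wear_min = 480,
                          nonwear_max = 600)
  expect_identical(rule_for("fitbit", cfg)$threshold, 1000)
  expect_identical(rule_for("samsung", cfg)$threshold, 480)
  expect_identical(rule_for("polar", cfg)$threshold, 600)
})

test_that("rule boundaries follow the strict inequalities", {
  floor_rule <- rule_for("fitbit")
  rec <- make_records(
    make_record("p", "fitbit", "2019-01-01", steps = 149),
    make_record("p", "fitbit", "2019-01-02", steps = 150),
    make_record("p", "fitbit", "2019-01-03", steps = 151)
  )
  expect_identical(is_valid_day(rec, floor_rule)$valid,
                   c(FALSE, FALSE, TRUE))
  # inclusive reading: exactly 150 steps counts
  incl <- rule_for("fitbit", trackdays_config(step_floor_inclusive = TRUE))
  expect_identical(is_valid_day(rec, incl)$valid, c(FALSE, TRUE, TRUE))

  wear_rule <- rule_for("garmin")
  wrec <- make_records(
    make_record("p", "garmin", "2019-01-01", steps = 1, sleep = 420,
                sedentary = 150, lpa = 20, mpa = 6, vpa = 3),  # 599
    make_record("p", "garmin", "2019-01-02", steps = 1, sleep = 420,
                sedentary = 150, lpa = 20, mpa = 7, vpa = 3),  # 600
    make_record("p", "garmin", "2019-01-03", steps = 1, sleep = 420,
                sedentary = 150, lpa = 20, mpa = 8, vpa = 3)   # 601
  )
  expect_identical(is_valid_day(wrec, wear_rule)$valid,
                   c(FALSE, FALSE, TRUE))

  cap_rule <- rule_for("polar")
  nrec <- make_records(
    make_record("p", "polar", "2019-01-01", steps = 1, nonwear = 839),
    make_record("p", "polar", "2019-01-02", steps = 1, nonwear = 840),
    make_record("p", "polar", "2019-01-03", steps = 1, nonwear = 841)
  )
  expect_identical(is_valid_day(nrec, cap_rule)$valid,
                   c(TRUE, FALSE, FALSE))
})

test_that("missing rule inputs make a day invalid, not an error", {
  wear_rule <- rule_for("garmin")
  rec <- make_record("p", "garmin", "2019-01-01", steps = 9000,
                     sleep = 420, sedentary = 200, lpa = 30, mpa = 10)
  res <- is_valid_day(rec, wear_rule)  # vpa absent
  expect_false(res$valid)
  expect_identical(res$reason, "insufficient wear evidence")

  floor_rule <- rule_for("fitbit")
  res2 <- is_valid_day(make_record("p", "fitbit", "2019-01-01"),
                       floor_rule)
  expect_false(res2$valid)

  cap_rule <- rule_for("polar")
  res3 <- is_valid_day(make_record("p", "polar", "2019-01-01",
                                   steps = 9000), cap_rule)
  expect_false(res3$valid)
  expect_identical(res3$reason, "insufficient wear evidence")
})

test_that("filter_valid partitions the input and judges per provider", {
  steps <- c(0, 100, 150, 151, 600, 1200, 2500, 3700, 4800, 5000)
  fitbit_days <- make_records(lapply(seq_along(steps), function(i) {
    make_record("f1", "fitbit", as.Date("2019-04-01") + i - 1,
                steps = steps[i])
  }))
  polar_day <- make_record("p1", "polar", "2019-04-01", steps = 10,
                           nonwear = 100)
  out <- filter_valid(dplyr::bind_rows(fitbit_days, polar_day))
  expect_identical(out$n_valid + out$n_excluded, 11L)
  expect_identical(sum(out$valid_days$provider == "fitbit"),
                   sum(steps > 150))
  # the polar day has only 10 steps yet is valid under its own rule
  expect_true("p1" %in% out$valid_days$participant_id)
  expect_identical(nrow(out$exclusions), out$n_excluded)
  expect_named(out$exclusions,
               c("participant_id", "date", "provider", "rule", "reason"))
})

test_that("filter_valid is deterministic and idempotent", {
  cohort <- generate_cohort(small_cohort_config(), seed = 3)
  once <- filter_valid(cohort)
  again <- filter_valid(cohort)
  expect_identical(once$valid_days, again$valid_days)
  cols <- names(cohort)
  twice <- filter_valid(once$valid_days[cols])
  expect_identical(twice$n_excluded, 0L)
  expect_identical(twice$valid_days[cols], once$valid_days[cols])
})

test_that("empty input yields an empty partition", {
  out <- filter_valid(trackdays:::empty_canonical())
  expect_identical(out$n_valid, 0L)
  expect_identical(out$n_excluded, 0L)
  expect_identical(nrow(out$valid_days), 0L)
})

test_that("validity is monotone in the rule's direction", {
  set.seed(42)
  floor_rule <- rule_for("fitbit")
  cap_rule <- rule_for("polar")
  for (i in 1:50) {
    s <- runif(1, 0, 400)
    rec <- make_record("p", "fitbit", "2019-01-01", steps = s)
    more <- make_record("p", "fitbit", "2019-01-01",
                        steps = s + runif(1, 0, 400))
    expect_true(is_valid_day(more, floor_rule)$valid >=
                  is_valid_day(rec, floor_rule)$valid)

    nw <- runif(1, 600, 1100)
    recn <- make_record("p", "polar", "2019-01-01", steps = 1,
                        nonwear = nw)
    less <- make_record("p", "polar", "2019-01-01", steps = 1,
                        nonwear = nw - runif(1, 0, 600))
    expect_true(is_valid_day(less, cap_rule)$valid >=
                  is_valid_day(recn, cap_rule)$valid)
  }
})
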