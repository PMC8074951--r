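# Builders and independent oracles shared across the test files.

# One canonical record with every unspecified field absent.
make_record <- function(participant_id, provider, date,
                        steps = NA, tee = NA, aee = NA, ree = NA,
                        lpa = NA, mpa = NA, vpa = NA,
                        sedentary = NA, sleep = NA, nonwear = NA) {
  tibble::tibble(
    participant_id = participant_id, provider = provider,
    date = as.Date(date),
    steps = as.numeric(steps), tee = as.numeric(tee),
    aee = as.numeric(aee), ree = as.numeric(ree),
    lpa = as.numeric(lpa), mpa = as.numeric(mpa), vpa = as.numeric(vpa),
    sedentary = as.numeric(sedentary), sleep = as.numeric(sleep),
    nonwear = as.numeric(nonwear)
  )
}

make_records <- function(...) dplyr::bind_rows(...)

# A cohort configuration small enough for fast unit tests (full-size
# cohorts are exercised in the acceptance suite).
small_cohort_config <- function(...) {
  cohort_config(n_participants = 10,
                provider_mix = c(fitbit = 5, garmin = 5), ...)
}

# Brute-force two-sided signed-rank p: enumerate all 2^n equiprobable
# sign assignments of the (mid)ranks and compare the positive-rank sum
# against the observed one. Independent of the convolution code path.
brute_force_signed_rank_p <- function(diffs, zero_method = "drop") {
  if (zero_method == "drop") {
    nz <- diffs[diffs != 0]
    r <- rank(abs(nz))
    w <- sum(r[nz > 0])
  } else {
    r_all <- rank(abs(diffs))
    keep <- diffs != 0
    nz <- diffs[keep]
    r <- r_all[keep]
    w <- sum(r[nz > 0])
  }
  n <- length(r)
  if (n == 0) return(NA_real_)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w), mean(w_all >= w)))
}

# Paired contrast of two custom windows through the real pipeline;
# returns the within-participant differences (window_b minus window_a).
window_contrast_diffs <- function(records, variable,
                                  window_a, window_b,
                                  config = trackdays_config()) {
  window_a <- as.Date(window_a)
  window_b <- as.Date(window_b)
  sub <- records[(records$date >= window_a[1] &
                    records$date <= window_a[2]) |
                   (records$date >= window_b[1] &
                      records$date <= window_b[2]), ]
  fv <- filter_valid(sub, config)
  periods <- dplyr::bind_rows(
    period("win_a", window_a[1], window_a[2]),
    period("win_b", window_b[1], window_b[2])
  )
  smry <- summarize_periods(fv$valid_days, periods, variable,
                            min_days = config$min_days)
  ya <- as.integer(format(window_a[1], "%Y"))
  yb <- as.integer(format(window_b[1], "%Y"))
  build_pairs(smry, variable, "win_a", ya, "win_b", yb,
              min_pairs = config$min_pairs)$diff
}
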