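# Paired two-period tests ------------------------------------------------

#' Paired t-test on within-participant differences
#'
#' Classical one-sample t on the paired differences, with an equal-tailed
#' 95% t-interval for the mean difference. Zero-variance differences give
#' a degenerate result (p undefined) rather than an error.
#'
#' @param diffs Numeric vector of paired differences (later period minus
#'   earlier period).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List: `estimate` (mean difference), `ci_lo`, `ci_hi`,
#'   `statistic`, `df`, `p`, `degenerate`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3))
paired_t <- function(diffs, conf_level = 0.95) {
  stopifnot(is.numeric(diffs), length(diffs) >= 2, !anyNA(diffs))
  if (stats::sd(diffs) == 0) {
    return(list(estimate = mean(diffs), ci_lo = mean(diffs),
                ci_hi = mean(diffs), statistic = NA_real_,
                df = length(diffs) - 1L, p = NA_real_, degenerate = TRUE))
  }
  fit <- stats::t.test(diffs, conf.level = conf_level)
  list(estimate = unname(fit$estimate),
       ci_lo = fit$conf.int[1], ci_hi = fit$conf.int[2],
       statistic = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, degenerate = FALSE)
}

# Exact null distribution of the positive-rank sum W+ for given (mid)ranks.
# Ranks are doubled so midranks (x.5 under ties) become integers; the
# distribution is built by convolution over the 2^n equiprobable sign
# assignments. Returns P(W+ <= w) and P(W+ >= w) at the observed value.
signed_rank_exact_p <- function(ranks, w_obs) {
  d <- as.integer(round(2 * ranks))
  total <- sum(d)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (di in d) {
    shifted <- c(numeric(di), f[seq_len(total + 1L - di)])
    f <- f + shifted
  }
  f <- f / 2^length(d)
  w2 <- round(2 * w_obs)
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# Tie-corrected normal approximation; mu/sigma2 are the null moments of
# W+ (conditional on the observed tie pattern). No continuity correction:
# with midranked ties the support is not an integer lattice.
signed_rank_normal_p <- function(w_obs, mu, sigma2) {
  if (sigma2 <= 0) return(NA_real_)
  z <- (w_obs - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test with the classical zero-handling
#' convention: zero differences are dropped before ranking (set
#' `zero_method = "pratt"` to rank them and then discard their ranks).
#' Ties are midranked. For effective n at most `exact_max_n` the p-value
#' comes from the exact null distribution of the positive-rank sum
#' (enumeration over all sign assignments, by convolution); above that, a
#' tie-corrected normal approximation is used. The location summary is
#' the plain median of the raw differences with their quartile range
#' (zeros included), matching the median (IQR) reporting convention —
#' not the Hodges-Lehmann pseudomedian.
#'
#' @param diffs Numeric vector of paired differences.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_max_n Largest effective n for the exact distribution
#'   (default 25).
#' @return List: `estimate` (median difference), `iqr_lo`, `iqr_hi`,
#'   `statistic` (W+), `n_effective`, `method` (`"exact"` or
#'   `"approx"`), `p`, `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))
wilcoxon_signed_rank <- function(diffs, zero_method = c("drop", "pratt"),
                                 exact_max_n = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(is.numeric(diffs), length(diffs) >= 2, !anyNA(diffs))
  est <- stats::median(diffs)
  qs <- stats::quantile(diffs, c(0.25, 0.75), names = FALSE)
  base <- list(estimate = est, iqr_lo = qs[1], iqr_hi = qs[2])

  nz <- diffs[diffs != 0]
  if (length(nz) == 0L) {
    return(c(base, list(statistic = NA_real_, n_effective = 0L,
                        method = "degenerate", p = NA_real_,
                        degenerate = TRUE)))
  }
  if (zero_method == "drop") {
    ranks_used <- rank(abs(nz))
    w <- sum(ranks_used[nz > 0])
  } else {
    # Pratt: zeros participate in ranking, then their ranks are removed.
    r_all <- rank(abs(diffs))
    keep <- diffs != 0
    ranks_used <- r_all[keep]
    w <- sum(r_all[keep & diffs > 0])
  }
  n_eff <- length(ranks_used)
  # Null moments of W+ = sum r_i * Bern(1/2): exact under midranked ties
  # (reduces to the textbook tie-corrected formulas when zeros are
  # dropped).
  mu <- sum(ranks_used) / 2
  sigma2 <- sum(ranks_used^2) / 4
  if (n_eff <= exact_max_n) {
    p <- signed_rank_exact_p(ranks_used, w)
    method <- "exact"
  } else {
    p <- signed_rank_normal_p(w, mu, sigma2)
    method <- "approx"
  }
  c(base, list(statistic = w, n_effective = as.integer(n_eff),
               method = method, p = p, degenerate = FALSE))
}

#' Normality gate for the paired-test choice
#'
#' Reproducible stand-in for a visual histogram check: Shapiro-Wilk on
#' the paired differences at `alpha`. `TRUE` means the paired t-test
#' will be used, `FALSE` the Wilcoxon signed-rank test. Constant
#' differences (zero variance) are degenerate and return `FALSE` with a
#' `"degenerate"` attribute.
#'
#' @param diffs Numeric vector of paired differences, length >= 3.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return Logical scalar.
#' @export
assess_normality <- function(diffs, alpha = 0.05) {
  stopifnot(is.numeric(diffs), !anyNA(diffs))
  if (length(diffs) < 3) {
    stop("normality assessment requires at least 3 differences",
         call. = FALSE)
  }
  if (stats::sd(diffs) == 0) {
    return(structure(FALSE, degenerate = TRUE))
  }
  stats::shapiro.test(diffs)$p.value >= alpha
}
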