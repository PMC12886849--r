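#' Turnover rate from a similarity schedule
#'
#' The short-term turnover rate of a community is the rate at which its mean
#' pairwise similarity declines with lag: an ordinary least-squares fit of
#' mean similarity against lag (with intercept) over the lags present in the
#' schedule, reported as the negative of the slope so that declining
#' similarity gives a positive rate (units: similarity per year). The
#' intercept is always estimated rather than pinned at 1 for lag 0, because
#' the lag-0 to lag-1 drop is dominated by false-negative pseudo-turnover
#' which biases all non-zero lags about equally; regressing over lags >= 1
#' bypasses it.
#'
#' Schedules with fewer than two lag points are an exclusion signal
#' (`rate = NA`), never a zero. The nominal OLS slope standard error is
#' reported only when at least three lags are available.
#'
#' @param schedule [mean_similarity_by_lag()] result.
#' @param lags Integer lags eligible for the regression (default `1:5`).
#' @param weight_by_pairs Weight lag means by their pair counts (default
#'   `FALSE`, plain unweighted regression).
#' @return One-row tibble: `rate`, `se`, `intercept`, `n_lags`.
#' @examples
#' sched <- tibble::tibble(lag = 1:5,
#'                         similarity = c(.90, .88, .86, .84, .82),
#'                         n_pairs = 10L)
#' turnover_rate(sched) # rate 0.02, se 0
#' @export
turnover_rate <- function(schedule, lags = 1:5, weight_by_pairs = FALSE) {
  sel <- schedule$lag %in% lags & !is.na(schedule$similarity)
  x <- schedule$lag[sel]
  y <- schedule$similarity[sel]
  n <- length(x)
  if (n < 2) {
    return(tibble::new_tibble(list(rate = NA_real_, se = NA_real_,
                                   intercept = NA_real_, n_lags = n),
                              nrow = 1L))
  }
  w <- if (weight_by_pairs) as.numeric(schedule$n_pairs[sel]) else
    rep(1, n)
  # closed-form (weighted) OLS with intercept; nominal slope SE as in lm()
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  se <- if (n >= 3) {
    resid <- y - intercept - slope * x
    sqrt(sum(w * resid^2) / (n - 2) / sxx)
  } else {
    NA_real_
  }
  tibble::new_tibble(list(rate = -slope, se = se, intercept = intercept,
                          n_lags = n), nrow = 1L)
}

#' Change in turnover rate across a breakpoint
#'
#' The since-minus-before difference of two turnover-rate estimates for the
#' same community, so that accelerating turnover is positive and
#' decelerating turnover negative. The standard error of the change is the
#' square root of the sum of squares of the two period standard errors
#' (standard error propagation); it is undefined if either period's SE is.
#' If either period's rate is undefined the change is undefined and the
#' community is excluded for this breakpoint.
#'
#' @param before,since One-row tibbles from [turnover_rate()].
#' @return One-row tibble: `delta`, `se_delta`.
#' @export
turnover_change <- function(before, since) {
  tibble::new_tibble(
    list(delta = since$rate - before$rate,
         se_delta = sqrt(before$se^2 + since$se^2)),
    nrow = 1L
  )
}
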