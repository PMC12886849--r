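#' Community eligibility for a breakpoint analysis
#'
#' A community enters the analysis for a given breakpoint year only when its
#' time series starts more than `max_lag` years before and ends at least
#' `max_lag` years after the breakyear, so that both periods can support the
#' full lag range.
#'
#' @param first_year,last_year First and last surveyed years (vectorised).
#' @param breakyear Candidate breakpoint year.
#' @param max_lag Largest lag used in the turnover regression (default 5).
#' @return Logical vector.
#' @examples
#' eligible_series(1965, 1985, 1975) # TRUE
#' eligible_series(1970, 1985, 1975) # FALSE: starts exactly 5 before
#' @export
eligible_series <- function(first_year, last_year, breakyear, max_lag = 5) {
  first_year < breakyear - max_lag & last_year >= breakyear + max_lag
}

#' Split survey years into before/since periods
#'
#' The breakyear itself belongs to the "since" period. Year pairs straddling
#' the breakyear contribute to neither period's similarity schedule (both
#' members of a pair must fall in the same period), which
#' [mean_similarity_by_lag()] enforces when given each period's years.
#'
#' @param years Integer vector of surveyed years.
#' @param breakyear Breakpoint year.
#' @return List with integer vectors `before` (`y < breakyear`) and `since`
#'   (`y >= breakyear`).
#' @export
split_periods <- function(years, breakyear) {
  list(before = years[years < breakyear], since = years[years >= breakyear])
}

#' Exclude exactly-zero turnover changes
#'
#' Communities whose before/since turnover rates are exactly equal (usually
#' both zero: a few persistent species, no compositional change resolved)
#' are discarded before computing median changes, because including them
#' would bias the median and complicate the sign-test null. Comparison is
#' exact: such deltas arise from identical discrete schedules.
#'
#' @param changes Tibble with a `delta` column.
#' @param tolerance Absolute tolerance for "zero" (default 0, exact).
#' @return Filtered tibble; attribute `n_zero_excluded` counts removals.
#' @export
exclude_zero_changes <- function(changes, tolerance = 0) {
  zero <- abs(changes$delta) <= tolerance
  out <- changes[!zero, ]
  attr(out, "n_zero_excluded") <- sum(zero)
  out
}

#' Median with exact (order-statistic) confidence interval and sign test
#'
#' Distribution-free inference for the median: the confidence interval is
#' the pair of order statistics `(x_(k), x_(n-k+1))` with `k` the largest
#' integer such that the binomial(n, 1/2) probability of fewer than `k`
#' successes is at most `(1 - confidence)/2` — a conservative exact
#' interval. Its inversion is the two-sided exact sign test on the counts of
#' positive versus negative values: the interval excludes zero exactly when
#' the sign test rejects at the same level. When `k = 0` (n too small for
#' any finite interval at the requested confidence, e.g. n <= 5 at 95%) the
#' interval is unbounded (`-Inf`, `Inf`).
#'
#' @param values Numeric vector (zeros should have been excluded upstream;
#'   the sign test ignores any that remain).
#' @param confidence Confidence level (default 0.95).
#' @return One-row tibble: `n`, `median`, `ci_low`, `ci_high`,
#'   `sign_test_p`, `n_positive`, `n_negative`.
#' @examples
#' median_exact_ci(c(.1, .2, .3, .4, .5, .6)) # CI (x1, x6), p = 2 * 2^-6
#' @export
median_exact_ci <- function(values, confidence = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    return(tibble::tibble(n = 0L, median = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, sign_test_p = NA_real_,
                          n_positive = 0L, n_negative = 0L))
  }
  x <- sort(values)
  alpha <- (1 - confidence) / 2
  # largest k with P(Binom(n, 1/2) < k) <= alpha; pbinom(k - 1, ...) form
  ks <- 0:ceiling(n / 2)
  k <- max(ks[pbinom(ks - 1, n, 0.5) <= alpha])
  ci <- if (k >= 1) c(x[k], x[n - k + 1]) else c(-Inf, Inf)
  np <- sum(values > 0)
  nn <- sum(values < 0)
  p <- if (np + nn > 0) binom.test(np, np + nn, 0.5)$p.value else NA_real_
  tibble::tibble(n = n, median = median(x), ci_low = ci[1], ci_high = ci[2],
                 sign_test_p = p, n_positive = np, n_negative = nn)
}

# per-community turnover changes for one breakyear, given precomputed
# pairwise similarities
changes_for_breakyear <- function(sims_tbl, breakyear, max_lag, lags) {
  rows <- purrr::pmap(
    list(sims_tbl$community_id, sims_tbl$taxon_group, sims_tbl$pair_sims,
         sims_tbl$first_year, sims_tbl$last_year),
    function(cid, taxon, ps, fy, ly) {
      if (!eligible_series(fy, ly, breakyear, max_lag)) return(NULL)
      yrs <- sort(unique(c(ps$year_i, ps$year_j)))
      per <- split_periods(yrs, breakyear)
      est <- lapply(per, function(p) {
        turnover_rate(mean_similarity_by_lag(ps, years = p,
                                             max_lag = max_lag), lags = lags)
      })
      if (is.na(est$before$rate) || is.na(est$since$rate)) return(NULL)
      ch <- turnover_change(est$before, est$since)
      tibble::new_tibble(
        list(community_id = cid, taxon_group = taxon, delta = ch$delta,
             se_delta = ch$se_delta, rate_before = est$before$rate,
             rate_since = est$since$rate),
        nrow = 1L
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Per-community turnover changes at one breakpoint year
#'
#' Runs the full per-community pipeline for a single breakyear: rarefied
#' pairwise similarities (computed once per community), eligibility, period
#' splitting, per-period lag regression, and the since-minus-before change
#' with propagated SE. Exactly-zero changes are retained here (they are
#' excluded at the summary stage) so the table can also feed precision
#' diagnostics such as delta-versus-SE plots.
#'
#' @param series [build_series()] tibble.
#' @param breakyear Breakpoint year.
#' @inheritParams breakpoint_scan
#' @return Tibble: `community_id`, `taxon_group`, `delta`, `se_delta`,
#'   `rate_before`, `rate_since`.
#' @export
turnover_changes_at <- function(series, breakyear, max_lag = 5,
                                lags = 1:max_lag, index = "ochiai",
                                n_subsamples = 100, seed = 1) {
  sims_tbl <- precompute_pair_sims(series, index, n_subsamples, seed)
  changes_for_breakyear(sims_tbl, breakyear, max_lag, lags)
}

precompute_pair_sims <- function(series, index, n_subsamples, seed) {
  dplyr::mutate(
    tibble::as_tibble(series),
    pair_sims = purrr::map2(.data$obs, .data$community_id, function(o, cid) {
      rarefied_pair_similarities(o, index = index,
                                 n_subsamples = n_subsamples,
                                 seed = seed, community_id = cid)
    })
  )
}

summarise_changes <- function(changes, confidence) {
  kept <- exclude_zero_changes(changes)
  s <- median_exact_ci(kept$delta, confidence)
  dplyr::mutate(
    dplyr::rename(s, n_communities = "n", median_delta = "median"),
    n_zero_excluded = attr(kept, "n_zero_excluded"),
    .after = "n_communities"
  )
}

#' Scan breakpoint years
#'
#' For every candidate breakpoint year: select eligible communities, split
#' each community's (precomputed, rarefied) pairwise similarities into
#' before/since schedules, regress similarity on lag per period, form the
#' since-minus-before change, drop exactly-zero changes, and summarise the
#' remainder by the median with its exact confidence interval and sign-test
#' p value — overall and, optionally, per taxon group. Rarefied similarities
#' are computed once per community and reused across breakyears.
#' Breakyears where no community survives the exclusions are reported with
#' `NA` summaries (inconclusive), not dropped.
#'
#' @param series [build_series()] tibble.
#' @param breakyears Integer vector of candidate breakpoint years.
#' @param max_lag Largest lag (default 5); also sets the eligibility margin.
#' @param lags Lags used in the regression (default `1:max_lag`).
#' @param index Similarity index name or function (default `"ochiai"`).
#' @param n_subsamples Rarefaction passes per community (default 100).
#' @param confidence Confidence level for the median CI (default 0.95).
#' @param seed Master seed for rarefaction.
#' @param by_taxon Also summarise per taxon group (default `FALSE`).
#' @return Tibble of class `breakpoint_scan`, one row per (breakyear,
#'   stratum): `breakyear`, `stratum`, `n_communities`, `n_zero_excluded`,
#'   `median_delta`, `ci_low`, `ci_high`, `sign_test_p`, `n_positive`,
#'   `n_negative`.
#' @export
breakpoint_scan <- function(series, breakyears, max_lag = 5,
                            lags = 1:max_lag, index = "ochiai",
                            n_subsamples = 100, confidence = 0.95, seed = 1,
                            by_taxon = FALSE) {
  sims_tbl <- precompute_pair_sims(series, index, n_subsamples, seed)
  out <- purrr::map(breakyears, function(by) {
    ch <- changes_for_breakyear(sims_tbl, by, max_lag, lags)
    if (nrow(ch) == 0) {
      ch <- tibble::tibble(community_id = character(),
                           taxon_group = character(), delta = double(),
                           se_delta = double())
    }
    overall <- dplyr::mutate(summarise_changes(ch, confidence),
                             stratum = "overall", .before = 1)
    strata <- overall
    if (by_taxon && nrow(ch) > 0) {
      per_tax <- ch |>
        dplyr::group_by(stratum = .data$taxon_group) |>
        dplyr::group_modify(~ summarise_changes(.x, confidence)) |>
        dplyr::ungroup()
      strata <- dplyr::bind_rows(overall, per_tax)
    }
    dplyr::mutate(strata, breakyear = by, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("breakpoint_scan", class(out))
  out
}
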