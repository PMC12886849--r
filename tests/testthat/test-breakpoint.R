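test_that("eligibility needs > max_lag years before and >= max_lag after", {
  expect_true(eligible_series(1965, 1985, 1975))
  expect_false(eligible_series(1970, 1985, 1975)) # starts exactly 5 before
  expect_false(eligible_series(1960, 1979, 1975)) # ends only 4 after
  expect_true(eligible_series(1969, 1980, 1975))
  expect_false(eligible_series(1960, 1984, 1975, max_lag = 10))
})

test_that("the breakyear belongs to the since period", {
  per <- split_periods(1970:1980, 1975)
  expect_equal(per$before, 1970:1974)
  expect_equal(per$since, 1975:1980)
  expect_equal(split_periods(1980:1985, 1975)$before, integer(0))
})

test_that("exactly-zero changes are excluded and counted", {
  ch <- tibble::tibble(delta = c(0.01, 0, -0.02))
  out <- exclude_zero_changes(ch)
  expect_equal(out$delta, c(0.01, -0.02))
  expect_equal(attr(out, "n_zero_excluded"), 1L)
  allz <- exclude_zero_changes(tibble::tibble(delta = c(0, 0)))
  expect_equal(nrow(allz), 0)
  none <- exclude_zero_changes(ch[ch$delta != 0, ])
  expect_equal(attr(none, "n_zero_excluded"), 0L)
})

test_that("exact median CI and sign test match hand-computed binomials", {
  six <- median_exact_ci(c(.05, .1, .2, .3, .4, .6))
  expect_equal(six$ci_low, 0.05) # k = 1: interval is (x(1), x(6))
  expect_equal(six$ci_high, 0.6)
  expect_gt(six$ci_low, 0)
  expect_equal(six$sign_test_p, 2 * 0.5^6)
  expect_equal(six$median, 0.25)

  five <- median_exact_ci(c(.1, .2, .3, .4, .5))
  expect_equal(five$sign_test_p, 2 * 0.5^5) # 0.0625: not significant
  expect_equal(five$ci_low, -Inf) # no finite 95% interval at n = 5
  expect_equal(five$ci_high, Inf)

  sym <- median_exact_ci(c(-3, -2, -1, 1, 2, 3))
  expect_equal(sym$median, 0)
  expect_lte(sym$ci_low, 0)
  expect_gte(sym$ci_high, 0)

  empty <- median_exact_ci(numeric(0))
  expect_true(is.na(empty$median))
})

test_that("CI excluding zero is equivalent to sign-test rejection (n <= 10)", {
  for (n in 1:10) {
    for (bits in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(bits, 2^(0:(n - 1))) > 0, 1, -1)
      s <- median_exact_ci(signs * seq_len(n))
      excl <- s$ci_low > 0 || s$ci_high < 0
      expect_equal(excl, s$sign_test_p < 0.05)
    }
  }
})

test_that("order-statistic interval brackets the sample median", {
  set.seed(11)
  for (n in c(6, 11, 24, 101)) {
    s <- median_exact_ci(rnorm(n))
    expect_lte(s$ci_low, s$median)
    expect_gte(s$ci_high, s$median)
    expect_equal(s$n_positive + s$n_negative, s$n)
  }
})

test_that("scan pipeline detects a true deceleration and reports strata", {
  cfg <- synthetic_config(n_communities = 60, years = 1960:1990,
                          replacement_rate_before = 0.10,
                          replacement_rate_after = 0.05, seed = 21)
  ens <- generate_ensemble(cfg)
  ser <- build_series(ens$records)
  scan <- breakpoint_scan(ser, breakyears = c(1975, 2030), by_taxon = TRUE)
  at_true <- dplyr::filter(scan, breakyear == 1975, stratum == "overall")
  expect_lt(at_true$ci_high, 0)
  expect_lt(at_true$sign_test_p, 0.05)
  expect_equal(at_true$n_communities, 60L)
  taxa <- dplyr::filter(scan, breakyear == 1975, stratum != "overall")
  expect_setequal(taxa$stratum, c("birds", "fish", "benthos", "all"))
  expect_equal(sum(taxa$n_communities), 60L)
  # a breakyear outside the data span is inconclusive, not dropped
  out_of_span <- dplyr::filter(scan, breakyear == 2030, stratum == "overall")
  expect_equal(nrow(out_of_span), 1L)
  expect_equal(out_of_span$n_communities, 0L)
  expect_true(is.na(out_of_span$median_delta))
})

test_that("under the null of no change, CIs exclude zero at about the
          nominal rate", {
  # equal replacement rates before/since: any detected "change" is type I
  rejections <- vapply(1:60, function(seed) {
    cfg <- synthetic_config(n_communities = 30, years = 1962:1988,
                            replacement_rate_before = 0.08,
                            replacement_rate_after = 0.08, seed = 4000 + seed)
    ser <- build_series(generate_ensemble(cfg)$records)
    ch <- exclude_zero_changes(turnover_changes_at(ser, 1975))
    s <- median_exact_ci(ch$delta)
    isTRUE(s$ci_low > 0 || s$ci_high < 0)
  }, TRUE)
  # exact type-I level at n = 30 is 4.3%; allow binomial slack on 60 draws
  expect_lte(mean(rejections), 0.15)
})

test_that("a single eligible community cannot exclude zero", {
  cfg <- synthetic_config(n_communities = 1, years = 1960:1990, seed = 3)
  ser <- build_series(generate_ensemble(cfg)$records)
  scan <- breakpoint_scan(ser, breakyears = 1975)
  expect_equal(scan$n_communities, 1L)
  expect_equal(scan$ci_low, -Inf)
  expect_equal(scan$ci_high, Inf)
})

test_that("ineligible and zero-delta communities do not perturb summaries", {
  cfg <- synthetic_config(n_communities = 12, years = 1960:1990,
                          replacement_rate_before = 0.10,
                          replacement_rate_after = 0.05, seed = 5)
  ser <- build_series(generate_ensemble(cfg)$records)
  base <- breakpoint_scan(ser, breakyears = 1975)

  # an ineligible community: series starts exactly 5 years before breakyear
  frozen_cfg <- synthetic_config(n_communities = 1, years = 1970:1990,
                                 replacement_rate_before = 0,
                                 replacement_rate_after = 0, seed = 99)
  extra <- generate_ensemble(frozen_cfg)$records
  extra$community_id <- "ineligible"
  with_extra <- breakpoint_scan(dplyr::bind_rows(
    ser_to_records(ser), extra) |> build_series(), breakyears = 1975)
  expect_equal(with_extra$median_delta, base$median_delta)
  expect_equal(with_extra$n_communities, base$n_communities)

  # an eligible but frozen community contributes an exact-zero delta only
  frozen2 <- generate_ensemble(
    synthetic_config(n_communities = 1, years = 1960:1990,
                     replacement_rate_before = 0,
                     replacement_rate_after = 0, seed = 98))$records
  frozen2$community_id <- "frozen"
  with_zero <- breakpoint_scan(dplyr::bind_rows(
    ser_to_records(ser), frozen2) |> build_series(), breakyears = 1975)
  expect_equal(with_zero$median_delta, base$median_delta)
  expect_equal(with_zero$n_zero_excluded, base$n_zero_excluded + 1L)
})
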