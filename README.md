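# lagturn

Tools for measuring **long-term change in short-term species turnover** from
presence/absence community survey time series, and for exploring, in a
Lotka–Volterra community model, why turnover can *slow down* even as the
environment changes faster.

## The problem

Temporal species turnover — the ongoing replacement of the species making up
a local community — can be driven by environmental change or by intrinsic
community dynamics (colonisation from a regional pool, competitive
displacement, extirpation). Survey time series let us ask whether turnover
has accelerated or decelerated over decades, but the raw data are messy:
sampling effort varies between years, surveys miss species that are present
(false negatives, producing *pseudo-turnover*), and many series have gaps.

`lagturn` implements an estimation pipeline built to be robust to exactly
these problems:

1. **Similarity.** Compositional similarity between two survey years is
   measured on presence/absence with the Ochiai index
   `a / sqrt((a + b)(a + c))` (`a` shared species, `b`/`c` unique to either
   year). Sørensen and Jaccard are available for robustness checks; Ochiai
   is the default because the lag-difference of its values has the smaller
   coefficient of variation under random false negatives (the package
   verifies this by Monte Carlo, see `cv_robustness_mc()`).
2. **Rarefaction.** Unequal effort is equalised by subsampling every survey
   year down to the series' minimum number of within-year samples, 100
   times, and averaging (`rarefied_pair_similarities()`).
3. **Turnover rate.** The turnover rate of a community is the negative OLS
   slope of mean similarity against lag over lags 1–5 years
   (`mean_similarity_by_lag()`, `turnover_rate()`). Regressing over non-zero
   lags bypasses pseudo-turnover, which biases all non-zero lags about
   equally (it shifts the intercept, not the slope).
4. **Breakpoint comparison.** For a candidate breakpoint year, eligible
   communities (starting more than 5 years before, ending at least 5 years
   after) get a before-rate and a since-rate; the since-minus-before
   difference is summarised across communities by its **median with the
   exact order-statistic confidence interval**, whose inversion is the
   two-sided sign test (`median_exact_ci()`, `breakpoint_scan()`).
5. **Climate context.** A recursive delayed-response filter
   `y_t = e^{-1/d} y_{t-1} + (1 - e^{-1/d}) x_t` smooths an annual climate
   anomaly series the way slow community responses would
   (`delayed_series()`).
6. **Mechanistic model.** A Lotka–Volterra competition simulator
   (`lv_params()`, `lv_integrate()`, `factorial_experiment()`,
   `fit_surface()`) reproduces intrinsic turnover driven by re-invasion from
   a large species pool and shows how environmental *degradation* (a uniform
   growth-rate reduction `d`) slows turnover while environmental *shift* (a
   moving niche optimum at rate `v`) speeds it.

A synthetic survey generator with exact closed-form expected similarities
(`synthetic_config()`, `generate_ensemble()`,
`expected_similarity_by_lag()`) provides ground truth for validating every
stage.

## Worked example

```r
library(lagturn)

# synthetic ensemble: 400 communities, replacement rate dropping by a third
# (0.09 -> 0.06 per year) at 1975
cfg <- synthetic_config(n_communities = 400, years = 1955:1995,
                        breakyear = 1975,
                        replacement_rate_before = 0.09,
                        replacement_rate_after = 0.06, seed = 77)
ens <- generate_ensemble(cfg)
series <- build_series(ens$records)

changes <- turnover_changes_at(series, breakyear = 1975)
summary_1975 <- median_exact_ci(exclude_zero_changes(changes)$delta)
summary_1975
#> # A tibble: 1 × 7
#>       n  median  ci_low ci_high sign_test_p n_positive n_negative
#>   <int>   <dbl>   <dbl>   <dbl>       <dbl>      <int>      <int>
#> 1   400 -0.0186 -0.0199 -0.0174   1.20e-104          8        392
```

The median change in turnover rate is −0.0186 similarity units per year
with a 95% confidence interval entirely below zero: turnover decelerated in
significantly more communities than it accelerated, as built into the
generator. The analytic expectation for this configuration
(`expected_turnover_rate(cfg, period = "after") -
expected_turnover_rate(cfg, period = "before")`) is −0.0187 per year.

Scanning many candidate breakyears and plotting:

```r
scan <- breakpoint_scan(series, breakyears = 1965:1988, by_taxon = TRUE)
autoplot(scan)
```

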