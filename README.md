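# windmatch

Matched-pair causal inference for wind-driven air pollution.

Epidemiological and economic studies often use daily wind direction as a
source of quasi-experimental variation in air-pollutant exposure. Whether a
day's wind blows from a polluting sector (here: the North-East, 10°–90°) is,
however, not randomly distributed over time — it co-varies with season,
temperature, humidity and wind speed, all of which also drive pollutant
concentrations. `windmatch` embeds such an observational daily time series
within a *hypothetical pairwise randomized experiment*, instead of relying on
a regression model to adjust and extrapolate:

1. **Treatment definition.** Day *i* is treated (`W_i = 1`) when the wind
   direction lies in the configured North-East sector. Under SUTVA each day
   has two potential concentrations `Y_i(0)`, `Y_i(1)` per pollutant, and the
   observed value is `Y_obs = (1 − W) Y(0) + W Y(1)`.
2. **Design.** A constrained bipartite matching pairs each treated day with
   at most one control day: calendar gap in [4, 60] days (the lower bound
   limits between-day interference, the upper bound keeps pairs within
   season), exact agreement on weekend / holiday / bank-day / rainfall
   category / previous-day treatment, and calipers on temperature (5 °C),
   wind speed (0.5 m/s), humidity (12 pp) and previous-day PM10 (8 µg/m³).
   Among all maximum-cardinality matchings the one of minimum total
   (caliper-normalised L1) distance is returned, solved exactly as a
   min-cost flow.
3. **Analysis.** Neymanian inference on the J matched pairs:
   `tau_hat = (1/J) Σ_j d_j` with `d_j` the treated-minus-control difference,
   the conservative variance
   `V_hat = Σ_j (d_j − tau_hat)² / (J (J − 1))` (exactly unbiased under a
   constant effect), and Gaussian intervals `tau_hat ± 1.96 √V_hat`
   (95%) and `± 2.576 √V_hat` (99%), per outcome for the previous, current
   and following day.
4. **Sensitivity.** Rosenbaum-style quantitative bias analysis on the
   Wilcoxon signed-rank statistic: worst-case p-value bounds and
   Γ-adjusted confidence intervals over all hidden biases that multiply the
   within-pair treatment odds by at most Γ, plus negative-control
   (previous-day) outcome checks and a pairwise-vs-complete randomization
   precision comparison.

A seeded synthetic generator (`synthetic_config()`, `generate_dataset()`)
produces daily datasets with the same statistical structure — seasonal
weather, mixture-distributed wind direction, AR(1) pollutant baselines —
plus the *hidden* potential outcomes and an optional unmeasured confounder,
so every stage of the pipeline can be validated against known ground truth.

## Worked example

```r
library(windmatch)

synth  <- generate_dataset(synthetic_config(), seed = 1)  # 4018 days, true PM10 effect = 5
design <- match_pairs(synth$data)
design
#> Matched pairwise design (optimal matching)
#>   treated days:  1038
#>   control days:  2980
#>   matched pairs: 118 (11.4% of treated)
#>   total distance: 282.8; mean 2.4

d <- pair_differences(design$data, design, "pm10", 0)
neyman_estimate(d, outcome = "pm10", offset = 0L,
                control_mean = mean(design$data$pm10[design$pairs$control_id]))
#> pm10: tau_hat = 5.37 ug/m3 (J = 118 pairs)
#>   95% CI (3.53, 7.22); 99% CI (2.95, 7.8); SE 0.942
#>   relative increase: 23.4% of the matched control mean

sensitivity_interval(d, gamma = 2)
#> Gamma = 2 sensitivity interval (alpha = 0.05)
#>   interval: (0.173, 10.8) ug/m3
#>   worst-case one-sided p at tau0 = 0: [0, 0.0172]
#>   Hodges-Lehmann estimate: 5.62
#>   method: Wilcoxon signed-rank, normal approximation, no continuity correction
```

Only 11–13% of treated days find an admissible control — the price of
demanding genuine comparability — yet the matched estimate brackets the true
effect of 5 µg/m³, and even if an unmeasured confounder doubled the odds of
North-East wind within pairs, the worst-case 95% interval would stay
positive. `lead_lag_effects()` extends the table to all pollutants and day
offsets, `balance_table()` / `plot(design)` quantify covariate balance
before vs after matching, `negative_control_check()` tests the previous-day
outcomes, and `run_pipeline()` drives all four stages from one config and
writes CSV artifacts plus a report.

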