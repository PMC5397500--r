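# popharvest

Population-based modelling of fruit growth, ripening and harvest-strategy
optimization, developed for open-field tomato (cv. 'Savior') grown in the
Vietnamese winter and summer seasons.

Open-field tomato is typically harvested in one pass, so a single batch
mixes overripe fruit (waste) with fruit too green to sell. `popharvest`
quantifies the economic cost of that practice and the benefit of
alternatives: it models each fruit's growth and colour kinetics, captures
fruit-to-fruit variation as variation in final size and *biological age*,
propagates that variation through Monte Carlo simulation of a virtual crop,
and values every candidate harvest schedule with a wholesale price model.

## The model

**Per-fruit kinetics.** Fruit mass follows Gompertz growth and hue angle
(CIELAB, ~105° green to ~52° red) decays exponentially once ripening is
triggered:

```
dM/dt = km · M · ln(Mmax / M),            M(0) = Mmax · exp(−C)
dH/dt = −(H − Hmin) · kh(M)
kh(M) = kh_max / (1 + (Mmax − M)/Mmax)^s
```

The mass-dependent switch `kh(M)` keeps colour constant during growth and
releases hue decay at rate `kh_max` as `M → Mmax` — an empirical stand-in
for the climacteric onset of ripening. Six parameters (`C`, `km`,
`kh_max`, `H0`, `Hmin`, `s`) are shared by all fruit of a season; each
fruit adds its own maximum mass `Mmax` and a biological shift `Δt` that
converts the shared experimental clock into its developmental clock,
`t_age = t_exp + Δt`.

**Calibration.** `calibrate()` jointly estimates the shared parameters and
every fruit's `(Mmax, Δt)` from on-plant time series of mass and hue by
minimizing a combined residual sum of squares in which both channels are
standardized to equal weight. The model is invariant under
`C → C·exp(km·δ)`, `Δt → Δt − δ`, so `C` is frozen (gauge constraint) and
`Δt` absorbs all per-fruit timing.

**Population and economics.** `sample_population()` draws virtual crops
preserving the average, variation, shape and correlation of the calibrated
`(Mmax, Δt)` set; `simulate_population()` evaluates all trajectories;
`classify_stage()` bins hue into ripening stages RS1 (mature green) …
RS6 (red ripe), with fruit below 54° counted as overripe waste. A
no-intercept mixture regression (`fit_price_model()` /
`predict_price()`),

```
price/kg = α1·RS1 + … + α6·RS6 + α7·RS1·RS6 + α8·RS2·RS6 + α9·RS1·RS5 ,
```

maps a batch's stage composition to its normalized wholesale price, and
`apply_harvest_strategy()` / `compare_strategies()` convert simulated
harvests — single-pass, fixed-interval or dynamic schedules targeting
chosen stages — into cumulative economic value (normalized price × kg),
saleable mass and waste.

Reference parameter sets for both 'Savior' seasons
(`savior_growth_params()`, `savior_population()`, `savior_price_survey()`,
`savior_price_coefficients()`) and synthetic-data generators emulating the
original field campaigns (`gen_fruit_observations()`,
`gen_price_survey()`) are included, so the entire workflow runs without
external data.

## Worked example

Calibrate a synthetic winter cohort, scale it up to a 10,000-fruit virtual
crop, and rank harvest strategies:

```r
library(popharvest)

g   <- savior_growth_params("winter")
d   <- gen_fruit_observations(cohort_spec(60, g, savior_population("winter")),
                              seed = 42)
fit <- calibrate(d$obs, calibration_config(fix = c(C = g$C)))
fit
#> Joint calibration fit
#>   fruit: 60 (excluded: 0)   outer iterations: 50 (not converged)
#>   combined normalized RSS: 7.67301   R^2: 0.9969
#>   C             4.87  (se fixed/approx NA)
#>   km         0.07064  (se 8.03e-05)
#>   kh_max       21.88  (se 1.2)
#>   H0           105.8  (se 0.034)
#>   Hmin         51.94  (se 0.253)
#>   s            53.41  (se 0.484)
#>   per-fruit Mmax: mean 107 g   delta_t: mean 7.274 d
```

The generating values (`km` 0.0702/d, `H0` 105.74°, `Hmin` 52.55°, mean
`Mmax` 107.1 g, mean `Δt` 7.01 d) are recovered to within a few
per cent from 60 fruit; `R²` is the explained fraction of the combined
normalized response. ("not converged" reports that the 50-iteration cap,
not the 1e-8 relative improvement threshold, stopped the alternation —
the remaining drift is in the weakly identified switch parameters.)

```r
pop <- sample_population(fit_population_distribution(fit$per_fruit),
                         10000, seed = 42)
sim <- simulate_population(fit$shared, pop, seq(20, 100, by = 1))
cf  <- savior_price_coefficients("winter")

sw <- single_harvest_sweep(sim, c(25, 95), coeffs = cf)
attr(sw, "best_date")
#> [1] 51

first_rs6 <- sim$t_exp_d[which(apply(sim$hue_deg < 58, 2, any))[1]]
win <- c(first_rs6, first_rs6 + 30)
strategies <- c(
  list(harvest_strategy("single", schedule = attr(sw, "best_date"))),
  lapply(1:4, function(iv) harvest_strategy("fixed_interval",
    c("RS5", "RS6"), interval = iv, window = win)))
compare_strategies(sim, strategies, coeffs = cf)
#>               label           mode n_events total_value value_rel saleable_kg waste_kg
#> 1 RS5+RS6 every 3 d fixed_interval        8       863.2    1.0000       969.0    24.88
#> 2 RS5+RS6 every 2 d fixed_interval       11       859.1    0.9953       991.3     0.00
#> 3 RS5+RS6 every 1 d fixed_interval       21       830.6    0.9622       988.8     0.00
#> 4 RS5+RS6 every 4 d fixed_interval        6       652.0    0.7553       732.1   264.05
#> 5     single @ 51 d         single        1       463.8    0.5373       822.0   162.29
```

For the slow-ripening winter crop, value rises as the interval between
RS5–RS6 harvests grows from 1 d to 3 d (fruit get time to reach the
dearest stage), collapses at 4 d (fruit overshoot into waste), and a
well-timed single harvest captures only ~54% of the best multi-harvest
value. `total_value` is normalized price × kg accumulated over harvests.

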