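# paretile

Percentile-based parameter estimation for the two-parameter Pareto
distribution, with goodness-of-fit indices and a Monte Carlo benchmarking
engine.

## The problem

Heavy-tailed positive data — earthquake casualty counts, insurance claim
sizes, fire losses, incomes — are routinely modelled by the Pareto
distribution with scale β (the support minimum) and shape α (the tail
index):

    f(x) = α β^α / x^(α+1),    F(x) = 1 − (β/x)^α,    x ≥ β,  α, β > 0.

Classical fits (maximum likelihood, method of moments) can be fragile on
such data: the moment estimator needs a finite variance (α > 2), and every
method is sensitive to how the far tail behaves. Percentile estimation
sidesteps some of this by equating theoretical CDF values with sample
percentiles and solving for (β, α). **paretile** implements the traditional
percentile estimator and three modifications of it, alongside ML and moment
baselines, for analysts who need to fit and compare Pareto tails:

| method | lower equation replaced by | closed form for α̂ |
|---|---|---|
| `PE` | sample quartile P25 | log 3 / (log P75 − log P25) |
| `PE-I` | population median β·2^(1/α) | log 0.5 / (log X̃ − log P75) |
| `PE-II` | population geometric mean β·e^(1/α) | (log 0.25 + 1) / (log GM − log P75) |
| `PE-III` | E[F(x₍₁₎)] = 1/(n+1) for the sample minimum | (log 0.25 − log n + log(n+1)) / (log x₍₁₎ − log P75) |
| `ML` | — | n / (Σ log xᵢ − n log x₍₁₎), β̂ = x₍₁₎ |
| `MM` | — | 1 + √(1 + X̄²/S²), β̂ = X̄(α̂−1)/α̂ |

The package's Monte Carlo engine compares the methods by total mean square
error, TMSE = MSE(β̂) + MSE(α̂), and total relative deviation,
TRD = |E(α̂)−α|/α + |E(β̂)−β|/β, across a grid of true parameters and sample
sizes; on that benchmark the minimum-based modification `PE-III` is the
uniformly best percentile method and `PE` the runner-up. For real data,
where the truth is unknown, four empirical-CDF distances (MAE, MAPE, RMSE,
RMSPE) rank the fitted models instead.

## Worked example

Fifteen synthetic casualty counts (heavy-tailed, units: deaths):

```r
library(paretile)
x <- c(1210, 150, 330, 1500, 4000, 960, 210, 540, 2630, 6200,
       480, 175, 880, 1920, 310)
fit <- fit_pareto(data.frame(deaths = x), deaths)
glance(fit)
#> # A tibble: 6 × 8
#>   method beta_hat alpha_hat    mae  mape   rmse rmspe     n
#>   <chr>     <dbl>     <dbl>  <dbl> <dbl>  <dbl> <dbl> <int>
#> 1 PE         206.     0.656 0.0618  25.8 0.0790  44.7    15
#> 2 PE-I       453.     1.04  0.128   45.8 0.176   64.1    15
#> 3 PE-II      106.     0.499 0.0858  30.6 0.0940  46.0    15
#> 4 PE-III     133.     0.543 0.0577  12.1 0.0700  15.4    15
#> 5 ML         150      0.603 0.0623  20.0 0.0702  30.9    15
#> 6 MM         812.     2.31  0.185   56.6 0.238   71.7    15
```

Each row is one fitted model: `beta_hat` is the estimated support minimum
(same units as the data), `alpha_hat` the tail index (smaller = heavier
tail), and the last four columns measure the distance between the fitted
CDF and the empirical CDF at the observed points (MAPE/RMSPE in percent).
Here `PE-III` tracks the empirical distribution most closely on every
index; `MM` illustrates its structural α̂ > 2 bias on a tail this heavy.
`autoplot(fit)` overlays the fitted CDFs on the empirical one.

Benchmarking estimators under a known truth:

```r
simulate_pareto_cell(beta = 1, alpha = 0.5, n = 100, reps = 2000, seed = 42)
#>   beta_true alpha_true   n method mean_beta_hat mean_alpha_hat      tmse      trd
#> 1         1        0.5 100     PE       1.03095        0.51520 0.0296511 0.061357
#> 2         1        0.5 100   PE-I       1.07898        0.52537 0.1447376 0.129717
#> 3         1        0.5 100  PE-II       1.16049        0.55392 0.4766505 0.268330
#> 4         1        0.5 100 PE-III       0.99989        0.50836 0.0046286 0.016832
```

2000 samples of size 100 were drawn from Pareto(1, 0.5) by inverse
transform; every method was fitted to every sample. `PE-III` is nearly
unbiased on both parameters and has a TMSE six times smaller than `PE`'s.
`simulate_pareto_grid()` runs the full grid of parameter pairs and sample
sizes; `autoplot()` on the result shows TMSE against n per method.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/paretile fit claims.csv --gof
Rscript inst/scripts/paretile gof claims.csv --beta 500 --alpha 1.2
Rscript inst/scripts/paretile simulate --seed 1 --out grid.csv
```

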