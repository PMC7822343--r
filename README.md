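# logbilal

Tools for modelling variables confined to the open unit interval —
proportions, rates, index scores — with the one-parameter **log-Bilal
distribution** and its mean-parametrized regression model. The package is
aimed at analysts who find beta regression inadequate for extremely skewed
bounded data (well-being indicators, disease proportions, poverty rates)
and want a simpler competitor with fully closed-form machinery.

## The model

The log-Bilal law is the distribution of `exp(-X)` for a Bilal lifetime
variable `X`. On `0 < y < 1`, with shape `θ > 0`:

```
f(y; θ) = (6/θ) y^(2/θ - 1) (1 - y^(1/θ))
F(y; θ) = 3 y^(2/θ) - 2 y^(3/θ)
E(Y^k)  = 6 / ((kθ + 2)(kθ + 3))
```

At `θ = 1` the density is exactly Beta(2,2). Because the mean
`μ = 6/((θ+2)(θ+3))` inverts in closed form,
`θ(μ) = (√(1 + 24/μ) − 5)/2`, covariates can act directly on the mean
through a logit link:

```
logit(μ_i) = x_iᵀ β,     y_i ~ log-Bilal(θ(μ_i))
```

The package provides:

* `dlogbilal` / `plogbilal` / `qlogbilal` / `rlogbilal` / `hlogbilal`,
  moments (`lb_moment`, `lb_var`, `lb_incomplete_moment`), the mean
  reparametrization (`mu_to_theta`, `theta_to_mu`) and the
  exponential-family decomposition (`lb_expfam`);
* `fit_unitdist()` — four estimators of `θ` (MLE, method of moments,
  least squares, weighted least squares) plus MLE fitting of the
  competing beta, Kumaraswamy, Topp-Leone and unit-Lindley families;
* `lbreg()` — the regression model, with Wald inference, AIC/BIC and
  quantile residuals (`summary`, `predict`, `residuals`, `simulate`,
  `plot` methods);
* `gof_report()` / `gof()` / `compare_unitdists()` — Kolmogorov–Smirnov,
  Cramér–von Mises and Anderson–Darling statistics with information
  criteria, for ranking fitted families;
* `estimator_study()` — a seeded Monte-Carlo engine comparing estimator
  bias, MSE and mean relative error across sample sizes;
* `read_unit_data()` / `generate_fixture()` and a command-line front-end
  (`inst/cli/logbilal-cli.R`) with `fit`, `regress`, `simulate` and
  `fixture` subcommands.

## Worked example

```r
library(logbilal)

dwbf <- system.file("extdata", "synthetic-dwbf.csv", package = "logbilal")
y <- read_unit_data(dwbf, "dwbf", percent = TRUE)  # 38 values in (0,1)

fit <- fit_unitdist(y)          # log-Bilal MLE
summary(fit)
#> log-Bilal fit by MLE (n = 38)
#>
#>       Estimate Std. Error
#> theta      5.2      0.609
#>
#> log-likelihood: 74.96  AIC: -147.9  BIC: -146.3

compare_unitdists(y)
#>       family   par1     se1 par2    se2    aic     bic      ad     cvm      ks
#>     logbilal 5.2000 0.60850   NA     NA -147.9 -146.30  0.3031 0.03815 0.07445
#>         beta 0.3083 0.05610 2.74 0.8270 -147.1 -143.90  0.2245 0.02730 0.06643
#>  kumaraswamy 0.3506 0.06424 2.04 0.5067 -146.3 -143.00  0.2569 0.03116 0.07126
#>    toppleone 0.2696 0.04373   NA     NA -147.3 -145.70  0.3976 0.05696 0.08322
#>  unitlindley 7.0950 1.03700   NA     NA  -80.5  -78.86 16.2900 1.63400 0.36620
#>  ...
#> lowest AIC: logbilal
```

The fitted shape `θ̂ = 5.2 (SE 0.61)` says the synthetic dwellings
variable is concentrated near zero (implied mean
`theta_to_mu(5.2) ≈ 0.10`), and the comparison table ranks the log-Bilal
fit first on AIC/BIC — unsurprising here, since the synthetic sample was
drawn from the model itself.

Regression on the synthetic education table:

```r
reg <- system.file("extdata", "synthetic-bli-regression.csv",
                   package = "logbilal")
dat <- read_unit_data(reg, "educ", covariates = c("hr", "dwbf", "lmi"),
                      percent = TRUE)
m <- lbreg(educ ~ hr + dwbf + lmi, data = dat)
summary(m)
#> Coefficients:
#>               Estimate Std. Error z value Pr(>|z|)
#> (Intercept)   2.262568   0.382734   5.912 3.39e-09 ***
#> hr           -0.081954   0.018006  -4.551 5.33e-06 ***
#> dwbf          0.079667   0.009649   8.256  < 2e-16 ***
#> lmi         -15.275745   2.664518  -5.733 9.87e-09 ***
#>
#> log-likelihood: 28.36 on 38 observations
#> AIC: -48.71  BIC: -42.16
plot(m)   # normal Q-Q plot of the quantile residuals
```

All four coefficients land within sampling error of the generating
values `(2.1136, −0.0705, 0.0724, −14.8182)`; negative signs mean the
covariate depresses the expected proportion.

From a shell, the same analyses run as:

```sh
Rscript inst/cli/logbilal-cli.R fit inst/extdata/synthetic-dwbf.csv \
    --response dwbf --percent-rescale
Rscript inst/cli/logbilal-cli.R simulate --theta 1.7 --reps 1000 \
    --nmin 20 --nmax 300 --nstep 40 --seed 1 --out study.csv
```

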