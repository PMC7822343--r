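---
title: "Modelling bounded responses with the log-Bilal distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bounded responses with the log-Bilal distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logbilal)
```

## The model

Proportions, rates and index scores live on the open unit interval, and
the standard toolbox for them (beta regression above all) struggles when
the data are extremely skewed towards one endpoint.  The log-Bilal
distribution is a one-parameter law on $(0,1)$ obtained as the
distribution of $e^{-X}$ for a Bilal lifetime variable $X$.  Its density
and distribution function are closed-form and free of special functions:

$$f(y;\theta) = \frac{6}{\theta}\, y^{2/\theta-1}\bigl(1-y^{1/\theta}\bigr),
\qquad
F(y;\theta) = 3y^{2/\theta} - 2y^{3/\theta}, \qquad \theta > 0 .$$

At $\theta=1$ the density is exactly Beta(2,2); as $\theta$ grows mass
piles up near 0, as $\theta \to 0$ near 1.  All raw moments are rational
in $\theta$,

$$E(Y^k) = \frac{6}{(k\theta+2)(k\theta+3)},$$

which is what makes a clean mean parametrization — and hence a regression
model — possible.  One point deserves correction relative to folklore
about this family: the mean is globally strictly decreasing in $\theta$,
but the **variance is not monotone**.  It rises to a single interior peak
at $\theta \approx 1.530$ (variance $\approx 0.0549$) and decreases only
beyond it; the package's tests assert exactly this unimodal behaviour.

### Quantiles without complex arithmetic

Writing $t = y^{1/\theta}$, the cdf is the cubic $g(t)=3t^2-2t^3$.  Rather
than Cardano radicals (whose cube roots are complex-valued for
probabilities in $(0,1)$), the quantile function uses the trigonometric
real root

$$t(u) = \tfrac12 - \sin\!\bigl(\tfrac13\arcsin(1-2u)\bigr),
\qquad Q(u;\theta) = t(u)^\theta,$$

an identity that follows from the sine triple-angle formula.  It is exact
to machine precision, monotone, and stable at both tails; the test suite
verifies $F(Q(u)) = u$ to $10^{-10}$ down to $u = 10^{-6}$ against an
independent bisection oracle.  All powers are evaluated as
$\exp(\cdot \log y)$ so that small $y$ combined with small $\theta$ cannot
overflow.  Random generation is plain inverse-transform sampling of
uniforms; reproducibility follows R's RNG via `set.seed()`.

### Boundary policy

The support is open: densities and quantiles reject 0 and 1, and samples
containing exact endpoint values raise an error naming the offending rows.
Nothing is ever silently clamped — a 0 in percentage data is a data
problem the user must resolve, not something a likelihood should paper
over.  The cdf alone accepts the closed endpoints.  The two places where
clipping *is* applied (probability-integral transforms that underflow to
0/1 inside the Anderson–Darling statistic or quantile residuals) warn
loudly and clip to $[10^{-10}, 1-10^{-10}]$.

## Estimating the shape

`fit_unitdist()` offers four estimators of $\theta$:

* **MLE** — direct maximization of
  $\ell(\theta) = n\log(6/\theta) + (2/\theta-1)\sum\log y_i +
  \sum\log(1-y_i^{1/\theta})$, by BFGS over $\log\theta$ from the
  method-of-moments start, then a root-polish of the analytic score so
  $|\ell'(\hat\theta)| < 10^{-6}$.  The likelihood depends on the data
  through $\sum_i \log y_i$ (the exponential-family sufficient statistic)
  — not through the arithmetic mean of the $y_i$, a distinction that
  matters when transcribing the formula.  The standard error is the
  inverse square root of the observed information, taken as a central
  second difference of $\ell$ at the optimum (relative step $10^{-5}$).
* **MM** — closed form
  $\hat\theta = \frac12\{(\bar y/(\bar y+24))^{-1/2}-5\}$ from
  mean-matching; here $\bar y$ genuinely is the mean of the $y_i$.
* **LSE / WLSE** — minimize
  $\sum_i w_i\,[F(y_{(i)};\theta) - i/(n+1)]^2$ with $w_i = 1$ or the
  inverse-variance weights $(n+1)^2(n+2)/\{i(n-i+1)\}$, by golden-section
  search over $\log\theta \in [\log 10^{-4}, \log 10^4]$.  Ties are
  resolved by a stable sort, so plotting positions follow sorted order.

`estimator_study()` compares them by Monte Carlo: at true
$\theta = 1.7$ it draws samples over a size grid (default
$n = 20, 25, \dots, 300$), applies every estimator to the *same* samples
(pairing removes between-sample noise from the method contrast), and
reports bias, MSE and mean relative error per method and $n$.  Each
(size, replicate) cell gets its own substream seed derived from the
master seed, so any subset of the study reproduces exactly.  The default
replication count is 1000 — enough for the qualitative ranking to be
stable across seeds while keeping a desk run in seconds — with the
full-scale 10\,000 available by argument.  The study's robust conclusion,
reproduced by the acceptance checks at $N = 1000$ with
$n \in \{20, 300\}$: all four estimators are consistent, and the MLE
attains the smallest MSE at $n = 300$.

## The regression model

To regress a bounded response on covariates, invert the mean map
$\mu = 6/((\theta+2)(\theta+3))$:

$$\theta(\mu) = \tfrac12\bigl(\sqrt{1 + 24/\mu} - 5\bigr),
\qquad
\mu_i = \frac{\exp(x_i^\top\beta)}{1+\exp(x_i^\top\beta)} .$$

`lbreg()` maximizes $\sum_i \log f(y_i;\theta(\mu_i))$ by BFGS with
finite-difference gradients (relative tolerance $10^{-12}$), starting
from $\beta_0 = \mathrm{logit}(\bar y)$ and zeros — the flat model — so
the optimizer begins at a defensible fit.  Two independent evaluation
routes of this likelihood (the sum of log densities, and the
mean-parametrized expression written out directly) agree to $10^{-12}$
in the tests.  Standard errors come from the inverse numerical Hessian
of the negative log-likelihood at the optimum; Wald $z$ statistics are
referred to the standard normal, the convention under which published
p-values for competing bounded-response regressions are computed.  Rank
deficiency, optimizer failure and a non-positive-definite Hessian raise
three distinct errors, because they require three different remedies.

Model criticism uses quantile residuals
$r_i = \Phi^{-1}\{F(y_i;\hat\theta_i)\}$, standard normal under a
correct specification.  The response is continuous, so the
randomization device needed for discrete data is unnecessary and the
residuals are deterministic.  `plot()` draws their normal Q-Q plot.  The
calibration experiment (200 correctly specified replicates at
$n = 500$) requires a 1%-level Kolmogorov–Smirnov normality test of the
residuals to pass in at least 95% of replicates; in practice it passes
in essentially all of them.

An intercept-only `lbreg()` fit is the univariate MLE in disguise:
$\theta(\mathrm{logistic}(\hat\beta_0))$ equals `fit_unitdist()`'s
$\hat\theta$, a reparametrization identity the tests check to $10^{-5}$.

## Ranking candidate families

`compare_unitdists()` fits the log-Bilal law alongside beta,
Kumaraswamy, Topp-Leone and unit-Lindley (Appendix-style densities, MLE
throughout: log-parameter BFGS with moment starts for the two-parameter
families, bounded scalar search for the one-parameter ones) and reports
the battery from `gof_report()`: the K-S statistic with its asymptotic
Kolmogorov p-value, the classical Cramér–von Mises $W^2$ and
Anderson–Darling $A^2$ computed from the fitted probability-integral
transforms, and AIC/BIC.  The classical (not small-sample-adjusted)
$A^2$/$W^2$ forms are used, at the fitted parameters, without
parameter-uncertainty correction — the convention of the
fitted-distribution comparison literature; published tables computed
with the adjusted variants can differ from these by a few percent.
Competing *regression* models (beta regression, unit-Lindley
regression) are deliberately out of scope: they are established
elsewhere and only their published coefficients are of interest for
context.

## Synthetic data, and what passing tests do not show

`generate_fixture()` writes the two input shapes the package consumes —
a univariate sample at known $\theta$, and a regression table with known
$\beta$ through the logit link, uniform covariates, and a JSON sidecar
recording the truth.  The shipped example files
(`inst/extdata/synthetic-dwbf.csv`,
`inst/extdata/synthetic-bli-regression.csv`; both labelled synthetic)
emulate a 38-country well-being-index extract: the dwellings variable is
drawn from the log-Bilal law at $\theta = 4.7063$ and the education
table uses generating coefficients $(2.1136, -0.0705, 0.0724, -14.8182)$
with covariate ranges matching published homicide-rate,
dwellings-percentage and labour-market-insecurity scales.  These are
stand-ins: they exercise the full pipeline shape, but they are *drawn
from the model itself*, so goodness-of-fit successes on them demonstrate
internal consistency, not real-data adequacy.  Real extracts carry ties,
rounding to one decimal, and model misspecification that the generator
deliberately does not emulate.

The genuine 2017 OECD Better Life Index extracts are not
redistributable here; to run the real-data reproductions place

* `oecd-bli-2017-dwbf.csv` (column `dwbf`, percentages) and
* `oecd-bli-2017-education.csv` (columns `educ`, `hr`, `dwbf`, `lmi`,
  response in percent)

under `inst/extdata/` before installing, as described in the README.
Without them the two real-data acceptance tests fail — by design, since
silently skipping a reproduction would overstate what was verified.

## Numerical choices, in one place

* Optimizers: BFGS over unconstrained transforms (log for positive
  parameters), relative tolerance $10^{-12}$, `maxit` 500; bounded
  golden-section for scalar fits, tolerance $10^{-10}$.
* Observed information: central differences, relative step $10^{-5}$.
* Score polish of the univariate MLE: `uniroot` within $\pm1\%$ of the
  BFGS optimum.
* Degenerate inputs: endpoint data rejected with row numbers; rank
  deficiency checked via QR before optimization; baseline likelihood
  evaluations that stray outside the parameter space return a large
  finite penalty instead of `NaN` so BFGS line searches cannot die.
* Problem sizes in the checks: the identity suite runs on a 9-point
  log-spaced $\theta$ grid over $[0.05, 50]$; recovery uses $n = 5000$;
  the Monte-Carlo comparison uses $N = 1000$ replicates at
  $n \in \{20, 300\}$; residual calibration uses 200 replicates at
  $n = 500$.  These sizes were chosen so every conclusion they support
  is stable across seeds.

## Limitations

* The shape of the hazard rate is classified numerically
  (`hazard_shape()`, sign changes of a finite-difference derivative on a
  grid); no closed-form boundary between the increasing and bathtub
  regimes is claimed.
* The K-S p-value is asymptotic; an exact small-$n$ method would be a
  natural extension.
* Only the distribution side of the competing families is implemented;
  their regression counterparts are not.
* The unit-Lindley comparison row in published tables for the dwellings
  variable appears internally inconsistent with data concentrated near
  zero (its reported estimate and information criterion imply a sample
  with mass near one); the package reports what the likelihood actually
  gives.
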