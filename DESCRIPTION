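Package: logbilal
Title: The Log-Bilal Distribution and Regression Model for Bounded Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density, distribution function, quantile function, random
    generation, moments and hazard function for the one-parameter log-Bilal
    distribution on the open unit interval, together with four point
    estimators of its shape parameter (maximum likelihood, method of
    moments, least squares and weighted least squares), a mean-parametrized
    regression model for bounded responses with a logit link and randomized
    quantile residuals, a goodness-of-fit battery (Kolmogorov-Smirnov,
    Cramer-von Mises, Anderson-Darling, AIC, BIC) with competing
    unit-interval families (beta, Kumaraswamy, Topp-Leone, unit-Lindley),
    and a Monte-Carlo engine comparing the bias, mean squared error and
    mean relative error of the estimators across sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite, optparse
Suggests: testthat (>= 3.0.0), fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
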