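#' Goodness-of-fit battery for a fitted unit-interval distribution
#'
#' Computes the Kolmogorov-Smirnov statistic with its asymptotic p-value,
#' the Cramér-von Mises statistic \eqn{W^2}, the Anderson-Darling statistic
#' \eqn{A^2}, and the AIC/BIC, for a sample judged against a fitted cdf.
#'
#' With \eqn{u_{(1)} \le \dots \le u_{(n)}} the sorted probability-integral
#' transforms \eqn{u_i = F(y_i;\hat\theta)}:
#' \deqn{D = \max_i \max\{i/n - u_{(i)},\; u_{(i)} - (i-1)/n\},}
#' \deqn{W^2 = \sum_i \left(u_{(i)} - \frac{2i-1}{2n}\right)^2 +
#'   \frac{1}{12n},}
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)\left[\log u_{(i)} +
#'   \log(1 - u_{(n+1-i)})\right].}
#' The K-S p-value uses the asymptotic Kolmogorov series
#' \eqn{2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2 n D^2}}.  The classical (not
#' small-sample-adjusted) \eqn{A^2} and \eqn{W^2} forms are used, computed
#' at the fitted parameters without parameter-uncertainty correction, as is
#' standard when ranking fitted families.  Transforms numerically equal to
#' 0 or 1 are clipped (with a warning) since \eqn{A^2} would be infinite.
#'
#' \code{gof} is the convenience wrapper for \code{\link{fit_unitdist}}
#' objects.
#'
#' @param y the sample, strictly inside (0, 1).
#' @param cdf a vectorized cdf callable mapping (0,1) to [0,1].
#' @param n_params number of estimated parameters (for AIC/BIC).
#' @param loglik maximized log-likelihood (for AIC/BIC).
#' @param clip_eps clipping bound for degenerate transforms.
#' @param fit a \code{"unitdist_fit"} object.
#' @param ... unused.
#' @return an object of class \code{"gof_report"}: a list with
#'   \code{ks_stat}, \code{ks_pvalue}, \code{cvm_stat}, \code{ad_stat},
#'   \code{aic}, \code{bic}, \code{n_params} and \code{n_obs}.
#' @examples
#' set.seed(2)
#' y <- rlogbilal(60, 1.7)
#' f <- fit_unitdist(y)
#' gof(f)
#' @export
gof_report <- function(y, cdf, n_params, loglik, clip_eps = 1e-10) {
  y <- as_unit_sample(y)
  n <- length(y)
  check_count(n_params, "n_params", min = 0L)
  u <- sort(cdf(y))
  if (any(diff(u) < -1e-12))
    stop("'cdf' is not monotone on the sample", call. = FALSE)
  if (any(u <= 0 | u >= 1)) {
    warning("probability-integral transforms at 0 or 1 clipped to [",
            format(clip_eps), ", 1 - ", format(clip_eps), "]")
    u <- pmin(pmax(u, clip_eps), 1 - clip_eps)
  }
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  cvm <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  ad <- -n - sum((2 * i - 1) * (log(u) + log(1 - rev(u)))) / n
  out <- list(ks_stat = ks, ks_pvalue = kolmogorov_pvalue(sqrt(n) * ks),
              cvm_stat = cvm, ad_stat = ad,
              aic = -2 * loglik + 2 * n_params,
              bic = -2 * loglik + n_params * log(n),
              n_params = as.integer(n_params), n_obs = n)
  class(out) <- "gof_report"
  out
}

# asymptotic Kolmogorov tail probability P(sup |B| > lambda)
kolmogorov_pvalue <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @rdname gof_report
#' @export
gof <- function(fit, ...) UseMethod("gof")

#' @rdname gof_report
#' @export
gof.unitdist_fit <- function(fit, ...) {
  cdf <- fitted_cdf(fit)
  gof_report(fit$data, cdf, n_params = length(fit$coefficients),
             loglik = fit$loglik)
}

# the cdf of a fitted family, with the estimates baked in
fitted_cdf <- function(fit) {
  p <- fit$coefficients
  switch(fit$family,
         logbilal    = function(q) plogbilal(q, p[["theta"]]),
         beta        = function(q) stats::pbeta(q, p[["alpha"]], p[["beta"]]),
         kumaraswamy = function(q) pkumaraswamy(q, p[["alpha"]], p[["beta"]]),
         toppleone   = function(q) ptoppleone(q, p[["theta"]]),
         unitlindley = function(q) punitlindley(q, p[["theta"]]))
}

#' @export
print.gof_report <- function(x, digits = 4L, ...) {
  cat("Goodness of fit (n =", x$n_obs, ", parameters =", x$n_params, ")\n")
  cat(sprintf("  K-S: %s (p = %s)\n", format(x$ks_stat, digits = digits),
              format(x$ks_pvalue, digits = digits)))
  cat(sprintf("  Cramer-von Mises W^2: %s\n",
              format(x$cvm_stat, digits = digits)))
  cat(sprintf("  Anderson-Darling A^2: %s\n",
              format(x$ad_stat, digits = digits)))
  cat(sprintf("  AIC: %s  BIC: %s\n", format(x$aic, digits = digits + 2),
              format(x$bic, digits = digits + 2)))
  invisible(x)
}

#' Compare unit-interval families on one sample
#'
#' Fits each requested family by maximum likelihood and tabulates the
#' estimates with the full goodness-of-fit battery, the workflow used to
#' rank candidate distributions for a bounded variable.
#'
#' @param y sample strictly inside (0, 1).
#' @param families character vector of families (see
#'   \code{\link{fit_unitdist}}).
#' @param control a list from \code{\link{lb_control}}.
#' @return a data frame of class \code{"unitdist_comparison"} with one row
#'   per family (estimates, SEs, AIC, BIC, A^2, W^2, K-S and its p-value),
#'   carrying the fitted objects in attribute \code{"fits"}.
#' @examples
#' set.seed(3)
#' y <- rlogbilal(80, 4.5)
#' compare_unitdists(y, c("logbilal", "beta"))
#' @export
compare_unitdists <- function(y,
    families = c("logbilal", "beta", "kumaraswamy", "toppleone",
                 "unitlindley"),
    control = lb_control()) {
  y <- as_unit_sample(y)
  fits <- lapply(families, function(f) fit_unitdist(y, family = f,
                                                    control = control))
  names(fits) <- families
  rows <- lapply(fits, function(f) {
    g <- gof(f)
    cf <- coef(f); se <- f$se
    data.frame(family = f$family,
               par1 = cf[1], se1 = se[1],
               par2 = if (length(cf) > 1) cf[2] else NA_real_,
               se2 = if (length(cf) > 1) se[2] else NA_real_,
               aic = g$aic, bic = g$bic, ad = g$ad_stat, cvm = g$cvm_stat,
               ks = g$ks_stat, ks_pvalue = g$ks_pvalue)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fits") <- fits
  class(out) <- c("unitdist_comparison", "data.frame")
  out
}

#' @export
print.unitdist_comparison <- function(x, digits = 4L, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  best <- df$family[which.min(df$aic)]
  cat("\nlowest AIC:", best, "\n")
  invisible(x)
}
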