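#' Fit a unit-interval distribution to a sample
#'
#' Fits one of the supported distributions on (0, 1) to a univariate sample
#' by maximum likelihood, or — for the log-Bilal family — also by method of
#' moments, least squares or weighted least squares.
#'
#' The four log-Bilal estimators of the shape \eqn{\theta}:
#' \describe{
#'   \item{\code{"mle"}}{direct maximization of the log-likelihood
#'     (quasi-Newton over \eqn{\log\theta}, started at the
#'     method-of-moments value, then polished so the analytic score
#'     vanishes).  The standard error comes from the observed information
#'     (central second difference of \eqn{\ell} at \eqn{\hat\theta}).}
#'   \item{\code{"mm"}}{closed form from equating the theoretical mean to
#'     the sample mean \eqn{\bar y}:
#'     \eqn{\hat\theta = \frac12\{(\bar y/(\bar y + 24))^{-1/2} - 5\}}.
#'     By construction the fitted mean reproduces \eqn{\bar y} exactly.}
#'   \item{\code{"lse"}}{minimizes
#'     \eqn{\sum_i [F(y_{(i)};\theta) - i/(n+1)]^2} over the order
#'     statistics with plotting positions \eqn{i/(n+1)}.}
#'   \item{\code{"wlse"}}{the same objective with weights
#'     \eqn{(n+1)^2(n+2)/\{i(n-i+1)\}} (inverse variances of the uniform
#'     order statistics).}
#' }
#' Ties in the sample are handled by a stable sort, so plotting positions
#' follow the sorted index.  For the competing families (\code{"beta"},
#' \code{"kumaraswamy"}, \code{"toppleone"}, \code{"unitlindley"}) only
#' maximum likelihood is available: two-parameter families are maximized
#' over log-parameters from moment-based starts, one-parameter families by
#' bounded scalar optimization; standard errors come from the numerical
#' observed information matrix.
#'
#' @param y numeric sample with every value strictly inside (0, 1).
#' @param family one of \code{"logbilal"}, \code{"beta"},
#'   \code{"kumaraswamy"}, \code{"toppleone"}, \code{"unitlindley"}.
#' @param method estimation method; families other than log-Bilal support
#'   \code{"mle"} only.
#' @param control a list from \code{\link{lb_control}}.
#' @return an object of class \code{"unitdist_fit"}: a list with the named
#'   \code{coefficients}, their standard errors \code{se}, \code{vcov},
#'   \code{loglik} (the log-likelihood evaluated at the estimate, whatever
#'   the method), \code{n}, \code{converged}, the least-squares
#'   \code{objective} when applicable, and the data.  Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{logLik} (hence
#'   \code{AIC}/\code{BIC}), \code{vcov}, and \code{\link{gof}}.
#' @examples
#' set.seed(7)
#' y <- rlogbilal(200, theta = 1.7)
#' fit <- fit_unitdist(y)                    # log-Bilal MLE
#' coef(fit); AIC(fit)
#' fit_unitdist(y, method = "mm")
#' fit_unitdist(y, family = "kumaraswamy")
#' @export
fit_unitdist <- function(y,
                         family = c("logbilal", "beta", "kumaraswamy",
                                    "toppleone", "unitlindley"),
                         method = c("mle", "mm", "lse", "wlse"),
                         control = lb_control()) {
  cl <- match.call()
  family <- match.arg(family)
  method <- match.arg(method)
  y <- as_unit_sample(y)
  if (family != "logbilal" && method != "mle")
    stop("method '", method, "' is only available for family 'logbilal'",
         call. = FALSE)
  fit <- if (family == "logbilal") {
    switch(method,
           mle  = logbilal_fit_mle(y, control),
           mm   = logbilal_fit_mm(y),
           lse  = logbilal_fit_ls(y, weighted = FALSE, control),
           wlse = logbilal_fit_ls(y, weighted = TRUE, control))
  } else {
    baseline_fit_mle(y, family, control)
  }
  fit$family <- family
  fit$method <- method
  fit$n <- length(y)
  fit$data <- y
  fit$call <- cl
  class(fit) <- "unitdist_fit"
  fit
}

# ---- log-Bilal estimators -------------------------------------------------

logbilal_fit_mm <- function(y) {
  ybar <- mean(y)
  theta <- (sqrt(1 + 24 / ybar) - 5) / 2
  if (theta <= 0)                      # unreachable for ybar < 1; guard anyway
    stop("method-of-moments estimate is non-positive (sample mean ",
         format(ybar), ")", call. = FALSE)
  list(coefficients = c(theta = theta), se = c(theta = NA_real_),
       vcov = NULL, loglik = logbilal_loglik(theta, y), converged = TRUE)
}

logbilal_fit_mle <- function(y, control) {
  n <- length(y)
  ll <- function(th) logbilal_loglik(th, y)
  start <- log(logbilal_fit_mm(y)$coefficients[["theta"]])
  opt <- optim(start,
               fn = function(lth) -ll(exp(lth)),
               gr = function(lth) -logbilal_score(exp(lth), y) * exp(lth),
               method = "BFGS",
               control = list(reltol = control$reltol, maxit = control$maxit))
  theta <- exp(opt$par)
  # polish: drive the analytic score to zero in a tight bracket
  lo <- theta * 0.99; hi <- theta * 1.01
  slo <- logbilal_score(lo, y); shi <- logbilal_score(hi, y)
  if (is.finite(slo) && is.finite(shi) && slo * shi < 0) {
    theta <- uniroot(function(th) logbilal_score(th, y), c(lo, hi),
                     tol = .Machine$double.eps^0.75)$root
  }
  info <- observed_info_1d(ll, theta, control)
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  converged <- opt$convergence == 0L &&
    abs(logbilal_score(theta, y)) < 1e-6 * max(1, n * 1e-3)
  if (!converged)
    warning("log-Bilal MLE did not converge cleanly (optim code ",
            opt$convergence, ", |score| = ",
            format(abs(logbilal_score(theta, y))), ")", call. = FALSE)
  list(coefficients = c(theta = theta), se = c(theta = se),
       vcov = matrix(se^2, 1, 1, dimnames = list("theta", "theta")),
       loglik = ll(theta), converged = converged)
}

# (weighted) least-squares objective on the order statistics
lse_objective <- function(theta, y, weighted) {
  n <- length(y)
  ys <- sort(y, method = "radix")            # stable sort; ties keep order
  i <- seq_len(n)
  w <- if (weighted) (n + 1)^2 * (n + 2) / (i * (n - i + 1)) else rep(1, n)
  sum(w * (plogbilal(ys, theta) - i / (n + 1))^2)
}

logbilal_fit_ls <- function(y, weighted, control) {
  if (length(y) < 2L)
    stop("least-squares fitting needs at least two observations",
         call. = FALSE)
  br <- log(control$theta_bracket)
  opt <- optimize(function(lth) lse_objective(exp(lth), y, weighted),
                  interval = br, tol = 1e-10)
  theta <- exp(opt$minimum)
  converged <- opt$minimum > br[1] + 1e-6 && opt$minimum < br[2] - 1e-6
  if (!converged)
    warning("least-squares estimate lies on the search boundary",
            call. = FALSE)
  list(coefficients = c(theta = theta), se = c(theta = NA_real_),
       vcov = NULL, loglik = logbilal_loglik(theta, y),
       objective = opt$objective, converged = converged)
}

# ---- methods --------------------------------------------------------------

#' @export
print.unitdist_fit <- function(x, digits = max(3L, getOption("digits") - 3L),
                               ...) {
  cat(family_label(x$family), "fit,", toupper(x$method),
      sprintf("(n = %d)\n", x$n))
  print(round(x$coefficients, digits))
  cat("log-likelihood:", format(x$loglik, digits = digits),
      " AIC:", format(AIC(x), digits = digits), "\n")
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' @export
summary.unitdist_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  tab <- cbind(Estimate = est, `Std. Error` = se)
  structure(list(fit = object, coefficients = tab,
                 aic = AIC(object), bic = BIC(object)),
            class = "summary.unitdist_fit")
}

#' @export
print.summary.unitdist_fit <- function(x,
    digits = max(3L, getOption("digits") - 3L), ...) {
  f <- x$fit
  cat(family_label(f$family), "fit by", toupper(f$method),
      sprintf("(n = %d)\n\n", f$n))
  printCoefmat(x$coefficients, digits = digits, na.print = "-")
  cat("\nlog-likelihood:", format(f$loglik, digits = digits),
      " AIC:", format(x$aic, digits = digits),
      " BIC:", format(x$bic, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.unitdist_fit <- function(object, ...) object$coefficients

#' @export
vcov.unitdist_fit <- function(object, ...) {
  if (is.null(object$vcov))
    stop("no covariance estimate for method '", object$method, "'",
         call. = FALSE)
  object$vcov
}

#' @export
logLik.unitdist_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

family_label <- function(family) {
  c(logbilal = "log-Bilal", beta = "beta", kumaraswamy = "Kumaraswamy",
    toppleone = "Topp-Leone", unitlindley = "unit-Lindley")[[family]]
}
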