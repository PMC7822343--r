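#' Log-likelihood and score of a log-Bilal sample
#'
#' For a sample \eqn{y_1,\dots,y_n} from the log-Bilal law the
#' log-likelihood is
#' \deqn{\ell(\theta) = n \log(6/\theta)
#'   + (2/\theta - 1) \sum_i \log y_i
#'   + \sum_i \log\left(1 - y_i^{1/\theta}\right),}
#' i.e. the sum of log-densities, and the score is
#' \deqn{\ell'(\theta) = -\frac{n}{\theta}
#'   - \frac{2}{\theta^2} \sum_i \log y_i
#'   + \frac{1}{\theta^2} \sum_i
#'     \frac{y_i^{1/\theta} \log y_i}{1 - y_i^{1/\theta}}.}
#' The data enter \eqn{\ell} only through \eqn{\sum_i \log y_i} and the
#' third term, consistent with the exponential-family sufficient statistic
#' \eqn{T(y) = \log y} (the likelihood depends on the logs of the
#' observations, not on their arithmetic mean).
#'
#' @param theta shape parameter (scalar).
#' @param y sample of values strictly inside (0, 1).
#' @return the log-likelihood (\code{logbilal_loglik}) or its derivative in
#'   \code{theta} (\code{logbilal_score}).
#' @examples
#' logbilal_loglik(1, 0.5)   # log(1.5)
#' @export
logbilal_loglik <- function(theta, y) {
  y <- as_unit_sample(y)
  check_theta(theta)
  sum(dlogbilal(y, theta, log = TRUE))
}

#' @rdname logbilal_loglik
#' @export
logbilal_score <- function(theta, y) {
  y <- as_unit_sample(y)
  check_theta(theta)
  n <- length(y)
  ly <- log(y)
  t <- exp(ly / theta)
  -n / theta - 2 * sum(ly) / theta^2 + sum(t * ly / (1 - t)) / theta^2
}

#' Fitting control parameters
#'
#' Numerical knobs shared by the fitting routines.
#'
#' @param reltol relative convergence tolerance passed to the optimizer.
#' @param maxit maximum number of optimizer iterations.
#' @param theta_bracket search bracket for \eqn{\theta} in the
#'   one-dimensional fits (used on the log scale).
#' @param hessian_step relative step for finite-difference observed
#'   information.
#' @param clip_eps probability-integral transforms are clipped into
#'   \code{[clip_eps, 1 - clip_eps]} (with a warning) before quantile
#'   residuals or Anderson-Darling terms are formed.
#' @return a named list of control values.
#' @export
lb_control <- function(reltol = 1e-12, maxit = 500L,
                       theta_bracket = c(1e-4, 1e4),
                       hessian_step = 1e-5, clip_eps = 1e-10) {
  stopifnot(reltol > 0, maxit >= 1, length(theta_bracket) == 2L,
            all(theta_bracket > 0), theta_bracket[1] < theta_bracket[2],
            hessian_step > 0, clip_eps > 0, clip_eps < 0.5)
  list(reltol = reltol, maxit = as.integer(maxit),
       theta_bracket = theta_bracket,
       hessian_step = hessian_step, clip_eps = clip_eps)
}

# Observed information (negative second derivative) of a scalar
# log-likelihood by central second difference.
observed_info_1d <- function(ll, theta, control) {
  h <- control$hessian_step * max(theta, 1)
  -(ll(theta + h) - 2 * ll(theta) + ll(theta - h)) / h^2
}
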