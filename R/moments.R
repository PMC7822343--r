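#' Moments of the log-Bilal distribution
#'
#' Closed-form raw moments, mean, variance and incomplete moments.  The
#' \eqn{k}-th raw moment is
#' \deqn{E(Y^k) = \frac{6}{(k\theta + 2)(k\theta + 3)},}
#' so the mean is \eqn{\mu = 6/((\theta+2)(\theta+3))} and the variance has
#' the rational closed form
#' \deqn{\mathrm{Var}(Y) = \frac{3\theta^2(\theta^2 + 10\theta + 13)}
#'   {(\theta^2 + 5\theta + 6)^2 (2\theta^2 + 5\theta + 3)}.}
#' Both mean and variance decrease strictly as \eqn{\theta} grows.
#'
#' The \eqn{r}-th incomplete moment (the contribution of \eqn{(0, t]} to the
#' \eqn{r}-th moment) is
#' \deqn{m_r(t) = \frac{6\, t^{r + 2/\theta}}{r\theta + 2}
#'             - \frac{6\, t^{r + 3/\theta}}{r\theta + 3},}
#' with \eqn{m_r(1) = E(Y^r)}.  Incomplete moments are the building blocks of
#' inequality measures such as the Gini and Lorenz curves.
#'
#' @param k,r positive integer moment order.
#' @param t upper truncation point in \eqn{(0, 1]}.
#' @param theta shape parameter, \eqn{\theta > 0}; vectorized.
#' @return moment values (vectorized over \code{theta}).
#' @examples
#' lb_moment(1, 1)               # 0.5 — Beta(2,2) mean
#' lb_var(1)                     # 0.05
#' lb_incomplete_moment(1, 0.5, 1)
#' @name lb_moments
NULL

#' @rdname lb_moments
#' @export
lb_moment <- function(k, theta) {
  check_count(k, "k")
  check_theta(theta)
  6 / ((k * theta + 2) * (k * theta + 3))
}

#' @rdname lb_moments
#' @export
lb_mean <- function(theta) lb_moment(1L, theta)

#' @rdname lb_moments
#' @export
lb_var <- function(theta) {
  check_theta(theta)
  3 * theta^2 * (theta^2 + 10 * theta + 13) /
    ((theta^2 + 5 * theta + 6)^2 * (2 * theta^2 + 5 * theta + 3))
}

#' @rdname lb_moments
#' @export
lb_incomplete_moment <- function(r, t, theta) {
  check_count(r, "r")
  check_theta(theta)
  if (!is.numeric(t) || anyNA(t) || any(t <= 0 | t > 1))
    stop("'t' must lie in (0, 1]", call. = FALSE)
  6 * t^(r + 2 / theta) / (r * theta + 2) -
    6 * t^(r + 3 / theta) / (r * theta + 3)
}

#' Mean parametrization of the log-Bilal distribution
#'
#' The mean \eqn{\mu = 6/((\theta+2)(\theta+3))} is a strictly decreasing
#' bijection from \eqn{\theta \in (0,\infty)} onto \eqn{\mu \in (0,1)}.
#' Inverting the quadratic gives
#' \deqn{\theta(\mu) = \frac{1}{2}\left(\sqrt{1 + 24/\mu} - 5\right)
#'   = \frac{1}{2}\left(\{\mu/(\mu+24)\}^{-1/2} - 5\right),}
#' the reparametrization used by the regression model so that covariates act
#' directly on \eqn{E(Y \mid x)}.
#'
#' @param theta shape parameter, \eqn{\theta > 0}.
#' @param mu mean in the open interval (0, 1).
#' @return \code{theta_to_mu} returns the mean; \code{mu_to_theta} the shape.
#'   The two are exact inverses (roundtrip to machine precision).
#' @examples
#' mu_to_theta(0.5)      # 1: the symmetric Beta(2,2) case
#' theta_to_mu(mu_to_theta(0.25))
#' @export
theta_to_mu <- function(theta) {
  check_theta(theta)
  6 / ((theta + 2) * (theta + 3))
}

#' @rdname theta_to_mu
#' @export
mu_to_theta <- function(mu) {
  check_mu(mu)
  (sqrt(1 + 24 / mu) - 5) / 2
}

#' Exponential-family decomposition
#'
#' The log-Bilal density factorizes as
#' \eqn{f(y;\theta) = \exp\{Q(\theta) T(y) + D(\theta) + S_\theta(y)\}} with
#' natural component \eqn{Q(\theta) = 2/\theta - 1}, sufficient statistic
#' \eqn{T(y) = \log y}, \eqn{D(\theta) = \log(6/\theta)} and
#' \eqn{S_\theta(y) = \log(1 - y^{1/\theta})}, exhibiting the one-parameter
#' exponential-family structure (for a sample, \eqn{\sum_i \log y_i} is
#' sufficient for \eqn{\theta}).
#'
#' @param theta shape parameter.
#' @return a list with the scalar components \code{Q} and \code{D}, the
#'   functions \code{T} and \code{S} of the data, and \code{recompose(y)}
#'   evaluating \eqn{\exp\{QT(y) + D + S(y)\}} (equal to
#'   \code{dlogbilal(y, theta)} pointwise).
#' @examples
#' ef <- lb_expfam(1.7)
#' ef$recompose(0.3) - dlogbilal(0.3, 1.7)
#' @export
lb_expfam <- function(theta) {
  check_theta(theta)
  if (length(theta) != 1L)
    stop("'theta' must be a single value", call. = FALSE)
  Q <- 2 / theta - 1
  D <- log(6 / theta)
  Tfun <- function(y) log(check_unit_open(y, "y"))
  Sfun <- function(y) log(-expm1(log(check_unit_open(y, "y")) / theta))
  list(Q = Q, D = D, T = Tfun, S = Sfun,
       recompose = function(y) exp(Q * Tfun(y) + D + Sfun(y)))
}
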