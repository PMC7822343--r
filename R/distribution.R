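#' The log-Bilal distribution
#'
#' Density, distribution function, survival function, hazard rate, quantile
#' function and random generation for the log-Bilal distribution with shape
#' parameter \code{theta}.
#'
#' The log-Bilal law is the distribution of \eqn{e^{-X}} when \eqn{X} follows
#' the Bilal lifetime distribution.  Its density on \eqn{0 < y < 1} is
#' \deqn{f(y;\theta) = \frac{6}{\theta}\, y^{2/\theta - 1}
#'   \left(1 - y^{1/\theta}\right), \qquad \theta > 0,}
#' with distribution function
#' \deqn{F(y;\theta) = 3 y^{2/\theta} - 2 y^{3/\theta}.}
#' At \eqn{\theta = 1} the density reduces to the Beta(2, 2) density
#' \eqn{6y(1-y)}.  The parameter \eqn{\theta} acts as a shape parameter:
#' small values push mass towards 1, large values towards 0.
#'
#' Writing \eqn{t = y^{1/\theta}}, the cdf is the cubic \eqn{3t^2 - 2t^3},
#' whose inverse on (0, 1) has the stable real closed form
#' \eqn{t(u) = 1/2 - \sin(\arcsin(1 - 2u)/3)} (a trigonometric solution of
#' the cubic; no complex arithmetic is needed), so the quantile function is
#' \eqn{Q(u;\theta) = t(u)^\theta}.  Random generation is inverse-transform
#' sampling of uniforms through \eqn{Q}; reproducibility follows R's RNG
#' state (\code{set.seed}).
#'
#' \code{dlogbilal} and \code{qlogbilal} reject values on the boundary of the
#' unit interval (the support is open); \code{plogbilal} accepts the closed
#' endpoints.  Out-of-range values raise errors rather than returning
#' \code{NaN}: silent clamping is never performed.
#'
#' @param x,q vector of quantiles.  \code{x} must lie strictly inside (0, 1);
#'   \code{q} may include the endpoints 0 and 1.
#' @param p vector of probabilities, strictly inside (0, 1).
#' @param n number of draws.
#' @param theta shape parameter, \eqn{\theta > 0}.  Recycled against the data
#'   argument.
#' @param log,log.p logical; if \code{TRUE}, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if \code{TRUE} (default) probabilities are
#'   \eqn{P(Y \le y)}, otherwise the survival function \eqn{P(Y > y)}.
#' @return \code{dlogbilal} the density, \code{plogbilal} the cdf (or
#'   survival function), \code{qlogbilal} the quantile function,
#'   \code{hlogbilal} the hazard rate \eqn{f/(1-F)}, and \code{rlogbilal} a
#'   vector of \code{n} draws.
#' @examples
#' dlogbilal(0.5, theta = 1)        # Beta(2,2) density at 1/2: 1.5
#' plogbilal(0.5, theta = 1)        # 0.5 (theta = 1 is symmetric)
#' qlogbilal(0.5, theta = 1.7)      # median
#' set.seed(1); mean(rlogbilal(1000, theta = 1.7))
#' @name logbilal
NULL

#' @rdname logbilal
#' @export
dlogbilal <- function(x, theta, log = FALSE) {
  check_unit_open(x, "x")
  check_theta(theta)
  # log f = log(6/theta) + (2/theta - 1) log y + log(1 - y^(1/theta));
  # powers go through exp(log(y)/theta) so small y / small theta cannot
  # overflow, and log(1 - t) uses expm1 for accuracy when t is near 0 or 1.
  lx <- log(x)
  logf <- log(6 / theta) + (2 / theta - 1) * lx + log(-expm1(lx / theta))
  if (log) logf else exp(logf)
}

#' @rdname logbilal
#' @export
plogbilal <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  check_unit_closed(q, "q")
  check_theta(theta)
  t <- exp(log(q) / theta)        # q = 0 -> t = 0, q = 1 -> t = 1
  p <- t * t * (3 - 2 * t)
  p <- pmin(pmax(p, 0), 1)
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname logbilal
#' @export
qlogbilal <- function(p, theta, lower.tail = TRUE, log.p = FALSE) {
  if (log.p) p <- exp(p)
  if (!is.numeric(p) || length(p) < 1L || anyNA(p))
    stop("'p' must be numeric and non-missing", call. = FALSE)
  if (any(p <= 0 | p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  check_theta(theta)
  if (!lower.tail) p <- 1 - p
  # real root in (0,1) of 3 t^2 - 2 t^3 = p via the sine triple-angle
  # identity; exact inverse of the cdf cubic, monotone in p
  t <- 0.5 - sin(asin(1 - 2 * p) / 3)
  exp(theta * log(t))
}

#' @rdname logbilal
#' @export
rlogbilal <- function(n, theta) {
  check_count(n, "n")
  check_theta(theta)
  qlogbilal(runif(n), theta)
}

#' @rdname logbilal
#' @export
hlogbilal <- function(x, theta) {
  check_unit_open(x, "x")
  check_theta(theta)
  s <- plogbilal(x, theta, lower.tail = FALSE)
  if (any(s <= 0))
    stop("hazard undefined where the survival function is zero", call. = FALSE)
  dlogbilal(x, theta) / s
}

#' Numerical hazard-shape diagnostic
#'
#' Classifies the shape of the log-Bilal hazard rate on a grid by counting
#' sign changes of a central finite-difference derivative.  This is a
#' numerical diagnostic (the hazard admits increasing and bathtub shapes
#' depending on \eqn{\theta}); no closed-form boundary between the regimes is
#' used.
#'
#' @param theta shape parameter.
#' @param grid_n number of interior grid points.
#' @param eps distance kept from the endpoints of (0, 1).
#' @return a list with the detected \code{shape} (\code{"increasing"},
#'   \code{"bathtub"} or \code{"other"}) and the number of sign changes of
#'   the hazard derivative on the grid.
#' @export
hazard_shape <- function(theta, grid_n = 2001L, eps = 1e-4) {
  check_theta(theta)
  y <- seq(eps, 1 - eps, length.out = grid_n)
  h <- hlogbilal(y, theta)
  d <- diff(h)
  sgn <- sign(d[d != 0])
  changes <- sum(diff(sgn) != 0)
  shape <- if (changes == 0 && all(d >= 0)) "increasing"
           else if (changes == 1 && d[1] < 0) "bathtub"
           else "other"
  list(shape = shape, sign_changes = changes)
}
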