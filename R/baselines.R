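#' Competing unit-interval distributions
#'
#' Density and distribution functions for the comparison families fitted
#' alongside the log-Bilal law: Kumaraswamy, Topp-Leone and unit-Lindley
#' (the beta family is available through \code{\link[stats]{dbeta}}).
#'
#' Densities on \eqn{0 < y < 1}:
#' \describe{
#'   \item{Kumaraswamy\eqn{(\alpha,\beta)}}{\eqn{\alpha\beta y^{\alpha-1}
#'     (1-y^\alpha)^{\beta-1}}, cdf \eqn{1-(1-y^\alpha)^\beta}.}
#'   \item{Topp-Leone\eqn{(\theta)}}{\eqn{\theta(2-2y)(2y-y^2)^{\theta-1}},
#'     cdf \eqn{(2y-y^2)^\theta}.}
#'   \item{unit-Lindley\eqn{(\theta)}}{\eqn{\frac{\theta^2}{1+\theta}
#'     (1-y)^{-3} \exp\{-\theta y/(1-y)\}}; the law of \eqn{X/(1+X)} for a
#'     Lindley variable \eqn{X}, with cdf
#'     \eqn{1 - \frac{1+\theta+\theta y/(1-y)}{1+\theta}
#'     e^{-\theta y/(1-y)}}.}
#' }
#'
#' @param x,q vector of values strictly inside (0, 1).
#' @param alpha,beta,theta positive parameters.
#' @param log,log.p,lower.tail as in \code{\link[stats]{dbeta}}.
#' @return density or probability values.
#' @examples
#' dkumaraswamy(0.3, 1, 2)  # equals dbeta(0.3, 1, 2)
#' ptoppleone(0.5, 0.7)     # (2*0.5 - 0.25)^0.7
#' @name unit_baselines
NULL

#' @rdname unit_baselines
#' @export
dkumaraswamy <- function(x, alpha, beta, log = FALSE) {
  check_unit_open(x, "x"); check_theta(alpha, "alpha"); check_theta(beta, "beta")
  lx <- log(x)
  logf <- log(alpha) + log(beta) + (alpha - 1) * lx +
    (beta - 1) * log(-expm1(alpha * lx))
  if (log) logf else exp(logf)
}

#' @rdname unit_baselines
#' @export
pkumaraswamy <- function(q, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_unit_closed(q, "q"); check_theta(alpha, "alpha"); check_theta(beta, "beta")
  s <- (1 - q^alpha)^beta                  # survival
  p <- if (lower.tail) 1 - s else s
  if (log.p) log(p) else p
}

#' @rdname unit_baselines
#' @export
dtoppleone <- function(x, theta, log = FALSE) {
  check_unit_open(x, "x"); check_theta(theta)
  logf <- log(theta) + log(2 - 2 * x) + (theta - 1) * log(2 * x - x^2)
  if (log) logf else exp(logf)
}

#' @rdname unit_baselines
#' @export
ptoppleone <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  check_unit_closed(q, "q"); check_theta(theta)
  p <- (2 * q - q^2)^theta
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname unit_baselines
#' @export
dunitlindley <- function(x, theta, log = FALSE) {
  check_unit_open(x, "x"); check_theta(theta)
  logf <- 2 * log(theta) - log1p(theta) - 3 * log1p(-x) - theta * x / (1 - x)
  if (log) logf else exp(logf)
}

#' @rdname unit_baselines
#' @export
punitlindley <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  check_unit_closed(q, "q"); check_theta(theta)
  z <- q / (1 - q)                          # q = 1 -> Inf -> p = 1
  s <- (1 + theta + theta * z) / (1 + theta) * exp(-theta * z)
  s[q == 1] <- 0
  p <- if (lower.tail) 1 - s else s
  if (log.p) log(p) else p
}

# ---- registry + MLE fitting ----------------------------------------------

baseline_families <- function() {
  list(
    beta = list(
      npar = 2L, names = c("alpha", "beta"),
      dfun = function(y, p, log = FALSE) dbeta(y, p[1], p[2], log = log),
      pfun = function(q, p) stats::pbeta(q, p[1], p[2]),
      start = function(y) {
        m <- mean(y); v <- max(var(y), 1e-8)
        k <- max(m * (1 - m) / v - 1, 1e-3)
        pmax(c(m * k, (1 - m) * k), 1e-3)
      }),
    kumaraswamy = list(
      npar = 2L, names = c("alpha", "beta"),
      dfun = function(y, p, log = FALSE) dkumaraswamy(y, p[1], p[2], log = log),
      pfun = function(q, p) pkumaraswamy(q, p[1], p[2]),
      start = function(y) {
        m <- mean(y); v <- max(var(y), 1e-8)
        k <- max(m * (1 - m) / v - 1, 1e-3)
        pmax(c(m * k, (1 - m) * k), 1e-3)
      }),
    toppleone = list(
      npar = 1L, names = "theta",
      dfun = function(y, p, log = FALSE) dtoppleone(y, p[1], log = log),
      pfun = function(q, p) ptoppleone(q, p[1]),
      start = function(y) -length(y) / sum(log(2 * y - y^2))),
    unitlindley = list(
      npar = 1L, names = "theta",
      dfun = function(y, p, log = FALSE) dunitlindley(y, p[1], log = log),
      pfun = function(q, p) punitlindley(q, p[1]),
      start = function(y) max((1 - mean(y)) / mean(y), 1e-3))
  )
}

baseline_fit_mle <- function(y, family, control) {
  fam <- baseline_families()[[family]]
  nll <- function(par) {
    # keep the optimizer inside the parameter space even when exp() of a
    # wandering log-parameter under/overflows
    if (!all(is.finite(par)) || any(par <= 0)) return(1e10)
    v <- -sum(fam$dfun(y, par, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  if (fam$npar == 1L) {
    br <- log(control$theta_bracket)
    opt <- optimize(function(lp) nll(exp(lp)), interval = br, tol = 1e-10)
    par <- exp(opt$minimum)
    info <- observed_info_1d(function(p) -nll(p), par, control)
    se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
    vc <- matrix(se^2, 1, 1, dimnames = list(fam$names, fam$names))
    converged <- opt$minimum > br[1] + 1e-6 && opt$minimum < br[2] - 1e-6
  } else {
    opt <- optim(log(fam$start(y)), function(lp) nll(exp(lp)),
                 method = "BFGS",
                 control = list(reltol = control$reltol,
                                maxit = control$maxit))
    par <- exp(opt$par)
    H <- stats::optimHess(par, nll)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    se <- if (!is.null(vc) && all(diag(vc) > 0)) sqrt(diag(vc))
          else rep(NA_real_, 2L)
    if (!is.null(vc)) dimnames(vc) <- list(fam$names, fam$names)
    converged <- opt$convergence == 0L
  }
  if (!converged)
    warning(family, " MLE did not converge cleanly", call. = FALSE)
  names(par) <- fam$names
  se <- stats::setNames(se, fam$names)
  list(coefficients = par, se = se, vcov = vc, loglik = -nll(par),
       converged = converged)
}
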