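# Internal argument checks shared across the package.

check_theta <- function(theta, arg = "theta") {
  if (!is.numeric(theta) || length(theta) < 1L || anyNA(theta))
    stop("'", arg, "' must be numeric and non-missing", call. = FALSE)
  if (any(theta <= 0))
    stop("'", arg, "' must be strictly positive", call. = FALSE)
  invisible(theta)
}

check_mu <- function(mu, arg = "mu") {
  if (!is.numeric(mu) || length(mu) < 1L || anyNA(mu))
    stop("'", arg, "' must be numeric and non-missing", call. = FALSE)
  if (any(mu <= 0 | mu >= 1))
    stop("'", arg, "' must lie in the open interval (0, 1)", call. = FALSE)
  invisible(mu)
}

# Values on the open unit interval; endpoints are rejected, never clamped.
check_unit_open <- function(x, arg = "x") {
  if (!is.numeric(x) || length(x) < 1L)
    stop("'", arg, "' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(x))
    stop("'", arg, "' contains missing values", call. = FALSE)
  bad <- which(x <= 0 | x >= 1)
  if (length(bad))
    stop("'", arg, "' must lie strictly inside (0, 1); offending position(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  invisible(x)
}

check_unit_closed <- function(x, arg = "q") {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    stop("'", arg, "' must be numeric and non-missing", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("'", arg, "' must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

# A univariate sample for distribution fitting: open-interval values, n >= 1.
as_unit_sample <- function(y, arg = "y") {
  y <- as.numeric(y)
  check_unit_open(y, arg)
  y
}

check_count <- function(n, arg = "n", min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min || n != round(n))
    stop("'", arg, "' must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(n))
}
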