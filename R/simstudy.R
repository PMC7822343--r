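#' Monte-Carlo comparison of the log-Bilal estimators
#'
#' Repeatedly draws log-Bilal samples at a known shape \eqn{\theta}, applies
#' each estimator, and summarizes the estimates by
#' \deqn{\mathrm{Bias} = \frac{1}{N}\sum_j (\hat\theta_j - \theta), \quad
#'   \mathrm{MSE} = \frac{1}{N}\sum_j (\hat\theta_j - \theta)^2, \quad
#'   \mathrm{MRE} = \frac{1}{N}\sum_j \hat\theta_j/\theta}
#' for every sample size in \code{n_grid}.  A consistent, relatively
#' unbiased estimator has bias and MSE shrinking to 0 and MRE approaching 1
#' as \eqn{n} grows.
#'
#' All methods see identical samples within a replicate (paired comparison,
#' which removes between-sample Monte-Carlo noise from the method
#' contrast).  Each (sample size, replicate) cell gets its own RNG
#' substream derived from the master \code{seed}, so results are fully
#' reproducible and independent of the order of evaluation.  Replicates in
#' which a method fails are dropped from that method's aggregate and
#' counted in \code{failures}; a method failing in more than half the
#' replicates at some \eqn{n} aborts the study, since that signals a
#' defect rather than bad data.
#'
#' The defaults mirror the standard design for this model
#' (\eqn{\theta = 1.7}, \eqn{n = 20, 25, \dots, 300}); \code{n_reps}
#' defaults to 1000 for desk-scale runs and can be raised to 10000 for a
#' full-scale study.
#'
#' @param theta true shape parameter.
#' @param n_grid strictly increasing vector of sample sizes (minimum 5).
#' @param n_reps Monte-Carlo replications per sample size.
#' @param methods character subset of \code{c("mle","mm","lse","wlse")},
#'   or a named list of custom estimator functions \code{function(y)}
#'   returning a scalar estimate.
#' @param seed master seed.
#' @param keep_estimates logical: retain the raw estimate matrices in the
#'   \code{"estimates"} attribute.
#' @param control a list from \code{\link{lb_control}}.
#' @return a data frame of class \code{"lb_simstudy"} with columns
#'   \code{method}, \code{n}, \code{bias}, \code{mse}, \code{mre},
#'   \code{failures}.  \code{plot} draws bias/MSE/MRE against \eqn{n};
#'   \code{\link[utils]{write.csv}} exports the tidy table.
#' @examples
#' st <- estimator_study(theta = 1.7, n_grid = c(20, 50), n_reps = 50,
#'                       methods = c("mle", "mm"), seed = 1)
#' st
#' @export
estimator_study <- function(theta = 1.7,
                            n_grid = seq(20L, 300L, by = 5L),
                            n_reps = 1000L,
                            methods = c("mle", "mm", "lse", "wlse"),
                            seed = 1L, keep_estimates = FALSE,
                            control = lb_control()) {
  check_theta(theta)
  n_reps <- check_count(n_reps, "n_reps")
  if (length(n_grid) < 1L || any(n_grid < 5) || any(diff(n_grid) <= 0))
    stop("'n_grid' must be strictly increasing with all sizes >= 5",
         call. = FALSE)
  ests <- resolve_estimators(methods, control)
  mnames <- names(ests)

  # per-(n, replicate) substream seeds drawn once from the master seed
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(n_grid) * n_reps),
                  nrow = n_reps)

  res <- vector("list", length(n_grid) * length(mnames))
  keep <- if (keep_estimates) list()
  k <- 0L
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    est_mat <- matrix(NA_real_, n_reps, length(mnames),
                      dimnames = list(NULL, mnames))
    for (j in seq_len(n_reps)) {
      set.seed(seeds[j, gi])
      y <- rlogbilal(n, theta)
      for (m in mnames) {
        est_mat[j, m] <- tryCatch(ests[[m]](y),
                                  error = function(e) NA_real_,
                                  warning = function(w) NA_real_)
      }
    }
    for (m in mnames) {
      th <- est_mat[, m]
      fail <- sum(is.na(th))
      if (fail > n_reps / 2)
        stop("method '", m, "' failed in ", fail, "/", n_reps,
             " replicates at n = ", n, call. = FALSE)
      th <- th[!is.na(th)]
      k <- k + 1L
      res[[k]] <- data.frame(method = m, n = n,
                             bias = mean(th - theta),
                             mse = mean((th - theta)^2),
                             mre = mean(th / theta),
                             failures = fail)
    }
    if (keep_estimates) keep[[as.character(n)]] <- est_mat
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  attr(out, "config") <- list(theta = theta, n_grid = n_grid,
                              n_reps = n_reps, methods = mnames,
                              seed = seed)
  if (keep_estimates) attr(out, "estimates") <- keep
  class(out) <- c("lb_simstudy", "data.frame")
  out
}

resolve_estimators <- function(methods, control) {
  builtin <- list(
    mle  = function(y) coef(fit_unitdist(y, method = "mle",
                                         control = control))[["theta"]],
    mm   = function(y) coef(fit_unitdist(y, method = "mm"))[["theta"]],
    lse  = function(y) coef(fit_unitdist(y, method = "lse",
                                         control = control))[["theta"]],
    wlse = function(y) coef(fit_unitdist(y, method = "wlse",
                                         control = control))[["theta"]])
  if (is.character(methods)) {
    bad <- setdiff(methods, names(builtin))
    if (length(bad))
      stop("unknown method(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    return(builtin[methods])
  }
  if (is.list(methods) && length(methods) &&
      all(vapply(methods, is.function, TRUE))) {
    if (is.null(names(methods)) || any(names(methods) == ""))
      stop("custom estimator list must be fully named", call. = FALSE)
    return(methods)
  }
  stop("'methods' must be a character vector or a named list of functions",
       call. = FALSE)
}

#' @export
print.lb_simstudy <- function(x, digits = 4L, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Monte-Carlo estimator study: theta = %s, N = %d, %d sample size(s)\n\n",
    format(cfg$theta), cfg$n_reps, length(cfg$n_grid)))
  df <- as.data.frame(x)
  df[c("bias", "mse", "mre")] <- lapply(df[c("bias", "mse", "mre")],
                                        signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.lb_simstudy <- function(x, ...) {
  cfg <- attr(x, "config")
  df <- as.data.frame(x)
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  for (stat in c("bias", "mse", "mre")) {
    wide <- do.call(cbind, lapply(cfg$methods,
      function(m) df[df$method == m, stat]))
    graphics::matplot(cfg$n_grid, wide, type = "l", lty = 1,
                      xlab = "n", ylab = stat, ...)
    graphics::abline(h = if (stat == "mre") 1 else 0, lty = 3)
    graphics::legend("topright", legend = cfg$methods, lty = 1,
                     col = seq_along(cfg$methods), bty = "n", cex = 0.8)
  }
  invisible(x)
}
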