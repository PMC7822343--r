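#' Read a unit-interval sample or regression table from CSV
#'
#' Reads a CSV with a header, validates that the response lies strictly
#' inside (0, 1), and returns either a numeric sample (no covariates) or a
#' data frame ready for \code{\link{lbreg}}.  Percentages are rescaled by
#' 1/100 only when \code{percent = TRUE} — never implicitly.  Rows with
#' missing values in the used columns are dropped with a message; responses
#' on the boundary raise an error naming the offending rows (values are
#' never clamped).
#'
#' @param path path to a CSV file with a header row.
#' @param response name of the response column; defaults to the first
#'   column.
#' @param covariates optional character vector of covariate column names.
#' @param percent logical: divide the response by 100 before validation.
#' @return if \code{covariates} is \code{NULL}, a numeric vector; otherwise
#'   a data frame containing the response and covariates, with the model
#'   formula in attribute \code{"formula"}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(rate = c(40, 50, 60)), f, row.names = FALSE)
#' read_unit_data(f, "rate", percent = TRUE)
#' @export
read_unit_data <- function(path, response = NULL, covariates = NULL,
                           percent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, header = TRUE)
  if (nrow(df) == 0L) stop("no rows in ", path, call. = FALSE)
  if (is.null(response)) response <- names(df)[1L]
  cols <- c(response, covariates)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cc in cols)
    if (!is.numeric(df[[cc]]))
      stop("column '", cc, "' is not numeric", call. = FALSE)
  used <- df[cols]
  keep <- stats::complete.cases(used)
  if (any(!keep)) {
    message("dropped ", sum(!keep), " row(s) with missing values")
    used <- used[keep, , drop = FALSE]
  }
  if (nrow(used) == 0L) stop("no complete rows remain", call. = FALSE)
  y <- used[[response]]
  if (percent) y <- y / 100
  bad <- which(y <= 0 | y >= 1)
  if (length(bad))
    stop("response '", response, "' outside the open interval (0, 1) ",
         "after any rescaling; offending row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  if (is.null(covariates)) return(y)
  used[[response]] <- y
  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " + ")))
  attr(used, "formula") <- fml
  used
}

#' Generate a synthetic fixture on disk
#'
#' Writes a CSV emulating the two input shapes the package consumes — a
#' univariate log-Bilal sample at a known shape, or a regression table with
#' a known coefficient vector through the logit link — together with a JSON
#' sidecar recording the generating truth.  Covariates are drawn i.i.d.
#' uniform on (0, 1); responses come from inverse-transform sampling at
#' \eqn{\theta(\mu_i)}.  Identical seeds give byte-identical files.
#'
#' @param kind \code{"sample"} or \code{"regression"}.
#' @param path output CSV path (the sidecar gets extension
#'   \code{.meta.json}).
#' @param n number of rows.
#' @param theta shape parameter (for \code{kind = "sample"}).
#' @param beta coefficient vector, intercept first (for
#'   \code{kind = "regression"}); \code{length(beta) - 1} covariates are
#'   generated.
#' @param seed integer seed.
#' @return invisibly, a list with the CSV and sidecar paths.
#' @examples
#' p <- generate_fixture("sample", tempfile(fileext = ".csv"),
#'                       n = 50, theta = 1.7, seed = 1)
#' length(read_unit_data(p$csv, "y"))
#' @export
generate_fixture <- function(kind = c("sample", "regression"), path,
                             n = 100L, theta = 1.7, beta = c(0, 1),
                             seed = 1L) {
  kind <- match.arg(kind)
  n <- check_count(n, "n")
  set.seed(as.integer(seed))
  if (kind == "sample") {
    check_theta(theta)
    df <- data.frame(y = rlogbilal(n, theta))
    truth <- list(kind = kind, theta = theta, n = n, seed = seed)
  } else {
    if (!is.numeric(beta) || length(beta) < 1L || anyNA(beta))
      stop("'beta' must be a numeric coefficient vector", call. = FALSE)
    p <- length(beta)
    X <- cbind(1, if (p > 1L) matrix(runif(n * (p - 1L)), n, p - 1L))
    mu <- lbreg_mu(X %*% beta)
    y <- qlogbilal(runif(n), mu_to_theta(mu))
    df <- data.frame(y = y)
    if (p > 1L) {
      xn <- paste0("x", seq_len(p - 1L))
      df[xn] <- X[, -1L, drop = FALSE]
    }
    truth <- list(kind = kind, beta = beta, n = n, seed = seed)
  }
  write.csv(df, path, row.names = FALSE)
  meta <- sub("\\.csv$", "", path)
  meta <- paste0(meta, ".meta.json")
  jsonlite::write_json(truth, meta, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = path, meta = meta))
}
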