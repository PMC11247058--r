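#' Median and interquartile range
#'
#' Non-normally distributed quantities (clot RBC and platelet content) are
#' summarised as median with 25th--75th percentiles. Quantiles use the
#' linear-interpolation convention (R type 7).
#'
#' @param v Numeric vector, non-empty; `NA`s are dropped.
#' @return A list with `median` and `iqr` (25th, 75th percentiles).
#' @export
median_iqr <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty vector", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], iqr = c(q[1], q[3]))
}

# shared assembly of a regression result from a fitted lm
ols_result <- function(fit, n) {
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  cf <- sm$coefficients
  beta <- cf[-1, 1]
  p_value <- cf[-1, 4]
  names(beta) <- names(p_value) <- rownames(cf)[-1]
  structure(list(
    intercept = unname(cf[1, 1]),
    beta = beta,
    ci95 = ci[-1, , drop = FALSE],
    p_value = p_value,
    intercept_ci95 = ci[1, ],
    intercept_p = unname(cf[1, 4]),
    r_squared = sm$r.squared,
    n = n,
    fit = fit),
    class = "clot_ols")
}

#' Simple (univariate) linear regression
#'
#' Ordinary least squares of one outcome on one predictor, reported as the
#' unstandardised coefficient with t-based 95% confidence interval
#' (n - 2 df), two-sided p-value and R-squared.
#'
#' @param y Outcome vector.
#' @param x Predictor vector.
#' @return An object of class `clot_ols` with `intercept`, `beta`, `ci95`,
#'   `p_value`, `r_squared`, `n`.
#' @export
simple_ols <- function(y, x) {
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("need at least 3 complete observations",
                          call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  ols_result(stats::lm(y ~ x), length(y))
}

#' Multiple least-squares linear regression
#'
#' OLS of one outcome on several predictors, with per-coefficient
#' unstandardised estimates, t-based 95% confidence intervals
#' (n - p - 1 df), two-sided p-values, overall R-squared and intercept.
#'
#' @param y Outcome vector.
#' @param X Data frame (or matrix) of predictors, one column each.
#' @return An object of class `clot_ols`.
#' @export
multiple_ols <- function(y, X) {
  X <- as.data.frame(X)
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  p <- ncol(X)
  if (length(y) <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  fit <- stats::lm(y ~ ., data = X)
  if (fit$rank < p + 1) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  ols_result(fit, length(y))
}

#' @export
print.clot_ols <- function(x, digits = 3, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.3f, intercept = %.4g\n",
              x$n, x$r_squared, x$intercept))
  tab <- data.frame(beta = x$beta,
                    ci_low = x$ci95[, 1], ci_high = x$ci95[, 2],
                    p = x$p_value)
  print(round(tab, digits))
  invisible(x)
}

#' Tidy one-row-per-coefficient view of a regression
#'
#' @param x A `clot_ols` object.
#' @return A data frame with columns `predictor`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `r_squared`, `intercept`, `n`.
#' @export
tidy_ols <- function(x) {
  stopifnot(inherits(x, "clot_ols"))
  data.frame(predictor = names(x$beta),
             beta = unname(x$beta),
             ci_low = unname(x$ci95[, 1]),
             ci_high = unname(x$ci95[, 2]),
             p = unname(x$p_value),
             r_squared = x$r_squared,
             intercept = x$intercept,
             n = x$n,
             row.names = NULL)
}

#' Simple + multiple regression table for a cohort
#'
#' Builds the standard reporting table for one or more outcomes: a simple
#' (univariate) regression per predictor, and one multiple regression on
#' all predictors jointly.
#'
#' @param data Data frame of per-clot values.
#' @param outcomes Character vector of outcome column names.
#' @param predictors Character vector of predictor column names, or a
#'   named list mapping each outcome to its own predictor set.
#' @return A data frame with one row per (outcome, model, predictor):
#'   columns `outcome`, `model` (`"simple"` or `"multiple"`), `predictor`,
#'   `beta`, `ci_low`, `ci_high`, `p`, `r_squared`, `intercept`, `n`.
#' @export
regression_table <- function(data, outcomes,
                             predictors = c("rbc_content",
                                            "platelet_content")) {
  rows <- list()
  for (out in outcomes) {
    preds <- if (is.list(predictors)) predictors[[out]] else predictors
    for (p in preds) {
      t1 <- tidy_ols(simple_ols(data[[out]], data[[p]]))
      t1$predictor <- p
      t1 <- cbind(outcome = out, model = "simple", t1)
      rows[[length(rows) + 1]] <- t1
    }
    tm <- tidy_ols(multiple_ols(data[[out]], data[preds]))
    tm <- cbind(outcome = out, model = "multiple", tm)
    rows[[length(rows) + 1]] <- tm
  }
  do.call(rbind, rows)
}
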