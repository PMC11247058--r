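test_that("simple regression recovers an exact linear relation", {
  x <- 1:6
  fit <- suppressWarnings(simple_ols(2 * x, x))
  expect_equal(unname(fit$beta), 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$ci95[1, 2] - fit$ci95[1, 1]), 0,
               tolerance = 1e-10)
  expect_error(simple_ols(1:5, rep(3, 5)), "constant")
})

test_that("simple and multiple fits match the normal-equations oracle", {
  # fixed 5-point hand dataset
  x <- c(1, 2, 4, 5, 9)
  y <- c(2.1, 3.9, 8.3, 9.8, 18.5)
  fit <- simple_ols(y, x)
  orc <- ols_oracle(y, cbind(x))
  expect_equal(unname(c(fit$intercept, fit$beta)), unname(orc$beta),
               tolerance = 1e-8)
  expect_equal(unname(fit$ci95[1, ]), unname(c(orc$ci_low[2], orc$ci_high[2])),
               tolerance = 1e-8)
  expect_equal(unname(fit$p_value[1]), unname(orc$p[2]), tolerance = 1e-8)
  expect_equal(fit$r_squared, orc$r2, tolerance = 1e-8)

  # random small multi-predictor designs
  set.seed(41)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    X <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, 2))
    yy <- 1 + 0.5 * X$a - 2 * X$b + rnorm(n)
    f <- multiple_ols(yy, X)
    o <- ols_oracle(yy, as.matrix(X))
    expect_equal(unname(c(f$intercept, f$beta)), unname(o$beta),
                 tolerance = 1e-8)
    expect_equal(unname(f$ci95[, 1]), unname(o$ci_low[-1]), tolerance = 1e-8)
    expect_equal(unname(f$ci95[, 2]), unname(o$ci_high[-1]), tolerance = 1e-8)
    expect_equal(unname(f$p_value), unname(o$p[-1]), tolerance = 1e-8)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-8)
  }
})

test_that("multiple regression with one predictor equals simple regression", {
  set.seed(13)
  x <- rnorm(30); y <- 1 + 2 * x + rnorm(30)
  fs <- simple_ols(y, x)
  fm <- multiple_ols(y, data.frame(x = x))
  expect_equal(unname(fm$beta), unname(fs$beta))
  expect_equal(unname(fm$ci95), unname(fs$ci95))
  expect_equal(unname(fm$p_value), unname(fs$p_value))
  expect_equal(fm$r_squared, fs$r_squared)
})

test_that("exact multivariate relation and diagnostics", {
  set.seed(3)
  X <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  y <- 1 + 2 * X$x1 + 3 * X$x2
  f <- suppressWarnings(multiple_ols(y, X))
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_equal(unname(f$beta), c(2, 3), tolerance = 1e-9)
  expect_equal(f$r_squared, 1)

  # residual orthogonality to each predictor
  yy <- y + rnorm(20)
  f2 <- multiple_ols(yy, X)
  res <- yy - (f2$intercept + as.matrix(X) %*% f2$beta)
  expect_lt(max(abs(crossprod(as.matrix(X), res))), 1e-8)

  # R^2 of the joint fit dominates each nested simple fit
  expect_gte(f2$r_squared, simple_ols(yy, X$x1)$r_squared)
  expect_gte(f2$r_squared, simple_ols(yy, X$x2)$r_squared)

  # collinearity is an error naming the offending column
  Xc <- data.frame(x1 = X$x1, x2 = 2 * X$x1)
  expect_error(multiple_ols(yy, Xc), "collinear")
})

test_that("confidence intervals cover a null slope at the nominal rate", {
  set.seed(71)
  hits <- replicate(300, {
    x <- rnorm(25); y <- rnorm(25)  # independent
    f <- simple_ols(y, x)
    f$ci95[1, 1] <= 0 && 0 <= f$ci95[1, 2]
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("median and IQR use linear-interpolation quantiles", {
  s <- median_iqr(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$iqr, c(3, 7))

  s2 <- median_iqr(rep(4.2, 10))
  expect_equal(s2$median, 4.2)
  expect_equal(s2$iqr, c(4.2, 4.2))

  set.seed(9)
  v <- rnorm(101)
  s3 <- median_iqr(v)
  expect_equal(s3$median, quantile_oracle(v, 0.5))
  expect_equal(s3$iqr, c(quantile_oracle(v, 0.25), quantile_oracle(v, 0.75)))

  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("regression_table emits one row per outcome/model/predictor", {
  set.seed(19)
  d <- data.frame(rbc_content = runif(30, 0, 100),
                  platelet_content = runif(30, 0, 90))
  d$ncct_density <- 17 + 0.35 * d$rbc_content + 0.22 * d$platelet_content +
    rnorm(30, 0, 3)
  tab <- regression_table(d, "ncct_density")
  expect_equal(nrow(tab), 4)  # 2 simple rows + 2 multiple rows
  expect_setequal(unique(tab$model), c("simple", "multiple"))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  expect_true(all(tab$n == 30))
})
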