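test_that("OLS recovers a noiseless line exactly", {
  x <- 1:10
  f <- fit_ols(2 * x + 1, x)
  expect_equal(vapply(f$coefficients, `[[`, numeric(1), "beta"), c(1, 2))
  expect_equal(f$r2, 1)
  expect_equal(f$see_abs, 0)
  expect_equal(sum(f$residuals), 0)
})

test_that("OLS matches a normal-equations oracle on random problems", {
  set.seed(31)
  for (i in 1:20) {
    n <- 20
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("v", seq_len(p))
    y <- rnorm(n, 5 + X %*% runif(p, -2, 2), 1)
    f <- fit_ols(y, X)
    # oracle: explicit inversion of the normal equations
    Xd <- cbind(1, X)
    bhat <- solve(t(Xd) %*% Xd) %*% t(Xd) %*% y
    see <- sqrt(sum((y - Xd %*% bhat)^2) / (n - p - 1))
    se <- sqrt(diag(solve(t(Xd) %*% Xd))) * see
    expect_equal(vapply(f$coefficients, `[[`, numeric(1), "beta"),
                 drop(bhat), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(vapply(f$coefficients, `[[`, numeric(1), "se"),
                 se, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(f$see_abs, see, tolerance = 1e-8)
    # adjusted R2 identity under the shared df convention
    expect_equal(f$adj_r2, 1 - f$see_abs^2 / stats::var(y))
  }
})

test_that("OLS preconditions", {
  expect_error(fit_ols(1:2, 1:2), "too few cases")
  expect_error(fit_ols(rnorm(10), rep(2, 10)), "constant-valued")
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(rnorm(10), X), "rank-deficient")
})

test_that("published fit statistics satisfy the adj-R2/SEE/SD identity", {
  for (g in muscle_groups()) {
    cc <- model_consistency(g)
    expect_equal(round(cc$adj_r2_from_see, 3), cc$adj_r2_printed)
    expect_equal(round(cc$see_pct_from_abs, 2), cc$see_pct_printed)
    expect_equal(round(cc$cv_residual_pct_from_abs, 2),
                 cc$cv_residual_pct_printed)
  }
})

test_that("semi-partial correlation: degenerate forms and oracle", {
  set.seed(32)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30)
  expect_equal(semi_partial_correlation(y, x), stats::cor(y, x))
  X <- cbind(x1 = x, x2 = x)
  expect_error(semi_partial_correlation(y, X, "x1"), "collinear")
  # 3-predictor case vs a brute-force two-stage residualization oracle
  for (i in 1:10) {
    X <- matrix(rnorm(25 * 3), 25)
    colnames(X) <- c("a", "b", "c")
    y <- rnorm(25, X %*% c(1, -0.5, 2))
    sp <- semi_partial_correlation(y, X, "b")
    res_b <- stats::residuals(stats::lm(X[, "b"] ~ X[, c("a", "c")]))
    expect_equal(sp, stats::cor(y, res_b), tolerance = 1e-10)
  }
})

test_that("Durbin-Watson statistic: hand cases, bounds, table", {
  dwd <- musclevol:::durbin_watson_d
  expect_equal(dwd(c(1, 1, 1, 1)), 0)
  expect_equal(dwd(c(1, -1, 1, -1)), 3)
  expect_true(is.na(dwd(rep(0, 5))))
  # published worked case: d = 1.67 at n = 14, k = 1 exceeds the upper bound
  dw <- durbin_watson(rnorm(14), k = 1)
  expect_equal(dw$du, 1.350)
  expect_true(1.67 > dw_upper_bound(14, 1))
  expect_equal(dw_upper_bound(6, 1), 1.400)
  expect_equal(dw_upper_bound(20, 2), 1.538)
  expect_warning(dw_upper_bound(50, 1), "n = 6..20")
  expect_warning(dw_upper_bound(10, 3), "k = 1..2")
  # d stays in [0, 4] and is invariant to residual reversal
  set.seed(33)
  for (i in 1:50) {
    e <- rnorm(sample(5:40, 1))
    d <- dwd(e)
    expect_gte(d, 0)
    expect_lte(d, 4)
    expect_equal(dwd(rev(e)), d)
  }
})

test_that("Lilliefors normality test: preconditions, oracle, calibration", {
  expect_error(normality_test(1:3), "at least 4")
  expect_error(normality_test(rep(1, 10)), "constant")
  # frozen oracle values (statsmodels lilliefors, approx p-value method);
  # the deep tail branch agrees to 1e-8, the body branch to ~0.015
  expect_equal(normality_test(c(0:9, 30:39)), 0.0021583401, tolerance = 1e-6)
  expect_equal(normality_test((1:20)^1.5), 0.7788389, tolerance = 0.02)
  expect_equal(normality_test(sin(1:40)), 0.1361944, tolerance = 0.03)
  # gross bimodality rejected
  expect_lt(normality_test(c(rnorm(50, 0, 0.2), rnorm(50, 10, 0.2))), 0.05)
  # null calibration: reject rate near alpha
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    normality_test(rnorm(60)) < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
  # Shapiro-Wilk alternative wired through
  expect_equal(normality_test(sin(1:40), method = "shapiro"),
               stats::shapiro.test(sin(1:40))$p.value)
})

test_that("homoscedasticity check calibrated and powered", {
  het <- vapply(1:60, function(s) {
    set.seed(s)
    x <- runif(500, 1, 10)
    mu <- 10 + 2 * x
    f <- fit_ols(mu + rnorm(500, 0, 0.3 * mu), x)
    !homoscedasticity_check(f)$pass
  }, logical(1))
  expect_gte(mean(het), 0.9)
  hom <- vapply(1:60, function(s) {
    set.seed(s + 500)
    x <- runif(500, 1, 10)
    f <- fit_ols(10 + 2 * x + rnorm(500, 0, 3), x)
    homoscedasticity_check(f)$pass
  }, logical(1))
  expect_gte(mean(hom), 0.85)
  # constant residuals: degenerate, pass-with-flag
  f0 <- fit_ols(2 * (1:10) + 1, 1:10)
  hc <- homoscedasticity_check(f0)
  expect_true(hc$pass)
  expect_true(hc$degenerate)
})

test_that("Bland-Altman trend: hand oracle, degenerate, power", {
  r <- bland_altman_trend(c(10, 20, 30, 40), c(11, 19, 28, 36))
  expect_equal(r$residuals, c(-1, 1, 2, 4))
  # hand Pearson on the 4 points
  res <- c(-1, 1, 2, 4)
  mid <- c(10.5, 19.5, 29, 38)
  hand_r <- sum((res - mean(res)) * (mid - mean(mid))) /
    sqrt(sum((res - mean(res))^2) * sum((mid - mean(mid))^2))
  expect_equal(r$trend_r, hand_r, tolerance = 1e-12)

  d <- bland_altman_trend(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(d$degenerate)
  expect_false(d$systematic_error)
  expect_error(bland_altman_trend(1:3, 1:3), "at least 4")

  # proportional bias detected nearly always at n = 200
  pw <- vapply(1:40, function(s) {
    set.seed(s)
    crit <- rnorm(200, 100, 15)
    model <- crit - (0.1 * crit + rnorm(200, 0, 2))
    bland_altman_trend(crit, model)$systematic_error
  }, logical(1))
  expect_gte(mean(pw), 0.95)
})
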