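# Statistical primitives for the model-development pipeline: forced-entry
# OLS with inference, semi-partial correlation, the Durbin-Watson statistic
# with tabulated 5% upper bounds, a Lilliefors-corrected normality test, a
# quantitative homoscedasticity check, and the difference-versus-mean
# (Bland-Altman) agreement trend.

#' Forced-entry ordinary least squares with inference
#'
#' Fits `y = b0 + X b + e` with an intercept always included. The standard
#' error of the estimate is `SEE = sqrt(SS_res / (n - p - 1))`; standardised
#' residuals are `residual / SEE` (not studentized); 95% confidence intervals
#' use the t distribution on `n - p - 1` degrees of freedom.
#'
#' @param y Numeric response, cm^3 in the volume application.
#' @param X Predictor matrix or data.frame (no intercept column), or a
#'   numeric vector for simple regression.
#' @return Object of class `regression_fit`: `coefficients` (list, constant
#'   first, each with `beta`, `se`, `ci95_low`, `ci95_high`, `p_value`),
#'   `r2`, `adj_r2`, `see_abs`, `see_pct`, `residuals`, `std_residuals`,
#'   `fitted`, `dw`, `n`, `k` (number of predictors), `y_mean`.
#' @examples
#' x <- 1:10
#' f <- fit_ols(2 * x + 1, x)
#' vapply(f$coefficients, `[[`, numeric(1), "beta")  # c(1, 2)
#' @export
fit_ols <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) stop("y and X must have the same number of cases",
                         call. = FALSE)
  p <- ncol(X)
  if (n <= p + 1L) {
    stop("too few cases: need n > p + 1 (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant-valued predictor is not allowed besides the intercept",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  Xd <- cbind(`(constant)` = 1, X)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    stop("rank-deficient predictor matrix (collinear predictors)",
         call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xd %*% beta)
  res <- y - fitted
  df_res <- n - p - 1L
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  see <- sqrt(ss_res / df_res)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtX_inv)) * see
  tcrit <- stats::qt(0.975, df_res)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  coefs <- lapply(seq_along(beta), function(i) {
    list(name = names(beta)[i], beta = unname(beta[i]), se = unname(se[i]),
         ci95_low = unname(beta[i] - tcrit * se[i]),
         ci95_high = unname(beta[i] + tcrit * se[i]),
         p_value = unname(pval[i]))
  })
  structure(
    list(coefficients = coefs, r2 = r2, adj_r2 = adj_r2,
         see_abs = see, see_pct = 100 * see / mean(y),
         residuals = res,
         std_residuals = if (see > 0) res / see else res * 0,
         fitted = fitted,
         dw = durbin_watson_d(res),
         n = n, k = p, y_mean = mean(y),
         predictor_names = colnames(X), X = X, y = y),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, k = %d\n", x$n, x$k))
  for (cf in x$coefficients) {
    cat(sprintf("  %-28s %10.3f  SE %.3f  95%% CI (%.3f, %.3f)  p = %.3g\n",
                cf$name, cf$beta, cf$se, cf$ci95_low, cf$ci95_high,
                cf$p_value))
  }
  cat(sprintf("  R2 %.3f, adj R2 %.3f, SEE %.2f (%.2f%%), DW %.2f\n",
              x$r2, x$adj_r2, x$see_abs, x$see_pct, x$dw))
  invisible(x)
}

#' Predict from a `regression_fit`
#' @param object A [fit_ols()] result.
#' @param newdata Matrix/data.frame with the fitted predictor columns.
#' @param ... Unused.
#' @export
predict.regression_fit <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$predictor_names,
                                         drop = FALSE])
  storage.mode(nd) <- "double"
  betas <- vapply(object$coefficients, `[[`, numeric(1), "beta")
  drop(cbind(1, nd) %*% betas)
}

#' Semi-partial (part) correlation
#'
#' Correlation between `y` and the residual of the target predictor after
#' regressing it on the remaining columns of `X`. With a single predictor the
#' partialling set is empty and the result equals the Pearson correlation.
#'
#' @param y Response vector.
#' @param X Predictor matrix/data.frame (or vector, for a single candidate).
#' @param target Column name (or index) of the predictor of interest.
#' @return The semi-partial correlation (length-1 numeric).
#' @export
semi_partial_correlation <- function(y, X, target = 1L) {
  y <- as.numeric(y)
  X <- as.matrix(as.data.frame(X))
  if (is.character(target)) {
    if (!target %in% colnames(X)) {
      stop("target '", target, "' not found among predictors", call. = FALSE)
    }
    target <- match(target, colnames(X))
  }
  xt <- X[, target]
  others <- X[, -target, drop = FALSE]
  if (ncol(others) == 0L) {
    part <- xt - mean(xt)
  } else {
    Z <- cbind(1, others)
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      stop("rank deficiency among the partialling set", call. = FALSE)
    }
    part <- qr.resid(qz, xt)
    if (stats::sd(part) < 1e-12 * max(stats::sd(xt), 1)) {
      stop("target predictor is collinear with the partialling set",
           call. = FALSE)
    }
  }
  stats::cor(y, part)
}

# a fit whose residuals are numerical noise around an exact solution (e.g.
# zero-noise synthetic data) is degenerate for residual-based diagnostics
near_zero_residuals <- function(fit) {
  fit$see_abs < 1e-8 * max(abs(fit$y_mean), stats::sd(fit$y), 1)
}

# raw Durbin-Watson d from an ordered residual vector
durbin_watson_d <- function(residuals) {
  e <- as.numeric(residuals)
  denom <- sum(e^2)
  if (denom == 0) return(NA_real_)
  sum(diff(e)^2) / denom
}

# Published 5% significance upper bounds dU for the Durbin-Watson test,
# n = 6..20, k = 1 and 2 regressors excluding the intercept (Savin-White
# tabulation of the Durbin-Watson bounds).
.dw_upper_5pct <- list(
  k1 = c(`6` = 1.400, `7` = 1.356, `8` = 1.332, `9` = 1.320, `10` = 1.320,
         `11` = 1.324, `12` = 1.331, `13` = 1.340, `14` = 1.350, `15` = 1.361,
         `16` = 1.371, `17` = 1.381, `18` = 1.391, `19` = 1.401, `20` = 1.411),
  k2 = c(`6` = 1.896, `7` = 1.777, `8` = 1.699, `9` = 1.641, `10` = 1.604,
         `11` = 1.579, `12` = 1.562, `13` = 1.551, `14` = 1.543, `15` = 1.539,
         `16` = 1.536, `17` = 1.535, `18` = 1.535, `19` = 1.537, `20` = 1.538)
)

#' Tabulated Durbin-Watson 5% upper bound dU
#'
#' Embedded published bounds for n = 6..20 and k = 1..2 predictors. Outside
#' the table the nearest tabulated bound is used conservatively, with a
#' warning: n is clamped into 6..20 (dU varies slowly in n) and k into 1..2.
#'
#' @param n Number of cases (residuals).
#' @param k Number of predictors excluding the intercept.
#' @return The 5% upper bound dU.
#' @export
dw_upper_bound <- function(n, k = 1L) {
  if (k < 1L || k > 2L) {
    warning("Durbin-Watson bound table covers k = 1..2; using nearest k")
    k <- min(max(k, 1L), 2L)
  }
  tab <- .dw_upper_5pct[[paste0("k", k)]]
  if (n < 6L || n > 20L) {
    warning("Durbin-Watson bound table covers n = 6..20; using nearest n")
    n <- min(max(n, 6L), 20L)
  }
  unname(tab[as.character(as.integer(n))])
}

#' Durbin-Watson statistic with tabulated verdict
#'
#' `d = sum_t (e_t - e_{t-1})^2 / sum_t e_t^2` over the residuals in dataset
#' row order. The verdict is `pass` when d exceeds the tabulated 5% upper
#' bound dU(n, k): the test then supports the absence of positive first-order
#' autocorrelation. All-zero residuals leave d undefined (`NA`) and the
#' verdict flagged.
#'
#' @param residuals Ordered residual vector (dataset row order).
#' @param k Number of predictors excluding the intercept (for the bound).
#' @return List: `d`, `du`, `pass`, `undefined`.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))$d  # 3
#' @export
durbin_watson <- function(residuals, k = 1L) {
  e <- as.numeric(residuals)
  if (length(e) < 3L) stop("at least 3 residuals required", call. = FALSE)
  d <- durbin_watson_d(e)
  if (is.na(d)) {
    return(list(d = NA_real_, du = NA_real_, pass = NA, undefined = TRUE))
  }
  du <- dw_upper_bound(length(e), k)
  list(d = d, du = du, pass = d > du, undefined = FALSE)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data, with the Lilliefors correction of the null
#' distribution. The p value uses the Dallal-Wilkinson analytic
#' approximation, switching to the Stephens modification when the
#' approximate p exceeds 0.1 (the approximation is most accurate in the
#' tail).
#'
#' @param values Numeric sample, n >= 4, non-constant.
#' @param method `"lilliefors"` (default) or `"shapiro"` (Shapiro-Wilk,
#'   provided as an alternative).
#' @return The p value (length-1 numeric).
#' @export
normality_test <- function(values, method = c("lilliefors", "shapiro")) {
  method <- match.arg(method)
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 4L) stop("at least 4 values required", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant input: normality undefined",
                              call. = FALSE)
  if (method == "shapiro") return(stats::shapiro.test(x)$p.value)

  p <- stats::pnorm((x - mean(x)) / stats::sd(x))
  Dplus <- max(seq_len(n) / n - p)
  Dminus <- max(p - (seq_len(n) - 1) / n)
  K <- max(Dplus, Dminus)
  # Dallal-Wilkinson (1986) approximation, corrected
  if (n > 100) {
    Kd <- K * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- K
    nd <- n
  }
  pval <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
              2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
              0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pval > 0.1) {
    # Stephens (1974) modification for the body of the distribution
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * K
    pval <- if (KK <= 0.302) {
      1
    } else if (KK <= 0.5) {
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 - 138.55152 * KK^3 +
        81.218052 * KK^4
    } else if (KK <= 0.9) {
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 + 94.029866 * KK^3 -
        32.355711 * KK^4
    } else if (KK <= 1.31) {
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 - 12.234627 * KK^3 +
        2.423045 * KK^4
    } else {
      0
    }
  }
  min(max(pval, 0), 1)
}

#' Quantitative homoscedasticity check
#'
#' Correlates the absolute standardised residuals with the standardised
#' predicted values; the fit passes when the two-sided p value of the Pearson
#' correlation is at least `alpha` (no positive or negative spread trend).
#' Constant residuals are degenerate: reported as a pass with a flag.
#'
#' @param fit A [fit_ols()] result with at least 5 cases.
#' @param alpha Significance level, default 0.05.
#' @return List: `r`, `p`, `pass`, `degenerate`.
#' @export
homoscedasticity_check <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$n < 5L) stop("at least 5 cases required", call. = FALSE)
  ar <- abs(fit$std_residuals)
  zp <- (fit$fitted - mean(fit$fitted)) / stats::sd(fit$fitted)
  if (stats::sd(ar) == 0 || near_zero_residuals(fit)) {
    return(list(r = NA_real_, p = NA_real_, pass = TRUE, degenerate = TRUE))
  }
  ct <- stats::cor.test(ar, zp)
  list(r = unname(ct$estimate), p = ct$p.value,
       pass = ct$p.value >= alpha, degenerate = FALSE)
}

#' Difference-versus-mean (Bland-Altman) agreement trend
#'
#' Residuals are criterion minus model estimates; the abscissa is the mean of
#' the two methods. A significant Pearson correlation between residual and
#' mean indicates proportional (systematic) error. Zero-variance residuals
#' leave the trend undefined and are reported as no-trend with a flag.
#'
#' @param criterion,model Paired volume estimates, cm^3, n >= 4.
#' @param alpha Significance level for the systematic-error flag.
#' @return Object of class `agreement_result`: `mean_of_methods`,
#'   `residuals`, `trend_r`, `trend_p`, `systematic_error`, `degenerate`.
#' @export
bland_altman_trend <- function(criterion, model, alpha = 0.05) {
  criterion <- as.numeric(criterion)
  model <- as.numeric(model)
  if (length(criterion) != length(model)) {
    stop("criterion and model values must be paired", call. = FALSE)
  }
  if (length(criterion) < 4L) stop("at least 4 pairs required", call. = FALSE)
  res <- criterion - model
  mids <- (criterion + model) / 2
  if (stats::sd(res) < 1e-8 * max(stats::sd(criterion), 1) ||
      stats::sd(mids) == 0) {
    return(structure(
      list(mean_of_methods = mids, residuals = res, trend_r = NA_real_,
           trend_p = NA_real_, systematic_error = FALSE, degenerate = TRUE),
      class = "agreement_result"))
  }
  ct <- stats::cor.test(res, mids)
  structure(
    list(mean_of_methods = mids, residuals = res,
         trend_r = unname(ct$estimate), trend_p = ct$p.value,
         systematic_error = ct$p.value < alpha, degenerate = FALSE),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Agreement: degenerate (zero-variance residuals), no trend\n")
  } else {
    cat(sprintf("Agreement trend: r = %.3f, p = %.3g%s\n", x$trend_r,
                x$trend_p,
                if (x$systematic_error) " [systematic error]" else ""))
  }
  invisible(x)
}
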