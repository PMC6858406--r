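test_that("outlier exclusion removes a planted gross outlier and only it", {
  set.seed(41)
  x <- rnorm(20, 100, 10)
  expect_equal(length(exclude_outliers(x)$removed), 0)
  contaminated <- c(x, 100 + 60)  # single 6-SD point
  # verify by brute force that the contaminated sample fails normality
  expect_lt(normality_test(contaminated), 0.05)
  out <- exclude_outliers(contaminated)
  expect_equal(out$removed, 21L)
  expect_gte(out$p_final, 0.05)
  # cap zero is the identity (and warns that the sample stays non-normal)
  expect_warning(out0 <- exclude_outliers(contaminated, max_removals = 0),
                 "still non-normal")
  expect_equal(length(out0$removed), 0)
  expect_warning(exclude_outliers(c(rnorm(30, 0, 0.1), rnorm(30, 50, 0.1)),
                                  max_removals = 2),
                 "still non-normal")
  expect_error(exclude_outliers(1:5), "at least 6")
})

test_that("screening ranks a planted signal first and applies the rules", {
  set.seed(42)
  n <- 60
  d <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  mv <- 10 + 5 * d$signal + rnorm(n, 0, 0.5)
  scr <- screen_variables(d, mv, c("signal", "noise1", "noise2"))
  expect_equal(scr$candidates$name[1], "signal")
  expect_equal(scr$max_predictors, 4L)  # floor(60/15)

  # duplicated predictors: the weaker-ranked copy is excluded as collinear
  d$signal_copy <- d$signal
  scr2 <- screen_variables(d, mv, c("signal", "signal_copy", "noise1"))
  expect_false("signal_copy" %in% scr2$candidates$name)
  expect_equal(scr2$excluded$reason[scr2$excluded$name == "signal_copy"],
               "collinearity")

  # the 1-per-15 rule clamps to one predictor at n = 14
  scr3 <- screen_variables(d[1:14, ], mv[1:14],
                           c("signal", "noise1", "noise2"))
  expect_equal(scr3$max_predictors, 1L)
  expect_lte(nrow(scr3$candidates), 1L)

  expect_error(screen_variables(d, mv, c("signal", "absent_col")),
               "absent_col")
})

test_that("sample split reproduces the published holdout sizes", {
  s17 <- split_sample(17, 0.2, seed = 1)
  expect_length(s17$holdout, 3)
  expect_length(s17$development, 14)
  s18 <- split_sample(18, 0.2, seed = 1)
  expect_length(s18$holdout, 4)
  expect_length(s18$development, 14)
  # disjoint, exhaustive, deterministic
  expect_setequal(c(s18$holdout, s18$development), 1:18)
  expect_identical(split_sample(18, 0.2, seed = 5),
                   split_sample(18, 0.2, seed = 5))
  expect_error(split_sample(18, 0.6), "holdout_fraction")
  expect_error(split_sample(18, 0), "holdout_fraction")
})

test_that("leave-one-out selection keeps strong signals, drops noise", {
  set.seed(43)
  n <- 16
  x <- rnorm(n)
  y <- 3 + 5 * x + rnorm(n, 0, 1)  # slope many SEs from zero
  sel <- loo_candidate_selection(y, data.frame(x = x))
  expect_equal(sel$retained, "x")
  expect_true(all(sel$presence[, "x"]))

  # pure-noise predictor retained rarely over seeds
  rate <- mean(vapply(1:40, function(s) {
    set.seed(s)
    x <- rnorm(n)
    z <- rnorm(n)
    y <- 3 + 5 * x + rnorm(n, 0, 1)
    "z" %in% loo_candidate_selection(y, data.frame(x = x, z = z))$retained
  }, logical(1)))
  expect_lt(rate, 0.1)

  expect_error(loo_candidate_selection(rnorm(4), data.frame(a = rnorm(4),
                                                            b = rnorm(4))),
               "too small")
})

test_that("diagnostics flag planted violations", {
  set.seed(44)
  # insignificant predictor -> criterion 2 fails
  x1 <- rnorm(40)
  noise <- rnorm(40)
  f <- fit_ols(5 + 3 * x1 + rnorm(40), cbind(x1 = x1, noise = noise))
  d <- suppressWarnings(evaluate_diagnostics(f))
  expect_false(d$criteria[[2]]$pass)

  # more than one extreme standardised residual -> criterion 1 fails
  set.seed(45)
  x <- rnorm(13)
  y <- 2 * x + rnorm(13, 0, 0.05)
  y[1] <- y[1] + 3
  y[2] <- y[2] - 3
  f2 <- fit_ols(y, x)
  d2 <- suppressWarnings(evaluate_diagnostics(f2))
  expect_gte(d2$criteria[[1]]$evidence$n_extreme_residuals, 2)
  expect_false(d2$criteria[[1]]$pass)

  # criterion 7 stays advisory and never gates overall_pass
  cfg <- run_config(practicality = c(x = 0.1))
  d3 <- suppressWarnings(evaluate_diagnostics(fit_ols(2 * x + rnorm(13, 0, 0.1), x), cfg))
  expect_true(isTRUE(d3$criteria[[7]]$advisory))
})

test_that("develop_model runs the stated hip-extensor world end to end", {
  co <- hip_cohort(seed = 7, n = 18)
  cfg <- run_config(seed = 7)
  m <- develop_model(co, "hip_extensors", cfg)
  expect_s3_class(m, "developed_model")
  expect_equal(m$provenance$retained_variables, "mass_kg.thigh_length_m")
  expect_equal(m$cv$mean_residual_abs_pct,
               100 * m$cv$mean_residual_abs / m$cv$holdout_mean_mv)
  # criterion volumes come from the profiles, not a stored field
  expect_equal(unname(criterion_volumes(co, "hip_extensors")),
               co$latent_volumes$hip_extensors, tolerance = 1e-3)
  # determinism: byte-identical reports on a re-run
  m2 <- develop_model(co, "hip_extensors", cfg)
  expect_identical(as.character(model_report_json(m)),
                   as.character(model_report_json(m2)))
})

test_that("generating product is retained in the majority of seeds", {
  hits <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 17, seed = s,
                                      n_slices_range = c(5L, 8L)),
                          include_session2 = FALSE)
    m <- tryCatch(
      suppressWarnings(develop_model(co, "hip_extensors",
                                     run_config(seed = s))),
      error = function(e) NULL)
    !is.null(m) &&
      "mass_kg.thigh_length_m" %in% m$provenance$retained_variables
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("zero-noise pipeline: SEE ~ 0, zero CV residual, diagnostics pass", {
  g <- musclevol:::default_group_specs()
  for (nm in names(g)) g[[nm]]$noise_sd <- 0
  co <- generate_cohort(cohort_spec(n_subjects = 18, seed = 9, groups = g,
                                    n_slices_range = c(5L, 8L)))
  m <- develop_model(co, "knee_extensors", run_config(seed = 9))
  expect_lt(m$fit$see_abs, 1e-6)
  expect_lt(abs(m$cv$mean_residual), 1e-6)
  expect_true(m$diagnostics$overall_pass)
  expect_true(m$agreement$degenerate)
})

test_that("planted heteroscedastic cohort fails criterion 5", {
  fx <- constructed_ke_cohort(n = 100, seed = 46, noise_sd = 120,
                              heteroscedastic = TRUE)
  m <- suppressWarnings(
    develop_model(fx$data, "knee_extensors", run_config(seed = 46),
                  profiles = fx$profiles))
  expect_false(m$diagnostics$criteria[[5]]$pass)
})

test_that("model comparison follows the selection rules", {
  fx <- constructed_ke_cohort(n = 60, seed = 47, noise_sd = 60)
  cfg <- run_config(seed = 47)
  base <- suppressWarnings(develop_model(fx$data, "knee_extensors", cfg,
                                         profiles = fx$profiles))
  # identical models: residual r = 1, tie broken by fewer predictors -> "a"
  cmp <- compare_models(base, base)
  expect_equal(cmp$residual_r, 1)
  expect_equal(cmp$selected, "a")

  # a failing copy loses to the passing model
  failing <- base
  failing$diagnostics$overall_pass <- FALSE
  expect_equal(compare_models(failing, base)$selected, "b")
  expect_equal(compare_models(failing, failing)$selected, "none")

  expect_error(compare_models(base, {
    b <- base
    b$fit$y <- b$fit$y + 1
    b
  }), "same development cases")
})

test_that("stage failures are labelled", {
  co <- hip_cohort(seed = 7, n = 18)
  expect_error(develop_model(co$subjects, "hip_extensors"),
               "stage criterion")
})
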