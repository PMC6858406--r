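test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n_subjects = 2), "n_subjects")
  expect_error(cohort_spec(slice_spacing = 0), "slice_spacing")
  m <- musclevol:::.default_measurements
  m$mass_kg$sd <- -1
  expect_error(cohort_spec(measurements = m), "mass_kg")
  g <- musclevol:::default_group_specs()
  g$hip_extensors$noise_sd <- -5
  expect_error(cohort_spec(groups = g), "hip_extensors")
  g <- musclevol:::default_group_specs()
  g$hip_extensors$predictor <- c("mass_kg", "nope")
  expect_error(cohort_spec(groups = g), "nope")
})

test_that("same seed reproduces the cohort bit-for-bit", {
  a <- generate_cohort(cohort_spec(n_subjects = 8, seed = 42,
                                   n_slices_range = c(5L, 9L)))
  b <- generate_cohort(cohort_spec(n_subjects = 8, seed = 42,
                                   n_slices_range = c(5L, 9L)))
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_spec(n_subjects = 8, seed = 43,
                                    n_slices_range = c(5L, 9L)))
  expect_false(identical(a$subjects, c_$subjects))
})

test_that("zero-noise cohorts sit exactly on the generating line", {
  g <- musclevol:::default_group_specs()
  for (nm in names(g)) g[[nm]]$noise_sd <- 0
  co <- generate_cohort(cohort_spec(n_subjects = 5, seed = 2, groups = g),
                        include_profiles = FALSE)
  for (nm in names(g)) {
    pred <- co$subjects[[g[[nm]]$predictor[1]]] *
      co$subjects[[g[[nm]]$predictor[2]]]
    expect_equal(co$latent_volumes[[nm]],
                 g[[nm]]$constant + g[[nm]]$slope * pred)
  }
  # refit on a larger zero-noise cohort gives R2 = 1
  co <- generate_cohort(cohort_spec(n_subjects = 40, seed = 3, groups = g),
                        include_profiles = FALSE)
  pred <- co$subjects$mass_kg * co$subjects$thigh_length_m
  expect_equal(fit_ols(co$latent_volumes$hip_extensors, pred)$r2, 1)
})

test_that("generated profiles integrate to the latent volume", {
  p <- generate_csa_profile(60, 12, 1.5, seed = 9)
  v <- compute_muscle_volume(p)$volume
  expect_gte(v, 59.94)
  expect_lte(v, 60.06)
  expect_true(all(p$csa >= 0))
  # plantarflexor group-mean case: 1252.0 cm^3, 40 slices at 1.5 cm
  p2 <- generate_csa_profile(1252.0, 40, 1.5, seed = 10)
  expect_lt(abs(compute_muscle_volume(p2)$volume - 1252.0), 1.3)
  # determinism and preconditions
  expect_identical(generate_csa_profile(60, 12, 1.5, seed = 9), p)
  expect_error(generate_csa_profile(60, 2, 1.5), "at least 3")
  expect_error(generate_csa_profile(-1, 10, 1.5), "positive")

  # cohort-level: per-muscle profiles sum to the group latent volume
  co <- generate_cohort(cohort_spec(n_subjects = 4, seed = 6,
                                    n_slices_range = c(5L, 9L)))
  for (g in muscle_groups()) {
    mv <- criterion_volumes(co, g)
    expect_equal(unname(mv), co$latent_volumes[[g]], tolerance = 1e-3)
  }
})

test_that("sample moments approach the spec at n = 10000", {
  co <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 4),
                        include_profiles = FALSE, include_session2 = FALSE)
  # closed-form SD of a +/- 3 SD truncated normal: the truncation deflates
  # the SD by the factor sqrt(1 - 6 phi(3) / (2 Phi(3) - 1)) ~ 0.9866
  trunc_factor <- sqrt(1 - 6 * dnorm(3) / (2 * pnorm(3) - 1))
  for (nm in names(musclevol:::.default_measurements)) {
    m <- musclevol:::.default_measurements[[nm]]
    expect_lt(abs(mean(co$subjects[[nm]]) - m$mean) / m$mean, 0.02)
    expect_lt(abs(sd(co$subjects[[nm]]) - m$sd * trunc_factor) / m$sd, 0.02)
  }
})

test_that("OLS refit recovers the generating parameters within 2 SE", {
  co <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 8),
                        include_profiles = FALSE, include_session2 = FALSE)
  for (g in muscle_groups()) {
    gs <- co$spec$groups[[g]]
    pred <- co$subjects[[gs$predictor[1]]] * co$subjects[[gs$predictor[2]]]
    f <- fit_ols(co$latent_volumes[[g]], pred)
    const <- f$coefficients[[1]]
    slope <- f$coefficients[[2]]
    expect_lt(abs(const$beta - gs$constant), 2 * const$se)
    expect_lt(abs(slope$beta - gs$slope), 2 * slope$se)
  }
})

test_that("session-2 replicates carry TEM-scaled error", {
  co <- generate_cohort(cohort_spec(n_subjects = 5000, seed = 12),
                        include_profiles = FALSE)
  for (nm in c("mt_ant50_cm", "csa_lg25_cm2")) {
    tem_true <- musclevol:::.default_measurements[[nm]]$tem
    r <- compute_tem(co$subjects[[nm]], co$session2[[nm]], nm)
    expect_lt(abs(r$tem_abs - tem_true) / tem_true, 0.05)
  }
})

test_that("cohort CSV round-trip and JSON spec input", {
  co <- generate_cohort(cohort_spec(n_subjects = 4, seed = 13,
                                    n_slices_range = c(5L, 7L)))
  path <- withr::local_tempfile(fileext = ".csv")
  dict <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path, dictionary_path = dict)
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), 8)  # 4 subjects x 2 sessions
  expect_equal(back$mass_kg[back$session == 1],
               co$subjects$mass_kg, tolerance = 1e-8)
  expect_true(file.exists(dict))

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_subjects": 6, "seed": 99,
               "groups": {"hip_extensors": {"noise_sd": 0}}}', js)
  spec <- cohort_spec_from_json(js)
  expect_equal(spec$n_subjects, 6L)
  expect_equal(spec$groups$hip_extensors$noise_sd, 0)
  expect_equal(spec$groups$knee_extensors$noise_sd, 121.10)
})

test_that("infeasible predictor correlation is rejected", {
  expect_error(generate_cohort(cohort_spec(predictor_correlation = 0.95)),
               "predictor_correlation")
})
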