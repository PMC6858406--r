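# shared fixtures built in code

# small hip-extensor cohort with profiles, default stated-world parameters
hip_cohort <- function(seed = 7, n = 18) {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed))
}

# a hand-constructed cohort (data.frame + profiles) whose knee-extensor
# volumes follow mv = const + slope * (mt * mass) + noise, with the noise
# optionally proportional to the predictor (planted heteroscedasticity)
constructed_ke_cohort <- function(n, seed, noise_sd = 50,
                                  heteroscedastic = FALSE) {
  set.seed(seed)
  mass <- rnorm(n, 78, 8)
  mt <- rnorm(n, 3.6, 0.4)
  pred <- mt * mass
  noise <- if (heteroscedastic) {
    rnorm(n, 0, noise_sd * (pred / mean(pred))^3)
  } else {
    rnorm(n, 0, noise_sd)
  }
  mv <- 996.168 + 4.664 * pred + noise
  mv <- pmax(mv, 50)
  df <- data.frame(
    subject_id = sprintf("C%04d", seq_len(n)), session = 1L,
    mass_kg = mass, height_m = rnorm(n, 1.81, 0.07),
    thigh_length_m = rnorm(n, 0.42, 0.04), mt_ant50_cm = mt,
    stringsAsFactors = FALSE)
  roster <- muscle_group_roster$knee_extensors
  profiles <- lapply(seq_len(n), function(i) {
    w <- rep(1 / length(roster), length(roster))
    ps <- lapply(seq_along(roster), function(mi) {
      generate_csa_profile(mv[i] * w[mi], n_slices = 5, spacing = 2,
                           seed = seed + 1000L * i + mi,
                           muscle = roster[mi])
    })
    names(ps) <- roster
    list(knee_extensors = ps)
  })
  names(profiles) <- df$subject_id
  list(data = df, profiles = profiles, mv = mv)
}
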