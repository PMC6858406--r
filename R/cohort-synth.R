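# Synthetic cohort generator.
#
# Emulates the statistical structure the volume-estimation analysis assumes:
# anthropometric and ultrasound measurements drawn from stated normal
# marginals (truncated at +/- 3 SD), latent group volumes generated as
# MV = constant + slope * predictor + Normal(0, noise_sd) from the published
# model parameters, session-2 replicates with Normal(0, TEM * sqrt(2)) error,
# and per-muscle axial CSA slice series whose trapezoidal integral equals the
# latent volume. Shape realism of the CSA series is a non-goal; integral
# correctness is the contract.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# deterministic sub-stream seed from a master seed and up to two indices;
# stays inside 32-bit integer range
derive_seed <- function(master, a = 0L, b = 0L) {
  x <- as.numeric(master) %% 2147483647
  x <- (x * 48271 + as.numeric(a) * 7919 + as.numeric(b) * 104729 + 12345) %%
    2147483647
  as.integer(x)
}

# measurement marginals: shared anthropometrics use the whole-sample
# characteristics; group-specific ultrasound measures and limb lengths use
# the development-group values of the table that characterizes them.
# shank_length_m and the gluteal MT are not characterized in the published
# tables; values here are chosen as typical for recreationally active adult
# males (see the methods vignette).
.default_measurements <- list(
  mass_kg        = list(mean = 79.8, sd = 10.9, tem = NA_real_),
  height_m       = list(mean = 1.81, sd = 0.07, tem = NA_real_),
  thigh_length_m = list(mean = 0.41, sd = 0.03, tem = NA_real_),
  shank_length_m = list(mean = 0.44, sd = 0.03, tem = NA_real_),
  mt_glut_cm     = list(mean = 3.0,  sd = 0.5,  tem = 0.10),
  mt_ant50_cm    = list(mean = 3.6,  sd = 0.4,  tem = 0.10),
  mt_bfsh75_cm   = list(mean = 2.9,  sd = 0.6,  tem = 0.006),
  csa_lg25_cm2   = list(mean = 8.6,  sd = 1.9,  tem = 0.24)
)

default_group_specs <- function() {
  lapply(.published_models, function(m) {
    list(predictor = m$predictor, constant = m$constant, slope = m$slope,
         noise_sd = m$see_abs,
         mv_mean = m$dev$mv_cm3[["mean"]], mv_sd = m$dev$mv_cm3[["sd"]])
  })
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the published model-development statistics: each
#' measurement's stated mean/SD, each group's published regression constant
#' and slope with residual noise equal to the published SEE, and the
#' published between-session TEMs for the ultrasound measurements. The
#' factors of each composite predictor are drawn independently by default;
#' `predictor_correlation` introduces correlation between the two factors of
#' every composite predictor via a joint normal draw.
#'
#' @param n_subjects Number of subjects (>= 3); default 18, the study size.
#' @param seed Master seed; all randomness derives from it.
#' @param predictor_correlation Correlation between the factors of each
#'   composite predictor, default 0 (independence).
#' @param n_slices_range Integer range of CSA slices per muscle profile.
#' @param slice_spacing Uniform inter-slice distance, cm (default 1.5, the
#'   analysis interval of the criterion volumes).
#' @param measurements Named list of `list(mean, sd, tem)` per measurement
#'   column; defaults as above.
#' @param groups Named list per muscle group of
#'   `list(predictor, constant, slope, noise_sd, mv_mean, mv_sd)`; defaults
#'   from the published registry.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18, seed = 1,
                        predictor_correlation = 0,
                        n_slices_range = c(30L, 50L), slice_spacing = 1.5,
                        measurements = .default_measurements,
                        groups = default_group_specs()) {
  if (!is.numeric(n_subjects) || n_subjects < 3) {
    stop("invalid field n_subjects: must be at least 3", call. = FALSE)
  }
  if (slice_spacing <= 0) {
    stop("invalid field slice_spacing: must be positive", call. = FALSE)
  }
  if (abs(predictor_correlation) >= 1) {
    stop("invalid field predictor_correlation: must be in (-1, 1)",
         call. = FALSE)
  }
  for (nm in names(measurements)) {
    if (measurements[[nm]]$sd < 0) {
      stop("invalid field measurements$", nm, "$sd: negative SD",
           call. = FALSE)
    }
  }
  for (g in names(groups)) {
    if (groups[[g]]$noise_sd < 0) {
      stop("invalid field groups$", g, "$noise_sd: negative SD",
           call. = FALSE)
    }
    miss <- setdiff(groups[[g]]$predictor, names(measurements))
    if (length(miss)) {
      stop("invalid field groups$", g, "$predictor: unknown measurement ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         predictor_correlation = predictor_correlation,
         n_slices_range = as.integer(n_slices_range),
         slice_spacing = slice_spacing,
         measurements = measurements, groups = groups),
    class = "cohort_spec")
}

# correlation matrix over measurement columns with rho between the two
# factors of each composite predictor
spec_cor_matrix <- function(spec) {
  cols <- names(spec$measurements)
  C <- diag(length(cols))
  dimnames(C) <- list(cols, cols)
  for (g in spec$groups) {
    pr <- g$predictor
    C[pr[1], pr[2]] <- C[pr[2], pr[1]] <- spec$predictor_correlation
  }
  C
}

#' Generate a synthetic cohort
#'
#' Draws subject measurements from the spec's truncated-normal marginals,
#' latent muscle-group volumes from the spec's linear models, optional
#' session-2 ultrasound replicates with TEM-scaled error, and optional
#' per-muscle CSA slice profiles whose trapezoidal integrals reproduce the
#' latent volumes (the group's latent volume is partitioned across its
#' roster muscles). Regenerating with the same seed reproduces the cohort
#' bit-for-bit.
#'
#' @param spec A [cohort_spec()].
#' @param include_profiles Generate CSA profiles (disable for very large
#'   cohorts where only the measurement table is needed).
#' @param include_session2 Generate session-2 ultrasound replicates.
#' @return Object of class `synthetic_cohort`: `spec`, `subjects`
#'   (data.frame, session 1), `session2` (data.frame or `NULL`),
#'   `latent_volumes` (data.frame, one column per group, cm^3), `profiles`
#'   (nested list `[[subject_id]][[group]][[muscle]]` of [csa_profile()]s,
#'   or `NULL`).
#' @export
generate_cohort <- function(spec, include_profiles = TRUE,
                            include_session2 = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  cols <- names(spec$measurements)
  means <- vapply(spec$measurements, `[[`, numeric(1), "mean")
  sds <- vapply(spec$measurements, `[[`, numeric(1), "sd")

  C <- spec_cor_matrix(spec)
  L <- tryCatch(chol(C), error = function(e) {
    stop("predictor_correlation makes the joint distribution invalid",
         call. = FALSE)
  })

  out <- with_seed(spec$seed, {
    # truncated joint-normal draws: redraw whole rows violating +/- 3 SD
    Z <- matrix(stats::rnorm(n * length(cols)), n) %*% L
    repeat {
      bad <- which(apply(abs(Z) > 3, 1, any))
      if (!length(bad)) break
      Z[bad, ] <- matrix(stats::rnorm(length(bad) * length(cols)),
                         length(bad)) %*% L
    }
    V <- sweep(sweep(Z, 2, sds, `*`), 2, means, `+`)
    colnames(V) <- cols
    subjects <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                           session = 1L, V, stringsAsFactors = FALSE)

    latent <- data.frame(subject_id = subjects$subject_id,
                         stringsAsFactors = FALSE)
    for (g in names(spec$groups)) {
      gs <- spec$groups[[g]]
      pred <- V[, gs$predictor[1]] * V[, gs$predictor[2]]
      mv <- gs$constant + gs$slope * pred +
        stats::rnorm(n, 0, gs$noise_sd)
      while (any(mv <= 0)) {
        i <- which(mv <= 0)
        mv[i] <- gs$constant + gs$slope * pred[i] +
          stats::rnorm(length(i), 0, gs$noise_sd)
      }
      latent[[g]] <- mv
    }

    session2 <- NULL
    if (include_session2) {
      session2 <- subjects
      session2$session <- 2L
      for (nm in cols) {
        tem <- spec$measurements[[nm]]$tem
        if (!is.na(tem)) {
          v2 <- subjects[[nm]] + stats::rnorm(n, 0, tem * sqrt(2))
          while (any(v2 <= 0)) {
            i <- which(v2 <= 0)
            v2[i] <- subjects[[nm]][i] + stats::rnorm(length(i), 0,
                                                      tem * sqrt(2))
          }
          session2[[nm]] <- v2
        }
      }
    }
    list(subjects = subjects, latent = latent, session2 = session2)
  })

  profiles <- NULL
  if (include_profiles) {
    profiles <- list()
    for (i in seq_len(n)) {
      sid <- out$subjects$subject_id[i]
      profiles[[sid]] <- list()
      for (gi in seq_along(spec$groups)) {
        g <- names(spec$groups)[gi]
        roster <- muscle_group_roster[[g]]
        profiles[[sid]][[g]] <- with_seed(derive_seed(spec$seed, i, gi), {
          # partition the group volume across roster muscles
          w <- stats::rgamma(length(roster), shape = 4)
          w <- w / sum(w)
          ps <- lapply(seq_along(roster), function(mi) {
            nsl <- sample(seq(spec$n_slices_range[1], spec$n_slices_range[2]),
                          1)
            generate_csa_profile(out$latent[[g]][i] * w[mi], nsl,
                                 spec$slice_spacing, muscle = roster[mi])
          })
          names(ps) <- roster
          ps
        })
      }
    }
  }

  structure(
    list(spec = spec, subjects = out$subjects, session2 = out$session2,
         latent_volumes = out$latent, profiles = profiles),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, seed %d, %d groups%s%s\n",
              x$spec$n_subjects, x$spec$seed, length(x$spec$groups),
              if (!is.null(x$session2)) ", session-2 replicates" else "",
              if (!is.null(x$profiles)) ", CSA profiles" else ""))
  invisible(x)
}

#' Generate one synthetic CSA slice profile
#'
#' A jittered parabolic envelope (zero CSA at both ends, as at a muscle's
#' origin and insertion) rescaled so that its trapezoidal integral equals
#' `latent_volume` exactly.
#'
#' @param latent_volume Target volume, cm^3 (> 0).
#' @param n_slices Number of slices (>= 3).
#' @param spacing Inter-slice distance, cm (> 0).
#' @param seed Optional seed for a self-contained deterministic draw; `NULL`
#'   uses the ambient RNG stream.
#' @param jitter Multiplicative slice jitter SD (default 0.05).
#' @param muscle Muscle name for the profile.
#' @return A [csa_profile()].
#' @export
generate_csa_profile <- function(latent_volume, n_slices, spacing,
                                 seed = NULL, jitter = 0.05,
                                 muscle = "muscle") {
  if (!is.numeric(latent_volume) || latent_volume <= 0) {
    stop("latent_volume must be positive", call. = FALSE)
  }
  if (n_slices < 3L) {
    stop("n_slices must be at least 3 for a non-degenerate profile",
         call. = FALSE)
  }
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  draw <- function() {
    x <- seq_len(n_slices) - 1
    env <- x * (n_slices - 1 - x)
    csa <- pmax(env * (1 + stats::rnorm(n_slices, 0, jitter)), 0)
    raw <- sum((csa[-n_slices] + csa[-1]) / 2) * spacing
    csa * latent_volume / raw
  }
  csa <- if (is.null(seed)) draw() else with_seed(seed, draw())
  csa_profile(csa, spacing, muscle = muscle)
}

#' Criterion muscle-group volumes from a cohort's CSA profiles
#'
#' Integrates every roster muscle's profile and sums within the group --
#' the criterion volume used by the model pipeline is always computed from
#' the slice series, never read from a stored field.
#'
#' @param profiles Nested profile list (`[[subject_id]][[group]][[muscle]]`),
#'   or a `synthetic_cohort`.
#' @param group One of `muscle_groups()`.
#' @return Named numeric vector of volumes (cm^3) indexed by subject id.
#' @export
criterion_volumes <- function(profiles, group) {
  match_group(group)
  if (inherits(profiles, "synthetic_cohort")) {
    if (is.null(profiles$profiles)) {
      stop("cohort was generated without profiles", call. = FALSE)
    }
    profiles <- profiles$profiles
  }
  vapply(profiles, function(subj) {
    ps <- subj[[group]]
    if (is.null(ps)) {
      stop("no profiles for group '", group, "'", call. = FALSE)
    }
    compute_group_volume(ps, group)$volume
  }, numeric(1))
}

# ---- CSV / JSON interchange -------------------------------------------------

#' Write a cohort measurement table to CSV
#'
#' One row per subject-session; columns `subject_id`, `session`, then the
#' measurement columns with units encoded in their names (`mass_kg`,
#' `thigh_length_m`, `mt_ant50_cm`, ...). Optionally writes a data
#' dictionary CSV describing every column.
#'
#' @param cohort A `synthetic_cohort` (or a plain data.frame already in the
#'   row format).
#' @param path Output CSV path.
#' @param dictionary_path Optional path for the data-dictionary CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, dictionary_path = NULL) {
  df <- if (inherits(cohort, "synthetic_cohort")) {
    rbind(cohort$subjects,
          if (!is.null(cohort$session2)) cohort$session2)
  } else {
    as.data.frame(cohort)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(dictionary_path)) {
    desc <- c(
      subject_id = "subject identifier",
      session = "measurement session (1 or 2)",
      mass_kg = "body mass, kilograms",
      height_m = "standing height, metres",
      thigh_length_m = "greater trochanter to lateral femoral epicondyle, m",
      shank_length_m = "lateral femoral epicondyle to lateral malleolus, m",
      mt_glut_cm = "gluteal muscle thickness at mid-hip, cm",
      mt_ant50_cm = "anterior thigh muscle thickness at 50% thigh length, cm",
      mt_bfsh75_cm =
        "biceps femoris short-head thickness at 75% thigh length, cm",
      csa_lg25_cm2 =
        "lateral gastrocnemius cross-sectional area at 25% shank length, cm^2"
    )
    dict <- data.frame(column = names(df),
                       description = unname(desc[names(df)]),
                       stringsAsFactors = FALSE)
    dict$description[is.na(dict$description)] <- "(undocumented)"
    utils::write.csv(dict, dictionary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort measurement table from CSV
#' @param path CSV path as written by [write_cohort_csv()].
#' @return data.frame with at least `subject_id` and `session` columns.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "session") %in% names(df))) {
    stop("cohort CSV must have subject_id and session columns",
         call. = FALSE)
  }
  df
}

#' Write a cohort's CSA profiles to a long-format CSV
#'
#' Columns: `subject_id`, `group`, `muscle`, `slice_index`, `csa_cm2`,
#' `spacing_cm` (the format read back by [read_profiles_csv()]).
#'
#' @param cohort A `synthetic_cohort` with profiles.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$profiles)) {
    stop("cohort was generated without profiles", call. = FALSE)
  }
  rows <- list()
  for (sid in names(cohort$profiles)) {
    for (g in names(cohort$profiles[[sid]])) {
      for (m in names(cohort$profiles[[sid]][[g]])) {
        p <- cohort$profiles[[sid]][[g]][[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, muscle = m,
          slice_index = seq_len(p$n), csa_cm2 = p$csa,
          spacing_cm = p$spacing, stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort spec from JSON
#'
#' Accepts a JSON object with any subset of the [cohort_spec()] arguments;
#' omitted entries keep their defaults. (YAML is not supported; configs are
#' JSON.)
#'
#' @param path JSON file path.
#' @return A [cohort_spec()].
#' @export
cohort_spec_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("n_subjects", "seed", "predictor_correlation",
               "n_slices_range", "slice_spacing")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$measurements)) {
    meas <- .default_measurements
    for (nm in names(raw$measurements)) {
      meas[[nm]] <- utils::modifyList(
        meas[[nm]] %||% list(mean = NA, sd = NA, tem = NA_real_),
        as.list(raw$measurements[[nm]]))
    }
    args$measurements <- meas
  }
  if (!is.null(raw$groups)) {
    grps <- default_group_specs()
    for (g in names(raw$groups)) {
      grps[[g]] <- utils::modifyList(grps[[g]] %||% list(),
                                     as.list(raw$groups[[g]]))
    }
    args$groups <- grps
  }
  do.call(cohort_spec, args)
}
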