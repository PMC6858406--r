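# Registry of the four published muscle-group volume prediction models and
# the muscle rosters that define each group.

#' Muscle group rosters
#'
#' Named list mapping each lower-limb muscle group to the individual muscles
#' whose volumes are summed to form the group criterion volume.
#'
#' @format Named list of character vectors.
#' @export
muscle_group_roster <- list(
  hip_extensors = c(
    "gluteus_maximus", "gluteus_medius", "biceps_femoris_long_head",
    "semimembranosus", "semitendinosus", "adductor_magnus"
  ),
  knee_extensors = c(
    "rectus_femoris", "vastus_intermedius", "vastus_lateralis",
    "vastus_medialis"
  ),
  knee_flexors = c(
    "semimembranosus", "semitendinosus", "biceps_femoris_long_head",
    "biceps_femoris_short_head", "medial_gastrocnemius",
    "lateral_gastrocnemius", "popliteus", "sartorius", "gracilis"
  ),
  ankle_plantarflexors = c(
    "medial_gastrocnemius", "lateral_gastrocnemius", "soleus", "peroneals",
    "tibialis_posterior", "flexor_digitorum_longus", "flexor_hallucis_longus"
  )
)

#' Names of the supported muscle groups
#' @return Character vector of the four group identifiers.
#' @export
muscle_groups <- function() names(muscle_group_roster)

# one coefficient row: point estimate, SE, 95% CI, p value
coef_row <- function(name, beta, se, ci_low, ci_high, p) {
  list(name = name, beta = beta, se = se,
       ci95_low = ci_low, ci95_high = ci_high, p_value = p)
}

# The four published prediction models.  Every number is transcribed from the
# development study's result tables; `predictor` names the two measurement
# columns whose product forms the single independent variable, in the units
# encoded in the column names (kg, m, cm, cm^2 -- the equations mix units, so
# the column naming convention is load-bearing).
.published_models <- list(
  hip_extensors = list(
    group = "hip_extensors",
    label = "Hip extensors",
    predictor = c("mass_kg", "thigh_length_m"),
    predictor_label = "body mass (kg) x thigh length (m)",
    constant = 1087.037,
    slope = 64.946,
    coefficients = list(
      coef_row("constant", 1087.037, 410.022, 193.676, 1980.398, 0.021),
      coef_row("mass_kg.thigh_length_m", 64.946, 12.554, 37.594, 92.298, 0.001)
    ),
    r2 = 0.690, adj_r2 = 0.665,
    see_abs = 283.01, see_pct = 8.92,
    cv_residual_abs = -347.32, cv_residual_pct = 11.28,
    dw = 1.67,
    ba_trend = list(r = 0.270, p = 0.295, systematic_error = FALSE),
    dev = list(
      n = 14L,
      height_m = c(mean = 1.78, sd = 0.05),
      mass_kg = c(mean = 77.8, sd = 9.7),
      thigh_length_m = c(mean = 0.41, sd = 0.03),
      mv_cm3 = c(mean = 3171.9, sd = 488.7)
    ),
    cv = list(n = 3L, mv_mean = 3078.8, mv_range = c(2810.1, 3513.3))
  ),
  knee_extensors = list(
    group = "knee_extensors",
    label = "Knee extensors",
    predictor = c("mt_ant50_cm", "mass_kg"),
    predictor_label =
      "anterior thigh muscle thickness at 50% thigh length (cm) x body mass (kg)",
    constant = 996.168,
    slope = 4.664,
    coefficients = list(
      coef_row("constant", 996.168, 257.349, 429.747, 1562.588, 0.003),
      coef_row("mt_ant50_cm.mass_kg", 4.664, 0.905, 2.673, 6.655, 0.001)
    ),
    r2 = 0.707, adj_r2 = 0.681,
    see_abs = 121.10, see_pct = 5.24,
    cv_residual_abs = 20.11, cv_residual_pct = 0.95,
    dw = 2.32,
    ba_trend = list(r = 0.340, p = 0.197, systematic_error = FALSE),
    dev = list(
      n = 13L,
      height_m = c(mean = 1.81, sd = 0.07),
      mass_kg = c(mean = 78.2, sd = 8.2),
      thigh_length_m = c(mean = 0.42, sd = 0.04),
      mt_ant50_cm = c(mean = 3.6, sd = 0.4),
      mv_cm3 = c(mean = 2311.6, sd = 214.3)
    ),
    cv = list(n = 3L, mv_mean = 2110.32, mv_range = c(1809.1, 2302.9)),
    tem = list(measurement = "mt_ant50_cm", abs = 0.1, pct = 2.0)
  ),
  knee_flexors = list(
    group = "knee_flexors",
    label = "Knee flexors",
    predictor = c("mt_bfsh75_cm", "thigh_length_m"),
    predictor_label = paste(
      "biceps femoris short-head muscle thickness at 75% thigh length (cm)",
      "x thigh length (m)"),
    constant = 1199.444,
    slope = 318.147,
    coefficients = list(
      coef_row("constant", 1199.444, 161.753, 843.428, 1555.461, 0.001),
      coef_row("mt_bfsh75_cm.thigh_length_m", 318.147, 128.860, 34.528,
               601.766, 0.031)
    ),
    r2 = 0.357, adj_r2 = 0.298,
    see_abs = 125.37, see_pct = 7.89,
    cv_residual_abs = -42.72, cv_residual_pct = -2.66,
    dw = 2.18,
    ba_trend = list(r = 0.595, p = 0.015, systematic_error = TRUE),
    dev = list(
      n = 13L,
      mass_kg = c(mean = 78.6, sd = 8.2),
      height_m = c(mean = 1.80, sd = 0.06),
      mt_bfsh75_cm = c(mean = 2.9, sd = 0.6),
      thigh_length_m = c(mean = 0.41, sd = 0.04),
      mv_cm3 = c(mean = 1589.5, sd = 149.6)
    ),
    cv = list(n = 3L, mv_mean = 1607.2, mv_range = c(1269.3, 1826.0)),
    # absolute TEM printed as 0.00 at 0.2% of a 2.9 cm mean; the unrounded
    # absolute value implied by the percentage is carried here
    tem = list(measurement = "mt_bfsh75_cm", abs = 0.006, pct = 0.2)
  ),
  ankle_plantarflexors = list(
    group = "ankle_plantarflexors",
    label = "Ankle plantarflexors",
    predictor = c("csa_lg25_cm2", "mass_kg"),
    predictor_label = paste(
      "lateral gastrocnemius cross-sectional area at 25% shank length (cm^2)",
      "x body mass (kg)"),
    constant = 878.606,
    slope = 0.553,
    coefficients = list(
      coef_row("constant", 878.606, 140.417, 572.662, 1184.549, 0.001),
      coef_row("csa_lg25_cm2.mass_kg", 0.553, 0.201, 0.115, 0.991, 0.018)
    ),
    r2 = 0.387, adj_r2 = 0.336,
    see_abs = 134.91, see_pct = 10.78,
    cv_residual_abs = 92.44, cv_residual_pct = 6.37,
    dw = 1.44,
    ba_trend = list(r = 0.619, p = 0.006, systematic_error = TRUE),
    dev = list(
      n = 14L,
      height_m = c(mean = 1.81, sd = 0.07),
      mass_kg = c(mean = 78.5, sd = 7.8),
      csa_lg25_cm2 = c(mean = 8.6, sd = 1.9),
      mv_cm3 = c(mean = 1252.0, sd = 165.5)
    ),
    cv = list(n = 4L, mv_mean = 1451.5, mv_range = c(1198.8, 1748.2)),
    tem = list(measurement = "csa_lg25_cm2", abs = 0.24, pct = 2.5)
  )
)

#' Published prediction model registry
#'
#' Returns the published regression model for one muscle group (or all four),
#' including coefficients with standard errors, 95% confidence intervals and
#' p values, fit statistics (R-squared, adjusted R-squared, SEE absolute and
#' as a percentage of the development-group mean), cross-validation residuals,
#' the Durbin-Watson statistic, difference-versus-mean agreement trend, and
#' the development and cross-validation group characteristics.
#'
#' @param group One of `muscle_groups()`, or `NULL` for the full registry.
#' @return A list describing the model(s).
#' @examples
#' published_model("hip_extensors")$slope  # 64.946
#' @export
published_model <- function(group = NULL) {
  if (is.null(group)) return(.published_models)
  match_group(group)
  .published_models[[group]]
}

# validate a group name, with a helpful error
match_group <- function(group) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% names(.published_models)) {
    stop("unknown muscle group '", paste(group, collapse = ","),
         "'; expected one of: ",
         paste(names(.published_models), collapse = ", "), call. = FALSE)
  }
  group
}

#' Internal-consistency statistics of the published models
#'
#' Recomputes, from the registry's transcribed values, the arithmetic
#' identities that tie the published fit statistics together:
#' `adj_r2 = 1 - SEE^2 / SD(MV)^2` (same residual-df convention),
#' `SEE% = 100 * SEE / mean(MV)` over the development group, and
#' `CV% = 100 * |mean CV residual| / mean(holdout MV)`.
#'
#' @param group One of `muscle_groups()`.
#' @return List with `adj_r2_from_see`, `see_pct_from_abs`,
#'   `cv_residual_pct_from_abs` and the registry values they should match.
#' @export
model_consistency <- function(group) {
  m <- published_model(match_group(group))
  list(
    group = group,
    adj_r2_from_see = 1 - m$see_abs^2 / m$dev$mv_cm3[["sd"]]^2,
    adj_r2_printed = m$adj_r2,
    see_pct_from_abs = 100 * m$see_abs / m$dev$mv_cm3[["mean"]],
    see_pct_printed = m$see_pct,
    cv_residual_pct_from_abs = 100 * abs(m$cv_residual_abs) / m$cv$mv_mean,
    cv_residual_pct_printed = abs(m$cv_residual_pct)
  )
}
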