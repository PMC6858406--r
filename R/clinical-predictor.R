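# Apply the published prediction equations to new measurements.

# crude unit plausibility bounds keyed by column-name suffix; the equations
# mix metres, centimetres and kilograms, so catching a cm-for-m slip matters
.unit_bounds <- list(
  `_m` = c(0.1, 2.5, "metres (did you supply centimetres?)"),
  `_kg` = c(20, 250, "kilograms"),
  `_cm` = c(0.2, 15, "centimetres"),
  `_cm2` = c(1, 120, "square centimetres")
)

check_measurement_units <- function(name, value) {
  if (!is.finite(value) || value <= 0) {
    stop("measurement '", name, "' must be a positive number", call. = FALSE)
  }
  for (suffix in names(.unit_bounds)) {
    if (endsWith(name, suffix)) {
      b <- .unit_bounds[[suffix]]
      if (value < as.numeric(b[1]) || value > as.numeric(b[2])) {
        stop("measurement '", name, "' = ", value,
             " is implausible; expected ", b[3], call. = FALSE)
      }
      return(invisible(TRUE))
    }
  }
  invisible(TRUE)
}

#' Estimate a muscle-group volume from the published equation
#'
#' Evaluates `constant + slope * (input1 * input2)` for the group's published
#' model and attaches a +/- 1 SEE uncertainty band (the published models
#' report the SEE, not prediction intervals). Inputs outside the
#' model-development range (mean +/- 3 SD of the development group) trigger
#' an extrapolation warning; the knee flexor and ankle plantarflexor models
#' carry a systematic-error caveat (their difference-versus-mean plots showed
#' a significant positive trend).
#'
#' @param group One of `muscle_groups()`.
#' @param measurements Named list/vector holding the group's two required
#'   inputs, named as in `published_model(group)$predictor` (units encoded in
#'   the names).
#' @param warn_extrapolation Emit a warning when extrapolating.
#' @return Object of class `prediction_result`: `group`, `estimate` (cm^3),
#'   `band_low`, `band_high` (estimate -/+ SEE), `inputs`, `extrapolation`
#'   (logical), `caveat` (`NULL` or a string).
#' @examples
#' estimate_volume("hip_extensors",
#'                 c(mass_kg = 80, thigh_length_m = 0.40))$estimate  # 3165.3
#' @export
estimate_volume <- function(group, measurements, warn_extrapolation = TRUE) {
  m <- published_model(match_group(group))
  measurements <- as.list(measurements)
  miss <- setdiff(m$predictor, names(measurements))
  if (length(miss)) {
    stop("missing measurement(s) for ", group, ": ",
         paste(miss, collapse = ", "),
         " (units are encoded in the names)", call. = FALSE)
  }
  vals <- vapply(m$predictor, function(nm) {
    v <- as.numeric(measurements[[nm]])
    check_measurement_units(nm, v)
    v
  }, numeric(1))

  extrap <- FALSE
  for (nm in m$predictor) {
    ref <- m$dev[[nm]]
    if (!is.null(ref)) {
      lo <- ref[["mean"]] - 3 * ref[["sd"]]
      hi <- ref[["mean"]] + 3 * ref[["sd"]]
      if (vals[[nm]] < lo || vals[[nm]] > hi) {
        extrap <- TRUE
        if (warn_extrapolation) {
          warning("input ", nm, " = ", vals[[nm]],
                  " lies outside the model-development range (",
                  signif(lo, 3), "-", signif(hi, 3),
                  "); estimate is an extrapolation", call. = FALSE)
        }
      }
    }
  }

  est <- m$constant + m$slope * prod(vals)
  caveat <- if (m$ba_trend$systematic_error) {
    paste0("the ", m$label, " model showed a significant proportional ",
           "(systematic) error trend in its agreement analysis; interpret ",
           "with caution")
  }
  structure(
    list(group = group, estimate = est,
         band_low = est - m$see_abs, band_high = est + m$see_abs,
         see_abs = m$see_abs,
         inputs = as.list(vals), extrapolation = extrap, caveat = caveat),
    class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s volume estimate: %.1f cm^3 (+/- 1 SEE: %.1f-%.1f)\n",
              published_model(x$group)$label, x$estimate, x$band_low,
              x$band_high))
  if (x$extrapolation) cat("  note: extrapolation beyond the development range\n")
  if (!is.null(x$caveat)) cat("  caveat:", x$caveat, "\n")
  invisible(x)
}

#' Is a hypothesized volume difference detectable by a model?
#'
#' An effect (percentage difference in group volume) is considered detectable
#' when it exceeds the model's SEE expressed as a percentage of the
#' development-group mean.
#'
#' @param group One of `muscle_groups()`.
#' @param effect_pct Hypothesized effect size, percent (> 0).
#' @return List: `group`, `effect_pct`, `see_pct`, `detectable`, `margin`
#'   (`effect_pct - see_pct`).
#' @examples
#' sensitivity_check("knee_extensors", 5.60)$detectable  # TRUE
#' @export
sensitivity_check <- function(group, effect_pct) {
  m <- published_model(match_group(group))
  if (!is.numeric(effect_pct) || effect_pct <= 0) {
    stop("effect_pct must be positive", call. = FALSE)
  }
  list(group = group, effect_pct = effect_pct, see_pct = m$see_pct,
       detectable = effect_pct > m$see_pct,
       margin = effect_pct - m$see_pct)
}
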