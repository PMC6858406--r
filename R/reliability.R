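# Between-session measurement reliability as the typical error of
# measurement: TEM = SD(differences) / sqrt(2), with the percentage taken
# against the mean of the *first* session by convention.

#' Typical error of measurement between two sessions
#'
#' `tem_abs` is the sample standard deviation (n - 1 denominator) of the
#' paired session differences divided by sqrt(2); `tem_pct` expresses it as a
#' percentage of the session-1 mean. The sample SD is used because reliability
#' sub-studies are often tiny (here as small as two participants), where the
#' population SD is degenerate.
#'
#' Swapping the sessions leaves `tem_abs` unchanged; `tem_pct` changes only
#' through its denominator, an intentional asymmetry of the first-measurement
#' convention.
#'
#' @param session1,session2 Paired numeric vectors, same subjects, same order.
#' @param measurement Optional measurement name carried into the result.
#' @return Object of class `tem_result`: `measurement`, `tem_abs` (measurement
#'   units), `tem_pct` (%), `n_pairs`. If the session-1 mean is zero,
#'   `tem_pct` is `NA` and `pct_undefined` is `TRUE`.
#' @examples
#' compute_tem(c(10, 11, 12), c(10, 11, 12))$tem_abs  # 0
#' @export
compute_tem <- function(session1, session2, measurement = "measurement") {
  if (length(session1) != length(session2)) {
    stop("sessions must have equal length (paired by subject)", call. = FALSE)
  }
  if (length(session1) < 2L) {
    stop("at least 2 pairs required", call. = FALSE)
  }
  if (anyNA(session1) || anyNA(session2)) {
    stop("sessions must not contain NA", call. = FALSE)
  }
  d <- session1 - session2
  tem_abs <- stats::sd(d) / sqrt(2)
  m1 <- mean(session1)
  pct_undefined <- m1 == 0
  tem_pct <- if (pct_undefined) NA_real_ else 100 * tem_abs / m1
  structure(
    list(measurement = measurement, tem_abs = tem_abs, tem_pct = tem_pct,
         n_pairs = length(d), pct_undefined = pct_undefined),
    class = "tem_result")
}

#' @export
print.tem_result <- function(x, ...) {
  pct <- if (isTRUE(x$pct_undefined)) "undefined (zero session-1 mean)"
         else sprintf("%.2f%%", x$tem_pct)
  cat(sprintf("TEM for %s: %.4g (%s), n = %d pairs\n",
              x$measurement, x$tem_abs, pct, x$n_pairs))
  invisible(x)
}
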