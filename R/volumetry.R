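# Criterion muscle volume from serial axial cross-sectional areas.
#
# Volume is the trapezoidal sum over adjacent slices,
#   MV = sum_{i=1..n-1} (CSA_i + CSA_{i+1}) / 2 * h,
# with CSA in cm^2, uniform inter-slice distance h in cm, giving cm^3.

#' Construct a CSA profile
#'
#' An ordered series of axial cross-sectional areas for one muscle, with a
#' uniform inter-slice distance. Slices with zero CSA are legal (muscle
#' origin/insertion); negative CSA is not.
#'
#' @param csa Numeric vector of cross-sectional areas, cm^2, in anatomical
#'   order along the limb.
#' @param spacing Inter-slice distance h, cm (single positive number).
#' @param muscle Optional muscle name.
#' @return Object of class `csa_profile`.
#' @export
csa_profile <- function(csa, spacing, muscle = "muscle") {
  csa <- as.numeric(csa)
  if (length(csa) < 2L) stop("at least two slices required", call. = FALSE)
  if (anyNA(csa)) stop("CSA values must not contain NA", call. = FALSE)
  if (any(csa < 0)) stop("negative CSA not allowed", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("spacing must be a single positive number (cm)", call. = FALSE)
  }
  structure(
    list(muscle = as.character(muscle), csa = csa, spacing = spacing,
         n = length(csa)),
    class = "csa_profile")
}

#' @export
print.csa_profile <- function(x, ...) {
  cat(sprintf("CSA profile: %s, %d slices at %.3g cm, volume %.2f cm^3\n",
              x$muscle, x$n, x$spacing, compute_muscle_volume(x)$volume))
  invisible(x)
}

#' Trapezoidal muscle volume from a CSA profile
#'
#' @param profile A [csa_profile()].
#' @return List of class `muscle_volume` with `muscle` and `volume` (cm^3).
#' @examples
#' p <- csa_profile(rep(10, 5), spacing = 1.5)
#' compute_muscle_volume(p)$volume  # 60
#' @export
compute_muscle_volume <- function(profile) {
  if (!inherits(profile, "csa_profile")) {
    profile <- csa_profile(profile$csa, profile$spacing,
                           profile$muscle %||% "muscle")
  }
  csa <- profile$csa
  n <- length(csa)
  vol <- sum((csa[-n] + csa[-1]) / 2) * profile$spacing
  structure(list(muscle = profile$muscle, volume = vol),
            class = "muscle_volume")
}

#' Muscle-group volume as the sum of member muscle volumes
#'
#' Each member must belong to the named group's roster
#' (see [muscle_group_roster]). The sum is permutation-invariant.
#'
#' @param volumes List of `muscle_volume` results (or of [csa_profile()]s,
#'   which are integrated first).
#' @param group One of `muscle_groups()`.
#' @return `muscle_volume` with `muscle` set to the group name.
#' @export
compute_group_volume <- function(volumes, group) {
  match_group(group)
  if (length(volumes) == 0L) {
    stop("empty muscle list for group '", group, "'", call. = FALSE)
  }
  roster <- muscle_group_roster[[group]]
  vols <- vapply(volumes, function(v) {
    if (inherits(v, "csa_profile")) v <- compute_muscle_volume(v)
    if (!v$muscle %in% roster) {
      stop("muscle '", v$muscle, "' is not in the ", group, " roster",
           call. = FALSE)
    }
    v$volume
  }, numeric(1))
  structure(list(muscle = group, volume = sum(vols)),
            class = "muscle_volume")
}

#' Read CSA profiles from a long-format CSV
#'
#' Expects columns `subject_id`, `group`, `muscle`, `slice_index`, `csa_cm2`,
#' `spacing_cm` (the format written by [write_profiles_csv()]). Spacing must
#' be uniform within a profile; non-uniform spacing is rejected rather than
#' averaged.
#'
#' @param path CSV file path.
#' @return Nested list: `profiles[[subject_id]][[group]][[muscle]]`, each a
#'   [csa_profile()].
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "muscle", "slice_index", "csa_cm2",
            "spacing_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("profile CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (key in split(df, interaction(df$subject_id, df$group, df$muscle,
                                    drop = TRUE))) {
    key <- key[order(key$slice_index), , drop = FALSE]
    sp <- unique(key$spacing_cm)
    if (length(sp) != 1L) {
      stop("non-uniform spacing for subject ", key$subject_id[1], " muscle ",
           key$muscle[1], call. = FALSE)
    }
    sid <- as.character(key$subject_id[1])
    grp <- key$group[1]
    out[[sid]][[grp]][[key$muscle[1]]] <-
      csa_profile(key$csa_cm2, sp, muscle = key$muscle[1])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
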