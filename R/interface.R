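# Command-line entry point shared by all stages.
#
# Subcommands: simulate | volume | tem | develop | estimate.
# Invoke from a script as:  musclevol::run_cli()  (reads commandArgs()).

# parse "--key value" pairs after the subcommand; bare "--flag" => TRUE
parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument '", a, "'", call. = FALSE)
    }
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_require <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss)) {
    stop("missing required option(s): ",
         paste0("--", gsub("_", "-", miss), collapse = ", "), call. = FALSE)
  }
}

cli_usage <- function() {
  paste(
    "usage: musclevol <subcommand> [options]",
    "subcommands:",
    "  simulate --seed <int> --out <cohort.csv> [--n <int>]",
    "           [--spec <spec.json>] [--profiles-out <profiles.csv>]",
    "           [--dictionary-out <dict.csv>]",
    "  volume   --profiles <profiles.csv> --group <name>",
    "  tem      --cohort <cohort.csv> --measurement <column>",
    "  develop  --cohort <cohort.csv> --profiles <profiles.csv>",
    "           --group <name> --seed <int> [--config <config.json>]",
    "           [--out <report.json>]",
    "  estimate --group <name> --<measurement> <value> ... [--json]",
    sep = "\n")
}

#' Run the command-line interface
#'
#' Dispatches one of the subcommands `simulate`, `volume`, `tem`, `develop`,
#' `estimate`. All randomness flows from the `--seed` option. Errors print a
#' stage-labelled message to stderr and yield a nonzero status.
#'
#' @param argv Character vector of arguments; defaults to the process
#'   command line.
#' @return Integer exit status, invisibly (0 on success).
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L) {
      cat(cli_usage(), "\n")
      return(invisible(1L))
    }
    sub <- argv[1]
    opts <- parse_cli_args(argv[-1])
    switch(sub,
      simulate = cli_simulate(opts),
      volume = cli_volume(opts),
      tem = cli_tem(opts),
      develop = cli_develop(opts),
      estimate = cli_estimate(opts),
      stop("unknown subcommand '", sub, "'\n", cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_simulate <- function(opts) {
  cli_require(opts, c("seed", "out"))
  spec <- if (!is.null(opts$spec)) cohort_spec_from_json(opts$spec)
          else cohort_spec()
  spec$seed <- as.integer(opts$seed)
  if (!is.null(opts$n)) spec$n_subjects <- as.integer(opts$n)
  cohort <- generate_cohort(spec,
                            include_profiles = !is.null(opts$profiles_out))
  write_cohort_csv(cohort, opts$out,
                   dictionary_path = opts$dictionary_out)
  if (!is.null(opts$profiles_out)) {
    write_profiles_csv(cohort, opts$profiles_out)
  }
  cat("wrote", opts$out,
      if (!is.null(opts$profiles_out)) paste("and", opts$profiles_out),
      "\n")
}

cli_volume <- function(opts) {
  cli_require(opts, c("profiles", "group"))
  profs <- read_profiles_csv(opts$profiles)
  vols <- criterion_volumes(profs, opts$group)
  cat(jsonlite::toJSON(
    list(group = opts$group,
         volumes_cm3 = as.list(vols),
         mean_cm3 = mean(vols), sd_cm3 = stats::sd(vols)),
    auto_unbox = TRUE, digits = 6, pretty = TRUE), "\n")
}

cli_tem <- function(opts) {
  cli_require(opts, c("cohort", "measurement"))
  df <- read_cohort_csv(opts$cohort)
  col <- opts$measurement
  if (!col %in% names(df)) {
    stop("measurement column '", col, "' not in cohort CSV", call. = FALSE)
  }
  s1 <- df[df$session == 1L, ]
  s2 <- df[df$session == 2L, ]
  if (nrow(s2) == 0L) {
    stop("cohort CSV has no session-2 rows; TEM needs paired sessions",
         call. = FALSE)
  }
  s2 <- s2[match(s1$subject_id, s2$subject_id), ]
  tem <- compute_tem(s1[[col]], s2[[col]], measurement = col)
  cat(jsonlite::toJSON(unclass(tem), auto_unbox = TRUE, digits = 6,
                       pretty = TRUE), "\n")
}

cli_develop <- function(opts) {
  cli_require(opts, c("cohort", "profiles", "group", "seed"))
  cfg <- if (!is.null(opts$config)) run_config_from_json(opts$config)
         else run_config()
  cfg$seed <- as.integer(opts$seed)
  df <- read_cohort_csv(opts$cohort)
  profs <- read_profiles_csv(opts$profiles)
  model <- develop_model(df, opts$group, config = cfg, profiles = profs)
  js <- model_report_json(model, path = opts$out)
  if (is.null(opts$out)) cat(js, "\n") else cat("wrote", opts$out, "\n")
}

cli_estimate <- function(opts) {
  cli_require(opts, "group")
  json_out <- isTRUE(opts$json)
  meas <- opts[setdiff(names(opts), c("group", "json"))]
  meas <- lapply(meas, as.numeric)
  res <- estimate_volume(opts$group, meas)
  if (json_out) {
    cat(jsonlite::toJSON(unclass(res), auto_unbox = TRUE, digits = 6,
                         pretty = TRUE), "\n")
  } else {
    print(res)
  }
}
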