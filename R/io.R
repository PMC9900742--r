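trial_log_cols <- c("trial", "source", "direction", "start_mm",
                    "start_speed_mm_s", "stim_mm", "stim_speed_mm_s",
                    "response", "alpha_hat_mm", "beta_hat_mm")

#' Write / read a trial log
#'
#' One row per trial, comma-separated, UTF-8, '.' decimal, header row
#' mandatory. Columns: `trial`, `source`, `direction`, `start_mm`,
#' `start_speed_mm_s`, `stim_mm`, `stim_speed_mm_s`, `response`,
#' `alpha_hat_mm`, `beta_hat_mm`. All positions are mm (baseline-corrected)
#' and all speeds mm/s; units live in the column names, never in the cells.
#'
#' @param trials A trial tibble (e.g. `run_session(...)$trials`).
#' @param path File path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns the trial tibble.
#' @export
write_trial_log <- function(trials, path) {
  missing <- setdiff(trial_log_cols, names(trials))
  if (length(missing) > 0) {
    stop("trial log lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[, trial_log_cols], path)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no trial log at ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trial = readr::col_integer(),
                           source = readr::col_character(),
                           direction = readr::col_character(),
                           start_mm = readr::col_double(),
                           start_speed_mm_s = readr::col_double(),
                           stim_mm = readr::col_double(),
                           stim_speed_mm_s = readr::col_double(),
                           response = readr::col_character(),
                           alpha_hat_mm = readr::col_double(),
                           beta_hat_mm = readr::col_double()
                         ))
  missing <- setdiff(trial_log_cols, names(out))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing trial-log column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!out$response %in% response_levels())
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid `response` at row %d (must be 'left'/'right')",
                 path, bad[1]), call. = FALSE)
  }
  out
}

estimates_cols <- c("participant_id", "pse_test1_mm", "pse_test2_mm",
                    "unc_test1_mm", "unc_test2_mm")

#' Write / read a participant-estimates table
#'
#' Columns: `participant_id`, `pse_test1_mm`, `pse_test2_mm`,
#' `unc_test1_mm`, `unc_test2_mm` — the final PSE and uncertainty estimates
#' from the two test administrations.
#'
#' @param estimates Estimates tibble.
#' @param path File path.
#' @return `write_estimates` returns `path` invisibly; `read_estimates`
#'   returns the tibble.
#' @export
write_estimates <- function(estimates, path) {
  missing <- setdiff(estimates_cols, names(estimates))
  if (length(missing) > 0) {
    stop("estimates table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(estimates[, estimates_cols], path)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("no estimates table at ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           .default = readr::col_double()
                         ))
  missing <- setdiff(estimates_cols, names(out))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing estimates column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(out$unc_test1_mm <= 0 | out$unc_test2_mm <= 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: non-positive uncertainty at row %d", path, bad[1]),
         call. = FALSE)
  }
  out
}

#' Write / read a session configuration file
#'
#' Flat `key = value` text format, one field per line; `#` starts a
#' comment. Vector-valued fields are comma-separated. Unknown keys are
#' rejected so typos cannot silently fall back to defaults. The parameter
#' grid is encoded by its bounds and step (`alpha_min/max/step`,
#' `beta_min/max/step`), and the stimulus set by its values.
#'
#' @param config A [session_config()].
#' @param path File path.
#' @return `write_session_config` returns `path` invisibly;
#'   `read_session_config` returns a [session_config()].
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  g <- config$grid
  astep <- if (length(g$alpha) > 1) g$alpha[2] - g$alpha[1] else 1
  bstep <- if (length(g$beta) > 1) g$beta[2] - g$beta[1] else 1
  num <- function(x) paste(format(x, scientific = FALSE, trim = TRUE), collapse = ", ")
  lines <- c(
    "# propsi session configuration",
    sprintf("n_trials = %d", config$n_trials),
    sprintf("stimuli = %s", num(as.numeric(config$stimuli))),
    sprintf("alpha_min = %s", num(min(g$alpha))),
    sprintf("alpha_max = %s", num(max(g$alpha))),
    sprintf("alpha_step = %s", num(astep)),
    sprintf("beta_min = %s", num(min(g$beta))),
    sprintf("beta_max = %s", num(max(g$beta))),
    sprintf("beta_step = %s", num(bstep)),
    sprintf("start_center = %s", num(config$start_center)),
    sprintf("start_sd = %s", num(config$start_sd)),
    sprintf("start_speed_range = %s", num(config$start_speed_range)),
    sprintf("stimulus_speed_range = %s", num(config$stimulus_speed_range)),
    sprintf("far_period = %d", config$far_period),
    sprintf("near_period = %d", config$near_period),
    sprintf("preselect_warmup = %d", config$preselect_warmup),
    sprintf("break_trials = %s", num(config$break_trials)),
    sprintf("baseline_offset = %s", num(config$baseline_offset)),
    sprintf("n_front_starts = %d", config$n_front_starts),
    sprintf("pause_range = %s", num(config$pause_range)),
    sprintf("seed = %d", config$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

session_config_keys <- c(
  "n_trials", "stimuli", "alpha_min", "alpha_max", "alpha_step",
  "beta_min", "beta_max", "beta_step", "start_center", "start_sd",
  "start_speed_range", "stimulus_speed_range", "far_period", "near_period",
  "preselect_warmup", "break_trials", "baseline_offset", "n_front_starts",
  "pause_range", "seed"
)

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop("no config file at ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad) > 0) {
    stop(sprintf("%s: cannot parse line '%s'", path, lines[bad[1]]), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  unknown <- setdiff(keys, session_config_keys)
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown configuration key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop(sprintf("%s: duplicated key '%s'", path, keys[duplicated(keys)][1]),
         call. = FALSE)
  }
  get_num <- function(key, default) {
    if (!key %in% keys) return(default)
    as.numeric(strsplit(vals[match(key, keys)], ",", fixed = TRUE)[[1]])
  }
  grid <- psi_grid(
    alpha = seq(get_num("alpha_min", -100), get_num("alpha_max", 100),
                by = get_num("alpha_step", 1)),
    beta = seq(get_num("beta_min", 1), get_num("beta_max", 60),
               by = get_num("beta_step", 0.5))
  )
  n_trials <- as.integer(get_num("n_trials", 75))
  session_config(
    n_trials = n_trials,
    stimuli = stimulus_set(get_num("stimuli", seq(-100, 100, 10))),
    grid = grid,
    start_center = get_num("start_center", 100),
    start_sd = get_num("start_sd", 5),
    start_speed_range = get_num("start_speed_range", c(40, 50)),
    stimulus_speed_range = get_num("stimulus_speed_range", c(10, 30)),
    far_period = as.integer(get_num("far_period", 10)),
    near_period = as.integer(get_num("near_period", 5)),
    preselect_warmup = as.integer(get_num("preselect_warmup", 5)),
    break_trials = as.integer(get_num("break_trials", c(25, 50))),
    baseline_offset = get_num("baseline_offset", 0),
    n_front_starts = if ("n_front_starts" %in% keys)
      as.integer(get_num("n_front_starts", NA)) else NULL,
    pause_range = get_num("pause_range", c(0, 2)),
    seed = as.integer(get_num("seed", 1))
  )
}

#' Run manifest
#'
#' Records what produced a set of outputs: the command, a configuration
#' snapshot, all seeds, the package version, a timestamp, and the output
#' paths. Re-running the recorded command with the recorded seeds
#' regenerates the outputs exactly.
#'
#' @param command Character command name.
#' @param config A named list snapshot of the configuration.
#' @param seeds Named list/vector of seeds.
#' @param outputs Character vector of output paths.
#' @param path Optional path; when given the manifest JSON is written there.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(command, config = list(), seeds = list(),
                         outputs = character(0), path = NULL) {
  manifest <- list(
    command = command,
    config = config,
    seeds = seeds,
    package = "propsi",
    version = as.character(utils::packageVersion("propsi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(manifest))
  }
  manifest
}
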