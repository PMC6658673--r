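#' Write spike trains to CSV
#'
#' Schema: columns `trial_id`, `segment_label`, `spike_time_s` (header row,
#' UTF-8), one row per spike.
#'
#' @param trains a [spike_train()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- lapply(trains, function(tr) {
    if (!inherits(tr, "spike_train"))
      abort_invalid("`trains` must contain spike_train objects")
    if (length(tr$times) == 0) return(NULL)
    data.frame(trial_id = tr$trial_id, segment_label = tr$segment_label,
               spike_time_s = tr$times)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(trial_id = character(), segment_label = character(),
                     spike_time_s = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' Reads the schema written by [write_spike_csv()] and splits rows into one
#' [spike_train()] per `trial_id` (order of first appearance). Malformed
#' rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param duration segment duration in seconds (spike times must fall in
#'   `[0, duration)`).
#' @return list of [spike_train()] objects.
#' @export
read_spike_csv <- function(path, duration) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "segment_label", "spike_time_s")
  if (!all(need %in% names(df)))
    abort_invalid(sprintf("%s must have columns %s", path,
                          paste(need, collapse = ", ")))
  t_num <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(is.na(t_num) | t_num < 0 | t_num >= duration)
  if (length(bad))
    abort_invalid(sprintf(
      "malformed spike_time_s in %s at line(s) %s (header is line 1)",
      path, paste(bad + 1L, collapse = ", ")))
  df$spike_time_s <- t_num
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    d <- df[df$trial_id == id, ]
    spike_train(d$spike_time_s, duration, trial_id = as.character(id),
                segment_label = as.character(d$segment_label[1]))
  })
}

#' Write a stimulus series to CSV
#'
#' Schema: `frame_index` (1-based), `time_s` (frame onset), `luminance`.
#'
#' @param stim a [stimulus_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_csv <- function(stim, path) {
  if (!inherits(stim, "stimulus_series"))
    abort_invalid("`stim` must be a stimulus_series")
  n <- length(stim$values)
  write.csv(data.frame(frame_index = seq_len(n),
                       time_s = (seq_len(n) - 1) / stim$frame_rate,
                       luminance = stim$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus series from CSV
#'
#' @param path CSV written by [write_stimulus_csv()].
#' @return a [stimulus_series()] (frame rate inferred from `time_s`).
#' @export
read_stimulus_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame_index", "time_s", "luminance")
  if (!all(need %in% names(df)))
    abort_invalid(sprintf("%s must have columns %s", path,
                          paste(need, collapse = ", ")))
  fr <- if (nrow(df) > 1) 1 / mean(diff(df$time_s)) else 1
  stimulus_series(df$luminance, fr)
}

#' Write a rate or PCC series to CSV
#'
#' Schema: `time_s`, `value`, `flag` (`"ok"` or `"undefined"` for windows
#' where estimation failed or variance was zero).
#'
#' @param series a [rate_series()] or `pcc_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (!inherits(series, "rate_series") && !inherits(series, "pcc_series"))
    abort_invalid("`series` must be a rate_series or pcc_series")
  write.csv(data.frame(time_s = series$times, value = series$values,
                       flag = ifelse(is.na(series$values), "undefined", "ok")),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize an entropy-rate estimate to JSON
#'
#' Fields: `method`, `rate_bits_per_s`, `rate_bits_per_symbol`, `L_used`,
#' `slope`, `intercept`, `rms_residual`.
#'
#' @param est an `itr_estimate`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(est, path) {
  if (!inherits(est, "itr_estimate"))
    abort_invalid("`est` must be an itr_estimate")
  jsonlite::write_json(
    list(method = est$method,
         rate_bits_per_s = est$rate_per_second,
         rate_bits_per_symbol = est$rate_per_symbol,
         L_used = est$L_used,
         slope = est$fit_slope,
         intercept = est$fit_intercept,
         rms_residual = est$rms_residual),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Default run configuration
#'
#' The defaults of the analysis pipeline: encoding bin 12.5 ms (f = 80
#' bins/s), moving window T = 5 s, stride of one bin, block lengths 1..10
#' before the undersampling guard, 0.25-s PCC window, an RU protocol of
#' 128 repeat + 128 unique 8-s segments at 160 frames/s, and one OFF
#' rate-code cell plus one ON temporal-code cell.
#'
#' @param seed base RNG seed recorded in the config.
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(
    list(seed = as.integer(seed),
         frame_rate = 160,
         encoding = list(bin_width = 0.0125, window_T = 5, stride = 0.0125,
                         L_max = 10),
         pcc_window = 0.25,
         protocol = list(pattern = "RU", segment_duration = 8,
                         n_repeat_trials = 128, n_unique_trials = 128),
         cells = list(
           list(id = "OFF1", polarity = "OFF", regime = "rate_code",
                mean_rate = 5, gain = 6, spot_size = 2, refractory = 0.001),
           list(id = "ON1", polarity = "ON", regime = "temporal_code",
                mean_rate = 15, gain = 5, spot_size = 2,
                refractory = 0.001))),
    class = "run_config")
}

config_required <- list(
  seed = NULL, frame_rate = NULL,
  encoding = c("bin_width", "window_T", "stride", "L_max"),
  pcc_window = NULL,
  protocol = c("pattern", "segment_duration", "n_repeat_trials",
               "n_unique_trials"),
  cells = NULL)

validate_config <- function(config) {
  for (field in names(config_required)) {
    if (is.null(config[[field]]))
      abort_invalid(sprintf("config is missing field `%s`", field))
    for (sub in config_required[[field]]) {
      if (is.null(config[[field]][[sub]]))
        abort_invalid(sprintf("config is missing field `%s$%s`", field, sub))
    }
  }
  cell_need <- c("id", "polarity", "regime", "mean_rate", "gain",
                 "spot_size", "refractory")
  for (i in seq_along(config$cells)) {
    for (sub in cell_need) {
      if (is.null(config$cells[[i]][[sub]]))
        abort_invalid(sprintf("config is missing field `cells[[%d]]$%s`",
                              i, sub))
    }
  }
  structure(config, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Validates that every required field is present (errors name the missing
#' field).
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
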