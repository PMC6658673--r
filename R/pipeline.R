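cell_spec_from_config <- function(cc) {
  cell_spec(polarity = cc$polarity, regime = cc$regime,
            mean_rate = cc$mean_rate, gain = cc$gain,
            spot_size = cc$spot_size, refractory = cc$refractory,
            integration = cc$integration %||% 0.3)
}

protocol_from_config <- function(pc) {
  trial_protocol(pattern = pc$pattern,
                 segment_duration = pc$segment_duration,
                 n_repeat_trials = pc$n_repeat_trials,
                 n_unique_trials = pc$n_unique_trials)
}

# Simulate segments of one cell under the protocol; returns a list of
# spike_train with trial_id/segment_label filled in. Restricting `labels`
# skips the other segments without touching the RNG draws of the kept ones
# (each segment derives its own seed from its schedule position).
simulate_cell_trials <- function(spec, protocol, frame_rate, seed,
                                 labels = c("R", "U")) {
  stimuli <- gen_trial_stimuli(protocol, frame_rate, seed)
  keep <- which(vapply(stimuli, `[[`, character(1), "label") %in% labels)
  lapply(keep, function(j) {
    tr <- simulate_cell(spec, stimuli[[j]]$stimulus,
                        seed = derive_seed(seed, 100, j))
    tr$trial_id <- sprintf("trial%03d", j)
    tr$segment_label <- stimuli[[j]]$label
    tr
  })
}

#' Simulate a full experiment to disk
#'
#' Generates, for every cell in the configuration, the stimulus schedule of
#' the trial protocol and one spike train per segment, writing per-cell
#' spike CSVs, the frozen repeat-segment stimulus CSV, and a manifest JSON
#' (config hash, seeds, package version). Deterministic: rerunning with the
#' same configuration reproduces the files byte for byte.
#'
#' @param config a `run_config` (list, see [default_run_config()]) or a
#'   path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `spike_files` (named by cell id),
#'   `stimulus_file` and `manifest_file`.
#' @export
run_simulate <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(errorCondition(sprintf("cannot create output directory %s", out_dir),
                        class = c("spikecode_io_error", "spikecode_error")))
  protocol <- protocol_from_config(config$protocol)
  repeat_stim <- gen_luminance(config$frame_rate, protocol$segment_duration,
                               seed = derive_seed(config$seed, 0))
  stim_file <- file.path(out_dir, "repeat_stimulus.csv")
  write_stimulus_csv(repeat_stim, stim_file)
  spike_files <- character(0)
  for (i in seq_along(config$cells)) {
    cc <- config$cells[[i]]
    trains <- simulate_cell_trials(cell_spec_from_config(cc), protocol,
                                   config$frame_rate,
                                   seed = derive_seed(config$seed, i))
    f <- file.path(out_dir, sprintf("%s_spikes.csv", cc$id))
    write_spike_csv(trains, f)
    spike_files[cc$id] <- f
  }
  cfg_file <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_file)
  manifest <- list(
    package = "spikecode",
    version = as.character(packageVersion("spikecode")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    cell_seeds = lapply(seq_along(config$cells), function(i)
      derive_seed(config$seed, i)),
    files = c(unname(spike_files), stim_file))
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(spike_files = spike_files, stimulus_file = stim_file,
                 manifest_file = manifest_file))
}

# Core per-cell analysis shared by run_analyze and run_study.
analyze_trains <- function(trains, config, use_labels = "R") {
  enc <- config$encoding
  keep <- vapply(trains, function(tr)
    is.na(tr$segment_label) || tr$segment_label %in% use_labels, logical(1))
  trains <- trains[keep]
  if (length(trains) == 0)
    abort_invalid("no trials with the requested segment label")
  itr_list <- lapply(trains, sliding_metric_series, metric = "ITR",
                     window_T = enc$window_T, stride = enc$stride,
                     bin_width = enc$bin_width, L_set = seq_len(enc$L_max))
  fr_list <- lapply(trains, sliding_metric_series, metric = "FR",
                    window_T = enc$window_T, stride = enc$stride,
                    bin_width = enc$bin_width)
  itr_avg <- trial_average(itr_list)
  fr_avg <- trial_average(fr_list)
  pcc <- windowed_pcc(itr_avg$mean, fr_avg$mean, config$pcc_window)
  list(itr = itr_avg, fr = fr_avg, pcc = pcc,
       summary_pcc = summary_pcc(itr_avg$mean, fr_avg$mean),
       n_trials = length(trains),
       n_clamped = sum(vapply(itr_list, function(s)
         attr(s, "n_clamped") %||% 0L, integer(1))))
}

#' Analyze spike trains: ITR/FR series, trial averages and PCC
#'
#' Runs the moving-window pipeline on one cell's trials: per-trial ITR and
#' FR series, trial averages (mean, SD, CV%), the windowed PCC between the
#' averaged ITR and FR series, and the full-span summary PCC. By default
#' only repeat (R) segments are analysed, matching the repeat-trial
#' averaging protocol.
#'
#' @param spikes path to a spike CSV (schema of [write_spike_csv()]) or a
#'   list of [spike_train()] objects.
#' @param config a `run_config` or path to a YAML config.
#' @param out_dir optional output directory; when given, writes
#'   `itr_mean.csv`, `fr_mean.csv`, `pcc.csv`, `summary.json` and
#'   `analysis_log.txt`.
#' @param use_labels segment labels to analyse (default `"R"`).
#' @return invisibly, a list with `itr`, `fr` (trial averages: `mean`,
#'   `sd`, `cv_percent`), `pcc` (windowed series), `summary_pcc`,
#'   `n_trials` and `n_clamped` (ITR windows whose intercept was clamped).
#' @export
run_analyze <- function(spikes, config = default_run_config(),
                        out_dir = NULL, use_labels = "R") {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  trains <- if (is.character(spikes)) {
    read_spike_csv(spikes, config$protocol$segment_duration)
  } else {
    spikes
  }
  res <- analyze_trains(trains, config, use_labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_series_csv(res$itr$mean, file.path(out_dir, "itr_mean.csv"))
    write_series_csv(res$fr$mean, file.path(out_dir, "fr_mean.csv"))
    write_series_csv(res$pcc, file.path(out_dir, "pcc.csv"))
    jsonlite::write_json(
      list(n_trials = res$n_trials,
           summary_pcc = res$summary_pcc,
           itr_mean_bits_per_s = mean(res$itr$mean$values, na.rm = TRUE),
           fr_mean_spikes_per_s = mean(res$fr$mean$values, na.rm = TRUE),
           itr_cv_percent = res$itr$cv_percent,
           fr_cv_percent = res$fr$cv_percent),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    writeLines(c(
      sprintf("trials analysed: %d", res$n_trials),
      sprintf("ITR windows with clamped intercept: %d", res$n_clamped),
      sprintf("PCC windows undefined (zero variance): %d",
              res$pcc$n_undefined)),
      file.path(out_dir, "analysis_log.txt"))
  }
  invisible(res)
}

#' Run a complete simulated study in memory
#'
#' Simulates every cell of the configuration under the trial protocol,
#' analyses the repeat segments, and tabulates per-condition time-averaged
#' ITR, FR and summary PCC plus the spot-size category summary. This is the
#' end-to-end regime-separation experiment: rate-code cells should show
#' high ITR-FR correlation, temporal-code cells low.
#'
#' @param config a `run_config` or path to a YAML config.
#' @param out_dir optional directory for per-cell outputs and the summary
#'   JSON.
#' @return a list with `conditions` (data.frame: `cell_id`, `polarity`,
#'   `regime`, `spot_size`, `itr`, `fr`, `pcc`, `itr_cv_percent`,
#'   `fr_cv_percent`), `spot_summary` (from [summarize_by_spot_size()])
#'   and `analyses` (named list of per-cell results).
#' @export
run_study <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  protocol <- protocol_from_config(config$protocol)
  analyses <- list()
  rows <- list()
  for (i in seq_along(config$cells)) {
    cc <- config$cells[[i]]
    trains <- simulate_cell_trials(cell_spec_from_config(cc), protocol,
                                   config$frame_rate,
                                   seed = derive_seed(config$seed, i),
                                   labels = "R")
    res <- analyze_trains(trains, config)
    analyses[[cc$id]] <- res
    rows[[i]] <- data.frame(
      cell_id = cc$id, polarity = cc$polarity, regime = cc$regime,
      spot_size = cc$spot_size,
      itr = mean(res$itr$mean$values, na.rm = TRUE),
      fr = mean(res$fr$mean$values, na.rm = TRUE),
      pcc = res$summary_pcc,
      itr_cv_percent = res$itr$cv_percent,
      fr_cv_percent = res$fr$cv_percent)
    if (!is.null(out_dir)) {
      run_dir <- file.path(out_dir, cc$id)
      dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
      write_series_csv(res$itr$mean, file.path(run_dir, "itr_mean.csv"))
      write_series_csv(res$fr$mean, file.path(run_dir, "fr_mean.csv"))
      write_series_csv(res$pcc, file.path(run_dir, "pcc.csv"))
    }
  }
  conditions <- do.call(rbind, rows)
  regime_summary <- do.call(rbind, lapply(split(conditions,
                                                conditions$regime),
                                          function(d) data.frame(
    regime = d$regime[1], n = nrow(d), mean_pcc = mean(d$pcc),
    mean_itr = mean(d$itr), mean_fr = mean(d$fr))))
  rownames(regime_summary) <- NULL
  out <- list(conditions = conditions,
              spot_summary = summarize_by_spot_size(conditions),
              regime_summary = regime_summary,
              analyses = analyses)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(conditions = conditions, spot_summary = out$spot_summary),
      file.path(out_dir, "study_summary.json"),
      auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  }
  out
}

#' Configuration for the regime-separation study
#'
#' Builds a [default_run_config()] whose cell list realizes the coding-
#' strategy dichotomy experiment: `n_cells` OFF rate-code cells and
#' `n_cells` ON temporal-code cells, each recorded at every spot size in
#' `spots` (one condition per cell x spot, each with its own frozen repeat
#' stimulus). Repeat segments are 32 s long, giving the 27-s usable
#' estimation span of the long-block protocol; the longer span stabilizes
#' the per-condition summary PCC. The rate-code cells should show a high
#' ITR-FR correlation, the temporal-code cells a low one.
#'
#' @param seed base RNG seed.
#' @param n_cells cells per regime (default 3).
#' @param spots spot diameters in degrees (default one per size category:
#'   0.7, 1.5, 2.5).
#' @return a `run_config`.
#' @export
regime_study_config <- function(seed = 1, n_cells = 3,
                                spots = c(0.7, 1.5, 2.5)) {
  config <- default_run_config(seed)
  config$protocol$segment_duration <- 32
  cells <- list()
  for (cell in seq_len(n_cells)) {
    for (spot in spots) {
      cells[[length(cells) + 1L]] <- list(
        id = sprintf("OFF%d_%.1fdeg", cell, spot), polarity = "OFF",
        regime = "rate_code", mean_rate = 5, gain = 6, spot_size = spot,
        refractory = 0.001)
      cells[[length(cells) + 1L]] <- list(
        id = sprintf("ON%d_%.1fdeg", cell, spot), polarity = "ON",
        regime = "temporal_code", mean_rate = 15, gain = 5,
        spot_size = spot, refractory = 0.001, integration = 0.3)
    }
  }
  config$cells <- cells
  config
}

#' Direct-method error on short (paper-scale) windows
#'
#' Monte-Carlo validation of the direct method at moving-window scale:
#' simulates two-state Markov chains of `n_bits` bins with transition
#' probabilities drawn uniformly from `p_range` (moderately mixing by
#' default), estimates each chain's entropy rate by block-entropy
#' extrapolation, and compares with the analytic rate.
#'
#' @param n_reps number of replicate chains (default 1000).
#' @param n_bits bins per chain (default 400, i.e. T = 5 s at f = 80).
#' @param p_range range from which `p01` and `p10` are drawn independently.
#' @param L_set candidate block lengths before the undersampling guard.
#' @param seed RNG seed.
#' @return list with `mare_percent` (mean absolute relative error, %),
#'   `rel_errors` (signed, per replicate) and `n_reps`.
#' @export
direct_method_window_error <- function(n_reps = 1000, n_bits = 400,
                                       p_range = c(0.2, 0.5), L_set = 1:10,
                                       seed = NULL) {
  with_seed(seed, {
    rel <- vapply(seq_len(n_reps), function(r) {
      spec <- markov_spec(runif(1, p_range[1], p_range[2]),
                          runif(1, p_range[1], p_range[2]))
      h_true <- markov_entropy_rate(spec)$rate_per_symbol
      seq <- simulate_markov_train(spec, n_bits)
      est <- direct_method_rate(block_entropy_curve(seq, L_set),
                                f = 1 / spec$bin_width)
      (est$rate_per_symbol - h_true) / h_true
    }, numeric(1))
    list(mare_percent = 100 * mean(abs(rel)), rel_errors = rel,
         n_reps = n_reps)
  })
}

#' Validate the entropy-rate estimators against the Markov oracle
#'
#' Builds the estimator-validation table: one row per `(p01, p10)` grid
#' point comparing the analytic Markov entropy rate with the direct-method
#' and LZ76 estimates on a long simulated chain, plus one row for the
#' short-window experiment of [direct_method_window_error()].
#'
#' @param seed RNG seed.
#' @param grid data.frame with columns `p01`, `p10` (default: the 3x3 grid
#'   over \{0.1, 0.5, 0.9\}).
#' @param n_bins chain length for the long-sequence rows (default `1e6`).
#' @param window_bits,window_reps parameters of the short-window row
#'   (defaults 400 bits, 1000 replicates).
#' @return data.frame with columns `experiment`, `p01`, `p10`, `n_bins`,
#'   `n_reps`, `analytic`, `direct`, `lz76`, `rel_err_direct_pct`,
#'   `rel_err_lz76_pct`, `mare_direct_pct`.
#' @export
run_validate <- function(seed = 1,
                         grid = expand.grid(p01 = c(0.1, 0.5, 0.9),
                                            p10 = c(0.1, 0.5, 0.9)),
                         n_bins = 1e6, window_bits = 400,
                         window_reps = 1000) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- markov_spec(grid$p01[i], grid$p10[i])
    h <- markov_entropy_rate(spec)$rate_per_symbol
    seq <- simulate_markov_train(spec, n_bins,
                                 seed = derive_seed(seed, i))
    hd <- direct_method_rate(block_entropy_curve(seq), f = 80)$rate_per_symbol
    hl <- lz76_rate(seq, f = 80)$rate_per_symbol
    data.frame(experiment = "long_chain", p01 = grid$p01[i],
               p10 = grid$p10[i], n_bins = n_bins, n_reps = 1L,
               analytic = h, direct = hd, lz76 = hl,
               rel_err_direct_pct = 100 * abs(hd - h) / h,
               rel_err_lz76_pct = 100 * abs(hl - h) / h,
               mare_direct_pct = NA_real_)
  })
  werr <- direct_method_window_error(n_reps = window_reps,
                                     n_bits = window_bits,
                                     seed = derive_seed(seed, 999))
  rows[[length(rows) + 1L]] <- data.frame(
    experiment = "short_window", p01 = NA_real_, p10 = NA_real_,
    n_bins = window_bits, n_reps = window_reps,
    analytic = NA_real_, direct = NA_real_, lz76 = NA_real_,
    rel_err_direct_pct = NA_real_, rel_err_lz76_pct = NA_real_,
    mare_direct_pct = werr$mare_percent)
  do.call(rbind, rows)
}
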