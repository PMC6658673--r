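#' Stimulus luminance series
#'
#' A frame-by-frame luminance sample (arbitrary units, non-negative),
#' i.i.d. across frames: the temporally decorrelated "natural" luminance
#' protocol that drives the model cells.
#'
#' @param values non-negative luminance samples, one per frame.
#' @param frame_rate display frame rate in Hz.
#' @param seed seed the series was generated from (bookkeeping only).
#' @return object of class `stimulus_series` with `duration =
#'   length(values)/frame_rate`.
#' @export
stimulus_series <- function(values, frame_rate, seed = NA_integer_) {
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  values <- as.double(values)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    abort_invalid("luminance values must be finite and >= 0")
  structure(
    list(values = values, frame_rate = as.double(frame_rate),
         duration = length(values) / frame_rate, seed = seed),
    class = "stimulus_series")
}

#' @export
print.stimulus_series <- function(x, ...) {
  cat(sprintf("<stimulus_series> %d frames @ %g Hz (%.3f s), mean %.3f\n",
              length(x$values), x$frame_rate, x$duration, mean(x$values)))
  invisible(x)
}

#' Generate an i.i.d. "natural" luminance series
#'
#' Draws independent log-normal luminance samples (`sdlog = 1` by default,
#' the standard heavy-tailed marginal of natural luminance), one per frame.
#' Frames are independent, emulating a naturalistic luminance sequence whose
#' temporal correlations have been stripped.
#'
#' @param frame_rate frames per second (> 0); 160 Hz matches a CRT display.
#' @param duration series duration in seconds (> 0).
#' @param seed RNG seed; identical seeds give bitwise-identical series.
#' @param meanlog,sdlog log-normal parameters (defaults 0 and 1).
#' @return a [stimulus_series()] of `round(frame_rate * duration)` frames.
#' @export
gen_luminance <- function(frame_rate, duration, seed = NULL,
                          meanlog = 0, sdlog = 1) {
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n <- as.integer(round(frame_rate * duration))
  vals <- with_seed(seed, rlnorm(n, meanlog = meanlog, sdlog = sdlog))
  stimulus_series(vals, frame_rate, seed = seed %||% NA_integer_)
}

#' Trial protocol: repeat/unique segment interleaving
#'
#' Describes the stimulus schedule of one recording run: 8-s segments in
#' which repeats (R) of a single frozen luminance sample are interleaved
#' with unique (U) fresh samples, either alternating (`"RU"`, equal counts)
#' or four repeats per unique segment (`"RRRRU"`).
#'
#' @param pattern `"RU"` or `"RRRRU"`.
#' @param segment_duration segment length in seconds (default 8).
#' @param n_repeat_trials number of R segments (default 128). For `"RRRRU"`
#'   this must equal `4 * n_unique_trials` and is filled in if omitted.
#' @param n_unique_trials number of U segments.
#' @return an object of class `trial_protocol`.
#' @export
trial_protocol <- function(pattern = c("RU", "RRRRU"), segment_duration = 8,
                           n_repeat_trials = NULL, n_unique_trials = NULL) {
  if (length(pattern) != 1 || !pattern %in% c("RU", "RRRRU"))
    abort_invalid("`pattern` must be \"RU\" or \"RRRRU\"")
  check_number(segment_duration, "segment_duration", lower = 0,
               strict_lower = TRUE)
  if (pattern == "RU") {
    n_unique_trials <- n_unique_trials %||% n_repeat_trials %||% 128L
    n_repeat_trials <- n_repeat_trials %||% n_unique_trials
    if (n_repeat_trials != n_unique_trials)
      abort_invalid("pattern \"RU\" requires equal repeat and unique counts")
  } else {
    n_unique_trials <- n_unique_trials %||% 32L
    n_repeat_trials <- n_repeat_trials %||% (4L * n_unique_trials)
    if (n_repeat_trials != 4L * n_unique_trials)
      abort_invalid("pattern \"RRRRU\" requires n_repeat_trials = 4 * n_unique_trials")
  }
  check_number(n_repeat_trials, "n_repeat_trials", lower = 1)
  check_number(n_unique_trials, "n_unique_trials", lower = 1)
  structure(
    list(pattern = pattern, segment_duration = segment_duration,
         n_repeat_trials = as.integer(n_repeat_trials),
         n_unique_trials = as.integer(n_unique_trials)),
    class = "trial_protocol")
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat(sprintf("<trial_protocol> %s, %g-s segments, %d R + %d U\n",
              x$pattern, x$segment_duration, x$n_repeat_trials,
              x$n_unique_trials))
  invisible(x)
}

protocol_labels <- function(protocol) {
  block <- if (protocol$pattern == "RU") c("R", "U") else
    c("R", "R", "R", "R", "U")
  rep(block, protocol$n_unique_trials)
}

#' Generate the ordered stimulus schedule of a trial protocol
#'
#' Every R segment carries the same frozen luminance sample; every U segment
#' is a fresh draw. Sub-seeds are derived deterministically from `seed`.
#'
#' @param protocol a [trial_protocol()].
#' @param frame_rate frames per second.
#' @param seed base RNG seed.
#' @return a list of `list(label, stimulus)` entries in presentation order,
#'   class `trial_stimuli`.
#' @export
gen_trial_stimuli <- function(protocol, frame_rate = 160, seed = 1) {
  if (!inherits(protocol, "trial_protocol"))
    abort_invalid("`protocol` must be a trial_protocol")
  labels <- protocol_labels(protocol)
  repeat_stim <- gen_luminance(frame_rate, protocol$segment_duration,
                               seed = derive_seed(seed, 0))
  u_count <- 0L
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    if (labels[i] == "R") {
      out[[i]] <- list(label = "R", stimulus = repeat_stim)
    } else {
      u_count <- u_count + 1L
      out[[i]] <- list(
        label = "U",
        stimulus = gen_luminance(frame_rate, protocol$segment_duration,
                                 seed = derive_seed(seed, u_count)))
    }
  }
  structure(out, class = "trial_stimuli", protocol = protocol, seed = seed)
}

#' Model cell specification
#'
#' Parameters of a synthetic ON or OFF cell. `regime` selects the generative
#' code: `"rate_code"` cells modulate their instantaneous firing rate with
#' the stimulus (inhomogeneous Poisson), `"temporal_code"` cells keep their
#' rate fixed and modulate spike-pattern regularity instead (gamma renewal
#' with stimulus-dependent shape). ON cells are driven by luminance
#' increments, OFF cells by decrements; default mean rates (15 vs 5
#' spikes/s) encode the roughly threefold ON/OFF rate asymmetry of LGN
#' relay cells.
#'
#' @param polarity `"ON"` or `"OFF"`.
#' @param regime `"rate_code"` or `"temporal_code"`.
#' @param mean_rate mean firing rate in spikes/s (> 0); default 15 for ON,
#'   5 for OFF.
#' @param gain stimulus-to-rate coupling, in spikes/s per unit of contrast
#'   (rate code) or octaves of ISI shape per unit of contrast (temporal
#'   code). Default 6 (rate code) or 5 (temporal code).
#' @param spot_size stimulus spot diameter in degrees of visual angle (> 0);
#'   scales the effective gain through a difference-of-Gaussians
#'   center-surround factor.
#' @param refractory absolute refractory period in seconds (default 1 ms).
#' @param integration stimulus integration window in seconds (default
#'   0.3 s) over which temporal-code cells average the luminance before it
#'   modulates their spike-pattern regularity; ignored by rate-code cells,
#'   which follow the instantaneous contrast.
#' @return an object of class `cell_spec`.
#' @export
cell_spec <- function(polarity = c("ON", "OFF"),
                      regime = c("rate_code", "temporal_code"),
                      mean_rate = NULL, gain = NULL, spot_size = 2,
                      refractory = 0.001, integration = 0.3) {
  polarity <- match.arg(polarity)
  regime <- match.arg(regime)
  mean_rate <- mean_rate %||% (if (polarity == "ON") 15 else 5)
  gain <- gain %||% (if (regime == "rate_code") 6 else 5)
  check_number(mean_rate, "mean_rate", lower = 0, strict_lower = TRUE)
  check_number(gain, "gain")
  check_number(spot_size, "spot_size", lower = 0, strict_lower = TRUE)
  check_number(refractory, "refractory", lower = 0)
  check_number(integration, "integration", lower = 0)
  structure(
    list(polarity = polarity, regime = regime, mean_rate = mean_rate,
         gain = gain, spot_size = spot_size, refractory = refractory,
         integration = integration),
    class = "cell_spec")
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf(
    "<cell_spec> %s %s: mean %g spikes/s, gain %g, spot %g deg, refractory %g ms\n",
    x$polarity, x$regime, x$mean_rate, x$gain, x$spot_size,
    x$refractory * 1000))
  invisible(x)
}

#' Center-surround gain attenuation by spot size
#'
#' Difference-of-Gaussians factor describing how much of the stimulus drive
#' survives at a given spot diameter: small spots engage only part of the
#' receptive-field center, very large spots recruit the suppressive
#' surround. Normalized to 1 at the optimal spot size.
#'
#' @param spot_size spot diameter in degrees (> 0); vectorized.
#' @param center_sigma,surround_sigma Gaussian radii (degrees) of center and
#'   surround (defaults 0.6 and 1.8).
#' @param surround_weight relative surround strength (default 0.6).
#' @return attenuation factor in (0, 1].
#' @export
dog_attenuation <- function(spot_size, center_sigma = 0.6,
                            surround_sigma = 1.8, surround_weight = 0.6) {
  if (any(spot_size <= 0)) abort_invalid("`spot_size` must be > 0")
  raw <- function(d) {
    (1 - exp(-(d / (2 * center_sigma))^2)) -
      surround_weight * (1 - exp(-(d / (2 * surround_sigma))^2))
  }
  peak <- optimize(raw, c(1e-3, 20 * surround_sigma), maximum = TRUE)$objective
  raw(spot_size) / peak
}

# Per-frame contrast: z-scored luminance, signed by polarity (ON +, OFF -).
signed_contrast <- function(stim, polarity) {
  v <- stim$values
  s <- sd(v)
  c0 <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  if (polarity == "ON") c0 else -c0
}

# Causal boxcar moving average with partial windows at the start.
causal_boxcar <- function(x, width) {
  if (width <= 1L) return(x)
  cs <- cumsum(x)
  n <- length(x)
  lead <- cs[seq_len(min(width, n))] / seq_len(min(width, n))
  if (n <= width) return(lead)
  c(lead, (cs[(width + 1):n] - cs[1:(n - width)]) / width)
}

#' Effective contrast signal driving a model cell
#'
#' The per-frame stimulus drive a [cell_spec()] responds to: luminance
#' integrated over the cell's integration window (`spec$integration`
#' seconds, causal boxcar), z-scored to unit variance, and signed by
#' polarity (ON +, OFF -). Rate-code cells use instantaneous contrast
#' (`integration` is ignored for them); temporal-code cells use the
#' integrated signal, reflecting that spike-pattern regularity follows the
#' recent stimulus history rather than a single 6-ms frame.
#'
#' @param spec a [cell_spec()].
#' @param stim a [stimulus_series()].
#' @return numeric vector, one value per frame (mean 0, unit SD up to
#'   degenerate inputs).
#' @export
cell_contrast <- function(spec, stim) {
  if (!inherits(spec, "cell_spec")) abort_invalid("`spec` must be a cell_spec")
  if (!inherits(stim, "stimulus_series"))
    abort_invalid("`stim` must be a stimulus_series")
  if (spec$regime == "rate_code")
    return(signed_contrast(stim, spec$polarity))
  w <- max(1L, as.integer(round(spec$integration * stim$frame_rate)))
  sm <- causal_boxcar(stim$values, w)
  s <- sd(sm)
  c0 <- if (s > 0) (sm - mean(sm)) / s else rep(0, length(sm))
  if (spec$polarity == "ON") c0 else -c0
}

frame_at <- function(t, frame_rate, n_frames) {
  pmin(pmax(floor(t * frame_rate) + 1L, 1L), n_frames)
}

#' Simulate a rate-code model cell
#'
#' Inhomogeneous Poisson spiking with intensity
#' \eqn{\lambda(t) = \max(0,\; r_0 + g\,s_\pm(t))}, where \eqn{s_\pm(t)} is
#' the z-scored luminance contrast signed by polarity (ON +, OFF -) and
#' \eqn{g} is the gain attenuated by the spot-size factor
#' [dog_attenuation()]. Spikes are generated by thinning a homogeneous
#' Poisson process at \eqn{\max_t \lambda} and an absolute refractory period
#' is applied by discarding spikes closer than `refractory` to their
#' predecessor.
#'
#' @param spec a [cell_spec()] with `regime = "rate_code"`.
#' @param stim a [stimulus_series()].
#' @param seed optional RNG seed.
#' @return a [spike_train()] over the stimulus duration.
#' @export
simulate_rate_code_cell <- function(spec, stim, seed = NULL) {
  if (!inherits(spec, "cell_spec") || spec$regime != "rate_code")
    abort_invalid("`spec` must be a cell_spec with regime \"rate_code\"")
  if (!inherits(stim, "stimulus_series"))
    abort_invalid("`stim` must be a stimulus_series")
  g <- spec$gain * dog_attenuation(spec$spot_size)
  lam <- pmax(0, spec$mean_rate + g * signed_contrast(stim, spec$polarity))
  lam_max <- max(lam, spec$mean_rate, 1e-12)
  with_seed(seed, {
    n_cand <- rpois(1, lam_max * stim$duration)
    cand <- sort(runif(n_cand, 0, stim$duration))
    acc <- runif(n_cand) < lam[frame_at(cand, stim$frame_rate,
                                        length(stim$values))] / lam_max
    times <- apply_refractory(cand[acc], spec$refractory)
    spike_train(times, stim$duration)
  })
}

apply_refractory <- function(times, refractory) {
  if (refractory <= 0 || length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate a temporal-code model cell
#'
#' A burst-mode spike generator: pattern statistics follow the stimulus
#' while the expected firing rate does not. Bins of width `gen_bin` are
#' emitted by a two-state Markov chain whose stationary spike probability
#' is pinned at \eqn{\pi_1 = } `mean_rate * gen_bin` for every stimulus
#' value, while the stimulus modulates the chain's persistence (its second
#' eigenvalue): \eqn{\lambda(t) = \lambda_{max}\,
#' \mathrm{logit}^{-1}(-g\,s_\pm(t))}, with \eqn{s_\pm(t)} the integrated,
#' z-scored contrast of [cell_contrast()]. Low effective contrast drives
#' the cell towards persistent burst firing (high \eqn{\lambda}, low
#' entropy rate), high contrast towards independent tonic firing
#' (\eqn{\lambda \to 0}, entropy rate near its Bernoulli maximum) — the
#' tonic/burst dichotomy of thalamic relay cells. Because the stationary
#' law is fixed, the expected spike count of every window is constant: the
#' stimulus is encoded exclusively in the temporal arrangement of spikes.
#' Each spiking bin receives one spike at a uniform position within the
#' bin; the refractory period is applied by thinning.
#'
#' @param spec a [cell_spec()] with `regime = "temporal_code"` and
#'   `mean_rate < 1/gen_bin`.
#' @param stim a [stimulus_series()].
#' @param seed optional RNG seed.
#' @param gen_bin emission bin width in seconds (default 1/80 s).
#' @param lambda_max maximal chain persistence in `[0, 1)` (default 0.8).
#' @return a [spike_train()] over the stimulus duration.
#' @export
simulate_temporal_code_cell <- function(spec, stim, seed = NULL,
                                        gen_bin = 0.0125,
                                        lambda_max = 0.8) {
  if (!inherits(spec, "cell_spec") || spec$regime != "temporal_code")
    abort_invalid("`spec` must be a cell_spec with regime \"temporal_code\"")
  if (!inherits(stim, "stimulus_series"))
    abort_invalid("`stim` must be a stimulus_series")
  check_number(gen_bin, "gen_bin", lower = 0, strict_lower = TRUE)
  check_number(lambda_max, "lambda_max", lower = 0, upper = 1)
  pi1 <- spec$mean_rate * gen_bin
  if (pi1 >= 1)
    abort_invalid("`mean_rate` must be below 1/gen_bin spikes/s")
  g <- spec$gain * dog_attenuation(spec$spot_size)
  contrast <- cell_contrast(spec, stim)
  n_frames <- length(stim$values)
  n_bins <- as.integer(round(stim$duration / gen_bin))
  centers <- (seq_len(n_bins) - 0.5) * gen_bin
  lam <- lambda_max * stats::plogis(-g * contrast[frame_at(centers,
                                                           stim$frame_rate,
                                                           n_frames)])
  with_seed(seed, {
    u <- runif(n_bins)
    bits <- integer(n_bins)
    bits[1] <- as.integer(u[1] < pi1)
    for (i in seq_len(n_bins)[-1]) {
      p_spike <- if (bits[i - 1L] == 1L) pi1 + lam[i] * (1 - pi1)
                 else pi1 * (1 - lam[i])
      bits[i] <- as.integer(u[i] < p_spike)
    }
    pos <- which(bits == 1L)
    t <- sort((pos - 1 + runif(length(pos))) * gen_bin)
    spike_train(apply_refractory(t, spec$refractory), stim$duration)
  })
}

#' Simulate a model cell (dispatch on coding regime)
#'
#' @param spec a [cell_spec()].
#' @param stim a [stimulus_series()].
#' @param seed optional RNG seed.
#' @return a [spike_train()].
#' @export
simulate_cell <- function(spec, stim, seed = NULL) {
  if (!inherits(spec, "cell_spec"))
    abort_invalid("`spec` must be a cell_spec")
  if (spec$regime == "rate_code") simulate_rate_code_cell(spec, stim, seed)
  else simulate_temporal_code_cell(spec, stim, seed)
}
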