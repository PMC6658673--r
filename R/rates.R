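#' Moving-window rate time series
#'
#' A time-indexed series of window estimates — either the information
#' transmission rate (`metric = "ITR"`, bits/s) or the firing rate
#' (`metric = "FR"`, spikes/s). Times label the window start `t`, the value
#' at `t` summarizing `[t, t+T)`.
#'
#' @param times window start times in seconds (strictly increasing, constant
#'   stride).
#' @param values estimates (>= 0; `NA` marks windows where estimation
#'   failed).
#' @param window_T window length in seconds.
#' @param stride step between windows in seconds.
#' @param metric `"ITR"` or `"FR"`.
#' @return object of class `rate_series`.
#' @export
rate_series <- function(times, values, window_T, stride,
                        metric = c("ITR", "FR")) {
  metric <- match.arg(metric)
  if (length(times) != length(values))
    abort_invalid("`times` and `values` must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    abort_invalid("`times` must be strictly increasing")
  if (any(values < 0, na.rm = TRUE))
    abort_invalid("rate values must be >= 0")
  structure(
    list(times = as.double(times), values = as.double(values),
         window_T = window_T, stride = stride, metric = metric),
    class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf(
    "<rate_series> %s: %d windows (T = %g s, stride %g s), t in [%g, %g], mean %.3f\n",
    x$metric, length(x$times), x$window_T, x$stride,
    min(x$times), max(x$times), mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.rate_series <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "window start t [s]",
       ylab = if (x$metric == "ITR") "ITR [bits/s]" else "FR [spikes/s]",
       ...)
  invisible(x)
}

#' Firing rate over a time window
#'
#' Raw spike count in `[t, t+T)` divided by `T` (spikes per second).
#'
#' @param train a [spike_train()].
#' @param t window start in seconds.
#' @param T window length in seconds.
#' @return firing rate in spikes/s.
#' @export
firing_rate <- function(train, t, T) {
  if (!inherits(train, "spike_train"))
    abort_invalid("`train` must be a spike_train")
  check_number(T, "T", lower = 0, strict_lower = TRUE)
  if (t < 0 || t + T > train$duration + 1e-9)
    abort_range(sprintf("window [%g, %g) outside the segment [0, %g)",
                        t, t + T, train$duration))
  sum(train$times >= t & train$times < t + T) / T
}

window_starts <- function(span, window_T, stride) {
  n_steps <- floor((span - window_T) / stride + 1e-9)
  if (n_steps < 0)
    abort_estimation(sprintf(
      "segment span %g s is shorter than the window T = %g s", span, window_T))
  (0:n_steps) * stride
}

# Sliding block entropies by incremental count updates: as the window slides
# one bin, one word leaves and one enters per block length, so the entropy
# sum S = sum c*log2(c) is patched in O(1) per L per step.
sliding_block_entropies <- function(bits, T_bins, stride_bins, L_set) {
  n <- length(bits)
  n_windows <- (n - T_bins) %/% stride_bins + 1L
  emit <- seq(1L, by = stride_bins, length.out = n_windows)
  H <- matrix(NA_real_, nrow = n_windows, ncol = length(L_set),
              dimnames = list(NULL, paste0("L", L_set)))
  for (j in seq_along(L_set)) {
    L <- L_set[j]
    codes <- word_codes(bits, L)
    nw <- T_bins - L + 1L          # word positions per window (constant)
    cnt <- tabulate(codes[1:nw] + 1, nbins = 2^L)
    pos <- cnt[cnt > 0]
    S <- sum(pos * log2(pos))
    col <- numeric(n - T_bins + 1L)
    col[1] <- log2(nw) - S / nw
    if (n - T_bins >= 1) {
      for (i in 1:(n - T_bins)) {
        out_code <- codes[i] + 1
        co <- cnt[out_code]
        S <- S - co * log2(co) +
          (if (co > 1) (co - 1) * log2(co - 1) else 0)
        cnt[out_code] <- co - 1
        in_code <- codes[i + nw] + 1
        ci <- cnt[in_code]
        S <- S + (ci + 1) * log2(ci + 1) - (if (ci > 0) ci * log2(ci) else 0)
        cnt[in_code] <- ci + 1
        col[i + 1] <- log2(nw) - S / nw
      }
    }
    H[, j] <- pmax(col[emit], 0)
  }
  H
}

#' Moving-window ITR or FR time series for one trial
#'
#' Applies a moving window of length `window_T` in steps of `stride` over
#' the segment. FR windows use the raw spike count over `window_T`; ITR
#' windows are binarized at `bin_width` (grid anchored at `t_start`) and
#' passed through the block-entropy curve and direct-method extrapolation.
#' An 8-s segment with the default `T = 5` s yields window starts spanning
#' 3 s; a 32-s segment spans 27 s.
#'
#' @param train a [spike_train()].
#' @param metric `"ITR"` or `"FR"`.
#' @param window_T moving-window length in seconds (default 5).
#' @param stride window step in seconds (default one bin, 12.5 ms). For ITR
#'   it must be an integer multiple of `bin_width`.
#' @param bin_width encoding bin in seconds (default 1/80 s).
#' @param L_set candidate block lengths for the direct method (default
#'   1..10, subject to the undersampling guard per window).
#' @param t_start,t_end analysed sub-span of the segment.
#' @return a [rate_series()]. For ITR, attribute `"n_clamped"` counts
#'   windows whose raw intercept was clamped into `[0, 1]`.
#' @export
sliding_metric_series <- function(train, metric = c("ITR", "FR"),
                                  window_T = 5, stride = 0.0125,
                                  bin_width = 0.0125, L_set = 1:10,
                                  t_start = 0, t_end = train$duration) {
  metric <- match.arg(metric)
  if (!inherits(train, "spike_train"))
    abort_invalid("`train` must be a spike_train")
  check_number(window_T, "window_T", lower = 0, strict_lower = TRUE)
  check_number(stride, "stride", lower = 0, strict_lower = TRUE)
  span <- t_end - t_start
  starts <- window_starts(span, window_T, stride)
  if (metric == "FR") {
    vals <- vapply(starts, function(s) {
      sum(train$times >= t_start + s & train$times < t_start + s + window_T)
    }, numeric(1)) / window_T
    return(rate_series(t_start + starts, vals, window_T, stride, "FR"))
  }
  stride_bins <- stride / bin_width
  if (abs(stride_bins - round(stride_bins)) > 1e-6)
    abort_invalid("for ITR, `stride` must be an integer multiple of `bin_width`")
  stride_bins <- as.integer(round(stride_bins))
  f <- 1 / bin_width
  seq_all <- bin_spikes(train, bin_width, t_start, t_end)
  T_bins <- as.integer(round(window_T / bin_width))
  L_set <- sort(unique(as.integer(L_set)))
  L_set <- L_set[L_set >= 1 & L_set <= min(T_bins, 16L)]
  # The undersampling guard is applied once per segment (every window holds
  # the same number of bins, and the bin-wise entropy varies little within a
  # segment); a per-window guard would switch fitted L sets between
  # neighbouring windows and inject artificial jitter into the series.
  H1_seg <- entropy_from_counts(tabulate(seq_all$bits + 1L, 2L),
                                length(seq_all$bits))
  adm <- guard_admissible(L_set, T_bins, H1_seg)
  if (length(adm) < 2)
    abort_estimation("fewer than two block lengths pass the undersampling guard")
  H <- sliding_block_entropies(seq_all$bits, T_bins, stride_bins, adm)
  n_clamped <- 0L
  x <- 1 / adm
  vals <- vapply(seq_len(nrow(H)), function(i) {
    fit <- ols_line(x, H[i, ] / adm)
    ic <- fit[["intercept"]]
    if (ic < 0 || ic > 1) n_clamped <<- n_clamped + 1L
    min(max(ic, 0), 1) * f
  }, numeric(1))
  out <- rate_series(t_start + starts, vals, window_T, stride, "ITR")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Average rate series over repeat trials
#'
#' Pointwise mean and standard deviation over a list of series on a shared
#' time grid, plus the time-averaged coefficient of variation
#' `100 * SD/mean` (in percent) summarizing trial-to-trial variability.
#'
#' @param series_list list of [rate_series()] with identical times, window
#'   and metric.
#' @return list with components `mean` and `sd` (both [rate_series()]; the
#'   SD is the descriptive, population-denominator SD across trials) and
#'   `cv_percent` (scalar; time average over points with positive mean).
#' @export
trial_average <- function(series_list) {
  if (!is.list(series_list) || length(series_list) < 1 ||
      !all(vapply(series_list, inherits, logical(1), "rate_series")))
    abort_invalid("`series_list` must be a non-empty list of rate_series")
  ref <- series_list[[1]]
  same <- vapply(series_list, function(s) {
    s$metric == ref$metric && length(s$times) == length(ref$times) &&
      isTRUE(all.equal(s$times, ref$times, tolerance = 1e-8))
  }, logical(1))
  if (!all(same))
    abort_invalid("all series must share the same time grid and metric")
  m <- do.call(rbind, lapply(series_list, `[[`, "values"))
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  })
  pos <- !is.na(mu) & mu > 0 & !is.na(sdv)
  cv <- if (any(pos)) mean(100 * sdv[pos] / mu[pos]) else NA_real_
  list(mean = rate_series(ref$times, mu, ref$window_T, ref$stride,
                          ref$metric),
       sd = rate_series(ref$times, sdv, ref$window_T, ref$stride,
                        ref$metric),
       cv_percent = cv)
}

#' Windowed Pearson correlation between two rate series
#'
#' Pearson correlation of the two series restricted to a short moving
#' window (default 0.25 s), tracing how tightly ITR and FR co-vary over
#' time. Windows where either series has zero variance are flagged `NA`
#' rather than fabricated.
#'
#' @param a,b [rate_series()] on the same time grid.
#' @param pcc_window correlation window in seconds; must hold at least two
#'   samples (`pcc_window >= 2 * stride`).
#' @return object of class `pcc_series`: list of `times` (window starts),
#'   `values` (correlations in `[-1, 1]` or `NA`), `pcc_window`, and
#'   `n_undefined`.
#' @export
windowed_pcc <- function(a, b, pcc_window = 0.25) {
  if (!inherits(a, "rate_series") || !inherits(b, "rate_series"))
    abort_invalid("`a` and `b` must be rate_series")
  if (length(a$times) != length(b$times) ||
      !isTRUE(all.equal(a$times, b$times, tolerance = 1e-8)))
    abort_invalid("`a` and `b` must share the same time grid")
  w <- as.integer(round(pcc_window / a$stride))
  if (w < 2)
    abort_invalid("`pcc_window` must cover at least two samples (>= 2 * stride)")
  n <- length(a$times)
  if (n < w) abort_invalid("series shorter than the correlation window")
  nw <- n - w + 1L
  vals <- vapply(seq_len(nw), function(i) {
    xa <- a$values[i:(i + w - 1L)]
    xb <- b$values[i:(i + w - 1L)]
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < 2 || sd(xa[ok]) == 0 || sd(xb[ok]) == 0) return(NA_real_)
    cor(xa[ok], xb[ok])
  }, numeric(1))
  structure(
    list(times = a$times[seq_len(nw)], values = vals,
         pcc_window = pcc_window, n_undefined = sum(is.na(vals))),
    class = "pcc_series")
}

#' @export
print.pcc_series <- function(x, ...) {
  cat(sprintf(
    "<pcc_series> %d windows of %g s, mean PCC %.3f (%d undefined)\n",
    length(x$values), x$pcc_window, mean(x$values, na.rm = TRUE),
    x$n_undefined))
  invisible(x)
}

#' @export
plot.pcc_series <- function(x, ...) {
  plot(x$times, x$values, type = "l", ylim = c(-1, 1),
       xlab = "window start t [s]", ylab = "PCC(ITR, FR)", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Summary Pearson correlation over the full usable span
#'
#' Single Pearson correlation between two rate series over all shared time
#' points — the per-condition figure that spot-size summary tables report,
#' complementing the windowed series of [windowed_pcc()].
#'
#' @param a,b [rate_series()] on the same time grid.
#' @return correlation in `[-1, 1]`, or `NA` if either series is constant.
#' @export
summary_pcc <- function(a, b) {
  if (!inherits(a, "rate_series") || !inherits(b, "rate_series"))
    abort_invalid("`a` and `b` must be rate_series")
  if (length(a$times) != length(b$times) ||
      !isTRUE(all.equal(a$times, b$times, tolerance = 1e-8)))
    abort_invalid("`a` and `b` must share the same time grid")
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < 2 || sd(a$values[ok]) == 0 || sd(b$values[ok]) == 0)
    return(NA_real_)
  cor(a$values[ok], b$values[ok])
}

#' Spot-size category of a stimulus
#'
#' Small: `< 1` degree; medium: 1-2 degrees; large: `> 2` degrees.
#'
#' @param spot_size spot diameter(s) in degrees.
#' @return factor with levels `small`, `medium`, `large`.
#' @export
spot_category <- function(spot_size) {
  if (any(spot_size <= 0)) abort_invalid("`spot_size` must be > 0")
  factor(ifelse(spot_size < 1, "small",
                ifelse(spot_size <= 2, "medium", "large")),
         levels = c("small", "medium", "large"))
}

#' Summarize per-condition results by spot-size category
#'
#' Groups per-cell, per-spot results into small/medium/large categories and
#' reports, per polarity and category, the min-max range of time-averaged
#' ITR, FR and summary PCC — the layout of a spot-size summary table. Empty
#' categories are omitted.
#'
#' @param results data.frame with columns `polarity` (`"ON"`/`"OFF"`),
#'   `spot_size` (degrees), `itr` (bits/s, time-averaged), `fr` (spikes/s,
#'   time-averaged) and `pcc` (summary PCC), one row per condition.
#' @return data.frame of class `spot_summary` with columns `polarity`,
#'   `category`, `n`, `itr_min`, `itr_max`, `fr_min`, `fr_max`, `pcc_min`,
#'   `pcc_max`.
#' @export
summarize_by_spot_size <- function(results) {
  need <- c("polarity", "spot_size", "itr", "fr", "pcc")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    abort_invalid(sprintf("`results` must be a data.frame with columns %s",
                          paste(need, collapse = ", ")))
  if (nrow(results) == 0) abort_invalid("`results` has no rows")
  results$category <- spot_category(results$spot_size)
  key <- interaction(results$polarity, results$category, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    data.frame(polarity = d$polarity[1],
               category = as.character(d$category[1]),
               n = nrow(d),
               itr_min = min(d$itr), itr_max = max(d$itr),
               fr_min = min(d$fr), fr_max = max(d$fr),
               pcc_min = min(d$pcc), pcc_max = max(d$pcc))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$polarity,
                   match(out$category, c("small", "medium", "large"))), ]
  rownames(out) <- NULL
  class(out) <- c("spot_summary", "data.frame")
  out
}
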