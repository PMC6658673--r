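#' Spike train container
#'
#' A sorted vector of spike times for one trial/segment, the raw observable
#' of the pipeline. Times are in seconds relative to segment onset.
#'
#' @param times numeric vector of spike times in seconds, `0 <= t < duration`.
#'   Sorted on construction.
#' @param duration segment duration in seconds.
#' @param trial_id optional trial identifier.
#' @param segment_label optional `"R"` (repeat) or `"U"` (unique) label.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration, trial_id = NA_character_,
                        segment_label = NA_character_) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  times <- as.double(times)
  if (anyNA(times) || any(!is.finite(times)))
    abort_invalid("spike times must be finite")
  if (any(times < 0) || any(times >= duration))
    abort_invalid("spike times must lie in [0, duration)")
  structure(
    list(times = sort(times), duration = as.double(duration),
         trial_id = trial_id, segment_label = segment_label),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s (%.2f spikes/s)",
              length(x$times), x$duration, length(x$times) / x$duration))
  if (!is.na(x$trial_id)) cat(sprintf("  trial %s", x$trial_id))
  if (!is.na(x$segment_label)) cat(sprintf(" [%s]", x$segment_label))
  cat("\n")
  invisible(x)
}

#' Binary sequence container
#'
#' Ordered 0/1 symbols obtained by binning a spike train at resolution
#' `bin_width` (the encoding bin \eqn{\Delta\tau}); the encoding frequency is
#' `f = 1/bin_width` bins per second.
#'
#' @param bits integer vector of 0/1 symbols.
#' @param bin_width bin width in seconds.
#' @param t_origin time (s) of the left edge of the first bin.
#' @return an object of class `binary_sequence`.
#' @export
binary_sequence <- function(bits, bin_width, t_origin = 0) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  check_number(t_origin, "t_origin")
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    abort_invalid("`bits` must contain only 0 and 1")
  structure(
    list(bits = bits, bin_width = as.double(bin_width),
         t_origin = as.double(t_origin)),
    class = "binary_sequence")
}

#' @export
print.binary_sequence <- function(x, ...) {
  n <- length(x$bits)
  preview <- paste(x$bits[seq_len(min(n, 40L))], collapse = "")
  if (n > 40L) preview <- paste0(preview, "...")
  cat(sprintf("<binary_sequence> %d bins @ %.4g ms (f = %.4g/s): %s\n",
              n, x$bin_width * 1000, 1 / x$bin_width, preview))
  invisible(x)
}

#' @export
length.binary_sequence <- function(x) length(x$bits)

#' Bin a spike train into a binary sequence
#'
#' Divides `[t_start, t_end)` into bins of width `bin_width` (left-closed,
#' half-open) and writes 1 where at least one spike falls in the bin.
#' Multiple spikes in a bin clip to 1; the number of clipped spikes and the
#' number of spikes outside the window are recorded as attributes
#' `"n_clipped"` and `"n_ignored"`.
#'
#' @param train a [spike_train()].
#' @param bin_width bin width in seconds (default 12.5 ms, i.e. f = 80/s).
#' @param t_start,t_end analysis window in seconds; the bin grid is anchored
#'   at `t_start`.
#' @return a [binary_sequence()] of `round((t_end - t_start)/bin_width)` bits.
#' @export
bin_spikes <- function(train, bin_width = 0.0125, t_start = 0,
                       t_end = train$duration) {
  if (!inherits(train, "spike_train"))
    abort_invalid("`train` must be a spike_train")
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (t_start >= t_end)
    abort_invalid("`t_start` must be strictly less than `t_end`")
  n_bins <- as.integer(round((t_end - t_start) / bin_width))
  idx <- floor((train$times - t_start) / bin_width + 1e-9)
  inside <- train$times >= t_start & train$times < t_end &
    idx >= 0 & idx < n_bins
  n_ignored <- sum(!inside)
  counts <- tabulate(idx[inside] + 1L, nbins = n_bins)
  seq <- binary_sequence(as.integer(counts > 0L), bin_width,
                         t_origin = t_start)
  attr(seq, "n_clipped") <- sum(pmax(counts - 1L, 0L))
  attr(seq, "n_ignored") <- n_ignored
  seq
}

#' Extract a time window from a binary sequence
#'
#' Returns the `round(T/bin_width)` bins covering `[t, t+T)`. With the
#' defaults used throughout (T = 5 s, f = 80 bins/s) a window is 400 bits.
#' A `t` that is not aligned with the bin grid is snapped down to
#' `floor((t - t_origin)/bin_width)` bins; the snap offset is recorded in
#' attribute `"t_snap"`.
#'
#' @param seq a [binary_sequence()].
#' @param t window start in seconds.
#' @param T window length in seconds.
#' @return a [binary_sequence()] of the window, with `t_origin` updated.
#' @export
extract_window <- function(seq, t, T) {
  if (!inherits(seq, "binary_sequence"))
    abort_invalid("`seq` must be a binary_sequence")
  check_number(T, "T", lower = 0, strict_lower = TRUE)
  start <- as.integer(floor((t - seq$t_origin) / seq$bin_width + 1e-9))
  len <- as.integer(round(T / seq$bin_width))
  if (start < 0 || start + len > length(seq$bits))
    abort_range(sprintf(
      "window [%g, %g) exceeds the sequence span [%g, %g)",
      t, t + T, seq$t_origin,
      seq$t_origin + length(seq$bits) * seq$bin_width))
  out <- binary_sequence(seq$bits[(start + 1L):(start + len)], seq$bin_width,
                         t_origin = seq$t_origin + start * seq$bin_width)
  attr(out, "t_snap") <- t - out$t_origin
  out
}

# Integer codes of all overlapping L-bin words (step 1); numeric to stay safe
# for joint codes up to 2^(2L).
word_codes <- function(bits, L) {
  n <- length(bits)
  if (L < 1L || L > n) abort_invalid("`L` must satisfy 1 <= L <= length(seq)")
  codes <- as.double(bits)
  if (L > 1L) {
    for (k in 2:L) codes <- codes[1:(n - k + 1L)] * 2 + bits[k:n]
  }
  codes
}

code_to_word <- function(codes, L) {
  vapply(codes, function(cd) {
    paste(rev((cd %/% 2^(0:(L - 1L))) %% 2), collapse = "")
  }, character(1))
}

#' Count overlapping words of length L
#'
#' Slides a window of `L` bins in steps of 1 bin over the sequence and counts
#' every word, giving `length(seq) - L + 1` word positions in total.
#'
#' @param seq a [binary_sequence()].
#' @param L word length in bins.
#' @return an object of class `word_distribution`: a list with `word_length`,
#'   `counts` (named integer vector, names are the binary words) and `total`.
#' @export
count_words <- function(seq, L) {
  if (!inherits(seq, "binary_sequence"))
    abort_invalid("`seq` must be a binary_sequence")
  codes <- word_codes(seq$bits, as.integer(L))
  r <- rle(sort(codes))
  counts <- as.integer(r$lengths)
  names(counts) <- code_to_word(r$values, as.integer(L))
  structure(
    list(word_length = as.integer(L), counts = counts,
         total = length(codes)),
    class = "word_distribution")
}

#' @export
print.word_distribution <- function(x, ...) {
  cat(sprintf("<word_distribution> L = %d, %d distinct words, %d positions\n",
              x$word_length, length(x$counts), x$total))
  print(x$counts)
  invisible(x)
}
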