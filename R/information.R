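# Shannon entropy (bits) from a vector of counts (zeros allowed).
entropy_from_counts <- function(counts, total = sum(counts)) {
  counts <- counts[counts > 0]
  if (total <= 0 || length(counts) == 0) return(0)
  p <- counts / total
  -sum(p * log2(p))
}

entropy_from_codes <- function(codes) {
  r <- rle(sort(codes))
  entropy_from_counts(r$lengths, length(codes))
}

#' Plug-in (maximum-likelihood) Shannon entropy of a word distribution
#'
#' \eqn{H = -\sum_w p_w \log_2 p_w} with \eqn{p_w} the observed relative
#' frequencies and the convention \eqn{0 \log 0 = 0}. No bias correction is
#' applied; the raw plug-in estimate feeds the direct-method extrapolation.
#'
#' @param dist a `word_distribution` from [count_words()].
#' @return entropy in bits, in `[0, L]` for binary words of length L.
#' @export
plugin_entropy <- function(dist) {
  if (!inherits(dist, "word_distribution"))
    abort_invalid("`dist` must be a word_distribution")
  if (dist$total < 1 || length(dist$counts) == 0)
    abort_invalid("empty word distribution")
  entropy_from_counts(dist$counts, dist$total)
}

#' Self-information of a word
#'
#' The information carried by an event of probability `p`:
#' \eqn{I = -\log_2 p} bits.
#'
#' @param p probability in (0, 1].
#' @return information in bits.
#' @export
word_information <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort_invalid("`p` must lie in (0, 1]")
  -log2(p)
}

#' Binary entropy function
#'
#' \eqn{H_b(p) = -p\log_2 p - (1-p)\log_2(1-p)} bits.
#'
#' @param p probability in \[0, 1\].
#' @return entropy in bits.
#' @export
binary_entropy <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort_invalid("`p` must lie in [0, 1]")
  term <- function(q) ifelse(q > 0, -q * log2(q), 0)
  term(p) + term(1 - p)
}

# Undersampling guard: a block length L enters the fit only while the number
# of word positions is at least 10 * 2^min(L, L * H1), where H1 is the
# single-bin plug-in entropy of the same data. 2^(L*H1) approximates the size
# of the typical set actually being sampled, so sparse (low-entropy) windows
# admit longer words than dense ones.
guard_admissible <- function(L_set, n_bits, H1, factor = 10) {
  n_pos <- n_bits - L_set + 1
  req <- factor * 2^pmin(L_set, L_set * H1)
  L_set[n_pos >= req & L_set <= n_bits]
}

#' Block-entropy curve of a binary sequence
#'
#' Computes the plug-in Shannon block entropy \eqn{H(L)} from overlapping
#' word counts for each requested block length. Block lengths failing the
#' undersampling guard (see Details) are dropped and reported in attribute
#' `"dropped_L"`.
#'
#' @details A length `L` is kept only while the number of word positions
#' `length(seq) - L + 1` is at least `10 * 2^min(L, L*H1)`, with `H1` the
#' single-bin entropy of the sequence — i.e. at least ten samples per word of
#' the typical set. Set `guard = FALSE` to disable (e.g. for analytic
#' sanity checks on short strings).
#'
#' @param seq a [binary_sequence()].
#' @param L_set integer vector of block lengths (default 1..10).
#' @param guard apply the undersampling guard? (default `TRUE`)
#' @return object of class `block_entropy_curve`: list with `points`
#'   (data.frame of `L`, `H`) and `source_length`.
#' @export
block_entropy_curve <- function(seq, L_set = 1:10, guard = TRUE) {
  if (!inherits(seq, "binary_sequence"))
    abort_invalid("`seq` must be a binary_sequence")
  L_set <- sort(unique(as.integer(L_set)))
  n <- length(seq$bits)
  if (any(L_set < 1L)) abort_invalid("block lengths must be >= 1")
  if (max(L_set) > n)
    abort_invalid("largest block length exceeds the sequence length")
  H1 <- entropy_from_counts(tabulate(seq$bits + 1L, 2L), n)
  keep <- if (guard) guard_admissible(L_set, n, H1) else L_set
  if (length(keep) == 0)
    abort_estimation("no block length passes the undersampling guard")
  H <- vapply(keep, function(L) {
    codes <- word_codes(seq$bits, L)
    if (L <= 20L) {
      entropy_from_counts(tabulate(codes + 1, nbins = 2^L), length(codes))
    } else {
      entropy_from_codes(codes)
    }
  }, numeric(1))
  structure(
    list(points = data.frame(L = keep, H = H), source_length = n),
    class = "block_entropy_curve",
    dropped_L = setdiff(L_set, keep))
}

#' @export
print.block_entropy_curve <- function(x, ...) {
  cat(sprintf("<block_entropy_curve> from %s bins\n",
              format(x$source_length)))
  print(x$points, row.names = FALSE)
  dl <- attr(x, "dropped_L")
  if (length(dl)) cat("dropped (undersampled) L:", paste(dl, collapse = ", "), "\n")
  invisible(x)
}

# Unweighted OLS of y on x; returns c(intercept, slope, rms).
ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- if (sxx > 0) sum((x - xb) * (y - yb)) / sxx else 0
  intercept <- yb - slope * xb
  res <- y - (intercept + slope * x)
  c(intercept = intercept, slope = slope, rms = sqrt(mean(res^2)))
}

new_itr_estimate <- function(rate_per_symbol, f, method, L_used = NA_integer_,
                             fit_slope = NA_real_, fit_intercept = NA_real_,
                             rms_residual = NA_real_, clamped = FALSE,
                             points = NULL) {
  structure(
    list(rate_per_symbol = rate_per_symbol,
         rate_per_second = rate_per_symbol * f,
         f = f, method = method, L_used = L_used,
         fit_slope = fit_slope, fit_intercept = fit_intercept,
         rms_residual = rms_residual, clamped = clamped, points = points),
    class = "itr_estimate")
}

#' Direct-method entropy-rate (ITR) estimate
#'
#' Fits an unweighted least-squares line to the points
#' \eqn{(1/L,\; H(L)/L)} of a block-entropy curve and extrapolates it to
#' \eqn{1/L = 0}; the intercept is the entropy rate in bits per symbol, and
#' times the encoding frequency `f` it is the information transmission rate
#' in bits per second. Intercepts outside `[0, 1]` (finite-sample artifacts
#' on near-deterministic data) are clamped and flagged.
#'
#' @param curve a [block_entropy_curve()] with at least two points.
#' @param f encoding frequency in bins per second (default 80).
#' @return an object of class `itr_estimate` with components
#'   `rate_per_symbol`, `rate_per_second`, `method = "direct"`, `L_used`,
#'   `fit_slope`, `fit_intercept` (raw), `rms_residual`, `clamped`, and the
#'   fitted `points`. Supports `print()`, `summary()`, `coef()`,
#'   `residuals()` and `plot()`.
#' @export
direct_method_rate <- function(curve, f = 80) {
  if (!inherits(curve, "block_entropy_curve"))
    abort_invalid("`curve` must be a block_entropy_curve")
  check_number(f, "f", lower = 0, strict_lower = TRUE)
  pts <- curve$points
  if (nrow(pts) < 2)
    abort_estimation("direct method needs at least two block-entropy points")
  x <- 1 / pts$L
  y <- pts$H / pts$L
  fit <- ols_line(x, y)
  rate <- min(max(fit[["intercept"]], 0), 1)
  new_itr_estimate(
    rate_per_symbol = rate, f = f, method = "direct", L_used = pts$L,
    fit_slope = fit[["slope"]], fit_intercept = fit[["intercept"]],
    rms_residual = fit[["rms"]],
    clamped = (fit[["intercept"]] < 0 || fit[["intercept"]] > 1),
    points = data.frame(L = pts$L, H = pts$H, x = x, y = y,
                        fitted = fit[["intercept"]] + fit[["slope"]] * x))
}

#' Lempel-Ziv (1976) complexity of a binary sequence
#'
#' Number of phrases `c(n)` in the LZ76 exhaustive-history parsing, in which
#' each phrase extends the longest factor seen earlier (self-overlap allowed)
#' by one fresh symbol.
#'
#' @param seq a [binary_sequence()] or a 0/1 vector.
#' @return integer phrase count.
#' @export
lz76_complexity <- function(seq) {
  bits <- if (inherits(seq, "binary_sequence")) seq$bits else as.integer(seq)
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    abort_invalid("sequence must be binary")
  .lz76_complexity_cpp(bits)
}

#' LZ76 entropy-rate estimate
#'
#' Normalizes the LZ76 phrase count as \eqn{c(n)\log_2(n)/n}, a consistent
#' entropy-rate estimator for stationary ergodic binary sources, used as a
#' cross-check on the direct method.
#'
#' @param seq a [binary_sequence()].
#' @param f encoding frequency in bins per second (default 80).
#' @return an `itr_estimate` with `method = "lz76"`.
#' @export
lz76_rate <- function(seq, f = 80) {
  if (!inherits(seq, "binary_sequence"))
    abort_invalid("`seq` must be a binary_sequence")
  n <- length(seq$bits)
  if (n < 2) abort_estimation("LZ76 rate needs at least 2 bins")
  check_number(f, "f", lower = 0, strict_lower = TRUE)
  raw <- .lz76_complexity_cpp(seq$bits) * log2(n) / n
  new_itr_estimate(rate_per_symbol = min(max(raw, 0), 1), f = f,
                   method = "lz76", fit_intercept = raw,
                   clamped = (raw > 1 || raw < 0))
}

#' Mutual information between two binary sequences
#'
#' Plug-in estimate on position-wise joint words of length `L`:
#' \eqn{MI = H(X^L) + H(Y^L) - H(X^L, Y^L)} bits. `H(Y)` upper-bounds the
#' mutual information between the stimulus and the response, which is why the
#' response entropy rate is the quantity tracked by the pipeline.
#'
#' @param x,y [binary_sequence()] objects of equal length.
#' @param L word length in bins (default 1).
#' @return mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y, L = 1) {
  if (!inherits(x, "binary_sequence") || !inherits(y, "binary_sequence"))
    abort_invalid("`x` and `y` must be binary_sequence objects")
  if (length(x$bits) != length(y$bits))
    abort_invalid("`x` and `y` must have equal length")
  L <- as.integer(L)
  cx <- word_codes(x$bits, L)
  cy <- word_codes(y$bits, L)
  joint <- cx * 2^L + cy
  mi <- entropy_from_codes(cx) + entropy_from_codes(cy) -
    entropy_from_codes(joint)
  max(mi, 0)
}

#' @export
print.itr_estimate <- function(x, ...) {
  cat(sprintf("<itr_estimate> %s: %.4f bits/bin = %.2f bits/s (f = %g/s)\n",
              x$method, x$rate_per_symbol, x$rate_per_second, x$f))
  if (isTRUE(x$clamped))
    cat(sprintf("  note: raw intercept %.4f clamped into [0, 1]\n",
                x$fit_intercept))
  invisible(x)
}

#' @export
summary.itr_estimate <- function(object, ...) {
  print(object)
  if (!is.null(object$points)) {
    cat(sprintf("  fit over L = {%s}: slope %.4f, intercept %.4f, rms %.2g\n",
                paste(object$L_used, collapse = ","),
                object$fit_slope, object$fit_intercept, object$rms_residual))
    print(object$points, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.itr_estimate <- function(object, ...) {
  c(intercept = object$fit_intercept, slope = object$fit_slope)
}

#' @export
residuals.itr_estimate <- function(object, ...) {
  if (is.null(object$points)) return(numeric(0))
  object$points$y - object$points$fitted
}

#' Plot the direct-method extrapolation
#'
#' Shows the normalized block entropies \eqn{H(L)/L} against \eqn{1/L} with
#' the fitted line; the intercept at \eqn{1/L = 0} is the entropy rate.
#'
#' @param x an `itr_estimate` produced by [direct_method_rate()].
#' @param ... passed to [plot()].
#' @export
plot.itr_estimate <- function(x, ...) {
  if (is.null(x$points))
    abort_invalid("no fitted points to plot for this estimate")
  plot(x$points$x, x$points$y, xlim = c(0, max(x$points$x)),
       ylim = range(c(0, x$points$y, x$rate_per_symbol)),
       xlab = "1 / L", ylab = "H(L) / L  [bits/bin]",
       main = sprintf("Direct method: h = %.4f bits/bin", x$rate_per_symbol),
       ...)
  abline(a = x$fit_intercept, b = x$fit_slope, lty = 2)
  points(0, x$rate_per_symbol, pch = 19)
  invisible(x)
}
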