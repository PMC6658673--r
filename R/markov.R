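#' Two-state Markov spike source
#'
#' Specification of a binary (no-spike/spike) Markov chain at bin resolution
#' `bin_width`, the package's analytic test oracle: its stationary law and
#' entropy rate are available in closed form. With symmetric transition
#' probabilities above 0.9 the chain emits nearly periodic `0101...`
#' sequences — a high firing rate carrying almost no information, the
#' canonical counter-example to equating spike rate with information rate.
#'
#' @param p01 probability of the transition no-spike to spike, per bin.
#' @param p10 probability of the transition spike to no-spike, per bin.
#' @param bin_width bin width in seconds (default 1/80 s).
#' @return an object of class `markov_spec`.
#' @export
markov_spec <- function(p01, p10, bin_width = 0.0125) {
  check_number(p01, "p01", lower = 0, upper = 1)
  check_number(p10, "p10", lower = 0, upper = 1)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  structure(list(p01 = p01, p10 = p10, bin_width = bin_width),
            class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf("<markov_spec> p01 = %g, p10 = %g, bin %g ms\n",
              x$p01, x$p10, x$bin_width * 1000))
  if (x$p01 + x$p10 > 0) {
    st <- markov_stationary(x)
    cat(sprintf("  stationary P(spike) = %.4f, entropy rate %.4f bits/bin\n",
                st[["pi1"]], markov_entropy_rate(x)$rate_per_symbol))
  }
  invisible(x)
}

#' Stationary law of a two-state Markov source
#'
#' Closed form: \eqn{\pi_1 = p_{01}/(p_{01}+p_{10})},
#' \eqn{\pi_0 = p_{10}/(p_{01}+p_{10})}.
#'
#' @param spec a [markov_spec()] with `p01 + p10 > 0`.
#' @return named numeric `c(pi0, pi1)`.
#' @export
markov_stationary <- function(spec) {
  if (!inherits(spec, "markov_spec"))
    abort_invalid("`spec` must be a markov_spec")
  s <- spec$p01 + spec$p10
  if (s <= 0)
    abort_invalid("p01 + p10 must be positive for a unique stationary law")
  c(pi0 = spec$p10 / s, pi1 = spec$p01 / s)
}

#' Analytic entropy rate of a two-state Markov source
#'
#' \eqn{h = \pi_0 H_b(p_{01}) + \pi_1 H_b(p_{10})} bits per bin, the
#' stationary average of the per-state transition entropies. This is the
#' oracle against which the direct-method and LZ76 estimators are validated.
#'
#' @param spec a [markov_spec()].
#' @param f encoding frequency in bins/s (default `1/spec$bin_width`).
#' @return an `itr_estimate` with `method = "analytic"`.
#' @export
markov_entropy_rate <- function(spec, f = 1 / spec$bin_width) {
  st <- markov_stationary(spec)
  h <- st[["pi0"]] * binary_entropy(spec$p01) +
    st[["pi1"]] * binary_entropy(spec$p10)
  new_itr_estimate(rate_per_symbol = h, f = f, method = "analytic")
}

#' Exact block-entropy curve of a two-state Markov source
#'
#' For a stationary Markov chain the block entropy is linear in the block
#' length: \eqn{H(L) = H_b(\pi_1) + (L-1)h}, so the direct-method points
#' \eqn{(1/L, H(L)/L)} lie exactly on a line with intercept \eqn{h}. Used as
#' an exact oracle for the extrapolation step.
#'
#' @param spec a [markov_spec()].
#' @param L_set block lengths.
#' @return a `block_entropy_curve` (with `source_length = Inf`).
#' @export
markov_block_entropy <- function(spec, L_set = 1:6) {
  st <- markov_stationary(spec)
  h <- markov_entropy_rate(spec)$rate_per_symbol
  L_set <- sort(unique(as.integer(L_set)))
  H <- binary_entropy(st[["pi1"]]) + (L_set - 1) * h
  structure(list(points = data.frame(L = L_set, H = H), source_length = Inf),
            class = "block_entropy_curve", dropped_L = integer(0))
}

#' Simulate a binary sequence from a Markov spike source
#'
#' The first bin is drawn from the stationary law (unless `start_state` is
#' forced); subsequent bins follow the transition matrix.
#'
#' @param spec a [markov_spec()].
#' @param n_bins number of bins to generate (>= 1).
#' @param seed optional RNG seed (the caller's RNG stream is restored).
#' @param start_state optional forced first state (0 or 1). Required when
#'   `p01 + p10 == 0`, where no unique stationary law exists.
#' @return a [binary_sequence()] at the spec's `bin_width`.
#' @export
simulate_markov_train <- function(spec, n_bins, seed = NULL,
                                  start_state = NULL) {
  if (!inherits(spec, "markov_spec"))
    abort_invalid("`spec` must be a markov_spec")
  n_bins <- as.integer(check_number(n_bins, "n_bins", lower = 1))
  if (!is.null(start_state) && !start_state %in% c(0, 1))
    abort_invalid("`start_state` must be 0 or 1")
  with_seed(seed, {
    start <- if (!is.null(start_state)) {
      as.integer(start_state)
    } else {
      st <- markov_stationary(spec)  # errors if p01 + p10 == 0
      as.integer(runif(1) < st[["pi1"]])
    }
    bits <- .markov_bits_cpp(n_bins, spec$p01, spec$p10, start)
    binary_sequence(bits, spec$bin_width, t_origin = 0)
  })
}

#' Simulate method for Markov spike sources
#'
#' @param object a [markov_spec()].
#' @param nsim number of independent sequences.
#' @param seed optional RNG seed.
#' @param n_bins bins per sequence.
#' @param ... unused.
#' @return a list of [binary_sequence()] objects (length `nsim`).
#' @export
simulate.markov_spec <- function(object, nsim = 1, seed = NULL,
                                 n_bins = 400, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      simulate_markov_train(object, n_bins))
  })
}
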