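# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Binary entropy, closed form.
hb <- function(p) {
  term <- function(q) if (q > 0) -q * log2(q) else 0
  term(p) + term(1 - p)
}

# Analytic entropy rate of a two-state chain (stationary average of the
# per-state transition entropies).
markov_rate_oracle <- function(p01, p10) {
  pi1 <- p01 / (p01 + p10)
  (1 - pi1) * hb(p01) + pi1 * hb(p10)
}

# Brute-force overlapping word counts by string slicing.
count_words_naive <- function(bits, L) {
  s <- paste(bits, collapse = "")
  words <- vapply(seq_len(nchar(s) - L + 1),
                  function(i) substr(s, i, i + L - 1), character(1))
  table(words)
}

entropy_naive <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# LZ76 phrase count by the quadratic textbook scan (Kaspar-Schuster),
# usable only for short sequences.
lz76_naive <- function(bits) {
  n <- length(bits)
  if (n == 0) return(0L)
  s <- paste(bits, collapse = "")
  c_n <- 1L
  i <- 1L  # start of current phrase (after the first symbol)
  p <- 2L
  while (p <= n) {
    k <- 0L
    # extend the phrase while s[p..p+k] occurs in s[1..p+k-1]
    while (p + k <= n &&
           grepl(substr(s, p, p + k), substr(s, 1, p + k - 1),
                 fixed = TRUE)) {
      k <- k + 1L
    }
    c_n <- c_n + 1L
    p <- p + k + 1L
  }
  c_n
}

# Small helper: spike train with one spike at each requested bin centre.
train_from_bits <- function(bits, bin_width = 0.0125) {
  centers <- (which(bits == 1L) - 0.5) * bin_width
  spike_train(centers, duration = length(bits) * bin_width)
}
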