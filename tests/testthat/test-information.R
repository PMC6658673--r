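test_that("plug-in entropy matches hand computations", {
  fair <- structure(list(word_length = 1L, counts = c("0" = 1L, "1" = 1L),
                         total = 2L), class = "word_distribution")
  expect_equal(plugin_entropy(fair), 1.0)
  wd <- count_words(binary_sequence(c(0L, 1L, 0L, 1L, 1L), 0.0125), 2)
  expect_equal(plugin_entropy(wd), 1.5)  # -(1/2)lg(1/2) - 2*(1/4)lg(1/4)
  single <- structure(list(word_length = 3L, counts = c("010" = 9L),
                           total = 9L), class = "word_distribution")
  expect_equal(plugin_entropy(single), 0)
  empty <- structure(list(word_length = 1L, counts = integer(0), total = 0L),
                     class = "word_distribution")
  expect_error(plugin_entropy(empty), class = "spikecode_invalid_argument")
})

test_that("word self-information is -log2(p)", {
  expect_equal(word_information(1), 0)
  expect_equal(word_information(0.25), 2)
  expect_equal(word_information(0.1), log2(10))
  expect_equal(word_information(0.1), 3.321928, tolerance = 1e-6)
  expect_error(word_information(0), class = "spikecode_invalid_argument")
  expect_error(word_information(-0.5), class = "spikecode_invalid_argument")
})

test_that("block-entropy curves reproduce analytic limits", {
  alt <- binary_sequence(rep(c(0L, 1L), 1000), 0.0125)
  curve <- block_entropy_curve(alt, 1:4)
  expect_equal(curve$points$H, rep(1, 4), tolerance = 1e-3)
  zeros <- binary_sequence(rep(0L, 500), 0.0125)
  expect_equal(block_entropy_curve(zeros, 1:5)$points$H, rep(0, 5))
  set.seed(3)
  coin <- binary_sequence(sample(0:1, 1e5, replace = TRUE), 0.0125)
  cc <- block_entropy_curve(coin, 1:8)
  expect_equal(cc$points$H, 1:8, tolerance = 0.02 / 8)
  # undersampling guard drops unsupported block lengths
  short <- binary_sequence(sample(0:1, 200, replace = TRUE), 0.0125)
  sc <- block_entropy_curve(short, 1:10)
  expect_lt(max(sc$points$L), 10L)
  expect_true(length(attr(sc, "dropped_L")) > 0)
  tiny <- binary_sequence(c(0L, 1L, 0L, 1L, 1L), 0.0125)
  expect_error(block_entropy_curve(tiny, 1:2),
               class = "spikecode_estimation_failure")
  expect_equal(block_entropy_curve(tiny, 1:2, guard = FALSE)$points$H[1],
               hb(3 / 5))
})

test_that("direct method extrapolates H(L)/L against 1/L to the rate", {
  # fair coin: H(L) = L exactly, so the fitted line is flat at 1 bit/bin
  coin <- direct_method_rate(markov_block_entropy(markov_spec(0.5, 0.5), 1:6),
                             f = 80)
  expect_equal(coin$fit_slope, 0, tolerance = 1e-12)
  expect_equal(coin$rate_per_symbol, 1)
  expect_equal(coin$rate_per_second, 80)
  # deterministic alternation: H(L) = 1, points (1/L, 1/L), intercept 0
  alt <- direct_method_rate(markov_block_entropy(markov_spec(1, 1), 1:6),
                            f = 80)
  expect_equal(alt$fit_slope, 1, tolerance = 1e-12)
  expect_equal(alt$rate_per_symbol, 0)
  # asymmetric chain: intercept equals the stationary transition entropy
  spec <- markov_spec(0.3, 0.4)
  est <- direct_method_rate(markov_block_entropy(spec, 1:6), f = 80)
  expect_equal(est$rate_per_symbol, markov_rate_oracle(0.3, 0.4),
               tolerance = 1e-10)
  expect_equal(est$rate_per_symbol, 0.9197, tolerance = 1e-4)
  one_pt <- structure(list(points = data.frame(L = 1L, H = 1), source_length = 10),
                      class = "block_entropy_curve")
  expect_error(direct_method_rate(one_pt, 80),
               class = "spikecode_estimation_failure")
})

test_that("itr_estimate objects expose fit diagnostics through methods", {
  est <- direct_method_rate(markov_block_entropy(markov_spec(0.3, 0.4), 1:6),
                            f = 80)
  expect_s3_class(est, "itr_estimate")
  expect_named(coef(est), c("intercept", "slope"))
  expect_equal(length(residuals(est)), 6L)
  expect_lt(max(abs(residuals(est))), 1e-10)
  expect_output(print(est), "bits/s")
  expect_output(summary(est), "slope")
})

test_that("markov stationary law and entropy rate are closed-form", {
  expect_equal(markov_stationary(markov_spec(0.95, 0.95)),
               c(pi0 = 0.5, pi1 = 0.5))
  expect_equal(markov_stationary(markov_spec(0.3, 0.4)),
               c(pi0 = 4 / 7, pi1 = 3 / 7))
  expect_equal(markov_stationary(markov_spec(1, 1)), c(pi0 = 0.5, pi1 = 0.5))
  expect_error(markov_stationary(markov_spec(0, 0)),
               class = "spikecode_invalid_argument")
  expect_equal(markov_entropy_rate(markov_spec(1, 1))$rate_per_symbol, 0)
  expect_equal(markov_entropy_rate(markov_spec(0.5, 0.5))$rate_per_symbol, 1)
  expect_equal(markov_entropy_rate(markov_spec(0.95, 0.95))$rate_per_symbol,
               hb(0.95))
  expect_equal(markov_entropy_rate(markov_spec(0.95, 0.95))$rate_per_symbol,
               0.2864, tolerance = 1e-4)
  # rate_per_second scales by the encoding frequency
  expect_equal(markov_entropy_rate(markov_spec(0.5, 0.5), f = 80)$rate_per_second,
               80)
})

test_that("LZ76 phrase counts match the quadratic textbook parser", {
  expect_equal(lz76_complexity(rep(0L, 100)), 2L)
  expect_equal(lz76_complexity(rep(c(0L, 1L), 50)), 3L)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    bits <- sample(0:1, n, replace = TRUE,
                   prob = c(0.5, 0.5) + runif(1, -0.3, 0.3) * c(1, -1))
    expect_identical(lz76_complexity(bits), lz76_naive(bits))
  }
})

test_that("normalized LZ76 complexity estimates the entropy rate", {
  zeros <- binary_sequence(rep(0L, 1e4), 0.0125)
  expect_lt(lz76_rate(zeros, 80)$rate_per_symbol, 0.01)
  set.seed(8)
  coin <- binary_sequence(sample(0:1, 1e5, replace = TRUE), 0.0125)
  expect_equal(lz76_rate(coin, 80)$rate_per_symbol, 1, tolerance = 0.1)
  sq <- simulate_markov_train(markov_spec(0.3, 0.4), 1e5, seed = 21)
  d <- direct_method_rate(block_entropy_curve(sq), 80)$rate_per_symbol
  l <- lz76_rate(sq, 80)$rate_per_symbol
  expect_lt(abs(l - d), 0.1)
})

test_that("plug-in mutual information obeys the Shannon identities", {
  set.seed(12)
  x <- binary_sequence(sample(0:1, 2e4, replace = TRUE), 0.0125)
  expect_equal(mutual_information(x, x, 1),
               plugin_entropy(count_words(x, 1)))
  y_comp <- binary_sequence(1L - x$bits, 0.0125)
  expect_equal(mutual_information(x, y_comp, 1),
               plugin_entropy(count_words(x, 1)))
  y_ind <- binary_sequence(sample(0:1, 2e4, replace = TRUE), 0.0125)
  expect_lte(mutual_information(x, y_ind, 1), 0.01)
  short <- binary_sequence(c(0L, 1L), 0.0125)
  expect_error(mutual_information(x, short, 1),
               class = "spikecode_invalid_argument")
  # H of either marginal upper-bounds MI, for dependent pairs too
  for (flip_p in c(0.1, 0.4)) {
    flips <- sample(0:1, 2e4, replace = TRUE, prob = c(1 - flip_p, flip_p))
    y_dep <- binary_sequence(as.integer(xor(x$bits, flips)), 0.0125)
    mi <- mutual_information(x, y_dep, 1)
    expect_gte(mi, 0)
    expect_lte(mi, plugin_entropy(count_words(x, 1)) + 1e-12)
    expect_lte(mi, plugin_entropy(count_words(y_dep, 1)) + 1e-12)
  }
})

test_that("block entropies grow and normalized entropies shrink with L", {
  for (p in list(c(0.2, 0.6), c(0.5, 0.5), c(0.9, 0.9))) {
    an <- markov_block_entropy(markov_spec(p[1], p[2]), 1:8)$points
    expect_true(all(diff(an$H) >= -1e-12))
    expect_true(all(diff(an$H / an$L) <= 1e-12))
  }
  sq <- simulate_markov_train(markov_spec(0.3, 0.5), 1e4, seed = 31)
  emp <- block_entropy_curve(sq, 1:6)$points
  expect_true(all(diff(emp$H) >= -0.02))
  expect_true(all(diff(emp$H / emp$L) <= 0.02))
})
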