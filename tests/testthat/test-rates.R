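test_that("firing rate is the raw count over the window length", {
  tr <- spike_train(seq(0.05, 4.95, length.out = 40), duration = 6)
  expect_equal(firing_rate(tr, 0, 5), 8)  # 40 spikes / 5 s
  expect_equal(firing_rate(tr, 5, 1), 0)
  expect_error(firing_rate(tr, 3, 5), class = "spikecode_out_of_range")
  set.seed(2)
  rates <- vapply(1:1000, function(j) {
    n <- rpois(1, 100)
    firing_rate(spike_train(sort(runif(n, 0, 5)), 5), 0, 5)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 20), 0.3)
  # additivity: counts over adjacent windows sum over their union
  expect_equal(firing_rate(tr, 0, 2) * 2 + firing_rate(tr, 2, 2) * 2,
               firing_rate(tr, 0, 4) * 4)
})

test_that("an 8-s segment supports a 3-s sliding span, a 32-s one 27 s", {
  tr <- spike_train(seq(0.1, 7.9, by = 0.05), duration = 8)
  fr <- sliding_metric_series(tr, "FR", window_T = 5, stride = 0.0125)
  expect_equal(min(fr$times), 0)
  expect_equal(max(fr$times), 3)
  expect_length(fr$times, 241L)
  long <- spike_train(seq(0.1, 31.9, by = 0.05), duration = 32)
  fr32 <- sliding_metric_series(long, "FR", window_T = 5, stride = 0.0125)
  expect_equal(max(fr32$times), 27)
  short <- spike_train(c(0.5, 1.5), duration = 4)
  expect_error(sliding_metric_series(short, "FR", window_T = 5),
               class = "spikecode_estimation_failure")
})

test_that("stationary inputs give flat FR and near-zero ITR series", {
  # strictly periodic train (off the bin grid): every window holds the
  # same count
  tr <- spike_train(seq(0.101, 7.99, by = 0.2), duration = 8)
  fr <- sliding_metric_series(tr, "FR", window_T = 5, stride = 0.0125)
  expect_equal(sd(fr$values), 0)
  expect_equal(unique(fr$values), 5)
  # deterministic alternation at the bin scale: ITR extrapolates to 0
  alt <- train_from_bits(rep(c(0L, 1L), 320))
  itr <- sliding_metric_series(alt, "ITR", window_T = 5, stride = 0.0125)
  expect_lt(max(itr$values), 1e-6)
  # ITR is bounded by the encoding frequency
  set.seed(9)
  noisy <- spike_train(sort(runif(600, 0, 8)), duration = 8)
  itr2 <- sliding_metric_series(noisy, "ITR", window_T = 5, stride = 0.25)
  expect_true(all(itr2$values <= 80))
  expect_true(all(itr2$values >= 0))
})

test_that("trial averaging gives pointwise mean, SD and a CV summary", {
  mk <- function(v) rate_series(c(0, 0.25), v, 5, 0.25, "FR")
  same <- trial_average(list(mk(c(3, 4)), mk(c(3, 4)), mk(c(3, 4))))
  expect_equal(same$sd$values, c(0, 0))
  expect_equal(same$cv_percent, 0)
  two <- trial_average(list(mk(c(2, 2)), mk(c(4, 4))))
  expect_equal(two$mean$values, c(3, 3))
  expect_equal(two$sd$values, c(1, 1))
  expect_equal(two$cv_percent, 100 / 3)
  expect_error(trial_average(list(mk(c(1, 2)),
                                  rate_series(c(0, 0.5), c(1, 2), 5, 0.5,
                                              "FR"))),
               class = "spikecode_invalid_argument")
  expect_error(trial_average(list()), class = "spikecode_invalid_argument")
})

test_that("windowed PCC respects affine invariance and flags degeneracy", {
  set.seed(4)
  n <- 400L
  a <- rate_series((0:(n - 1)) * 0.0125, cumsum(rnorm(n))^2 + 1, 5, 0.0125,
                   "ITR")
  b2 <- rate_series(a$times, 2 * a$values + 1, 5, 0.0125, "ITR")
  expect_equal(windowed_pcc(a, b2, 0.25)$values,
               rep(1, n - 19L), tolerance = 1e-10)
  bneg <- rate_series(a$times, max(a$values) - a$values, 5, 0.0125, "ITR")
  expect_equal(windowed_pcc(a, bneg, 0.25)$values,
               rep(-1, n - 19L), tolerance = 1e-10)
  expect_equal(summary_pcc(a, b2), 1)
  expect_equal(summary_pcc(a, bneg), -1)
  # zero-variance windows are flagged, not fabricated
  flat <- rate_series(a$times, rep(2, n), 5, 0.0125, "FR")
  wp <- windowed_pcc(a, flat, 0.25)
  expect_true(all(is.na(wp$values)))
  expect_equal(wp$n_undefined, length(wp$values))
  expect_true(is.na(summary_pcc(a, flat)))
  expect_error(windowed_pcc(a, rate_series(a$times + 1, a$values, 5,
                                           0.0125, "FR"), 0.25),
               class = "spikecode_invalid_argument")
  expect_error(windowed_pcc(a, b2, 0.0125),
               class = "spikecode_invalid_argument")
})

test_that("windowed PCC of independent noise averages to zero", {
  set.seed(14)
  n <- 5000L
  a <- rate_series((0:(n - 1)) * 0.0125, runif(n), 5, 0.0125, "ITR")
  b <- rate_series(a$times, runif(n), 5, 0.0125, "FR")
  wp <- windowed_pcc(a, b, 0.25)
  expect_lt(abs(mean(wp$values, na.rm = TRUE)), 0.05)
})

test_that("spot sizes fall into the small/medium/large categories", {
  expect_equal(as.character(spot_category(c(0.39, 0.98, 1.0, 2.0, 2.54))),
               c("small", "small", "medium", "medium", "large"))
  expect_error(spot_category(-1), class = "spikecode_invalid_argument")
})

test_that("spot-size summaries report per-category ranges", {
  res <- data.frame(
    polarity = c("ON", "ON", "OFF", "OFF"),
    spot_size = c(0.5, 0.8, 0.5, 2.6),
    itr = c(50, 58, 16, 20), fr = c(14, 18, 3, 4),
    pcc = c(0.35, 0.40, 0.60, 0.65))
  s <- summarize_by_spot_size(res)
  expect_s3_class(s, "spot_summary")
  on_small <- s[s$polarity == "ON" & s$category == "small", ]
  expect_equal(on_small$itr_min, 50)
  expect_equal(on_small$itr_max, 58)
  expect_equal(on_small$n, 2L)
  # one condition collapses to a point range
  off_large <- s[s$polarity == "OFF" & s$category == "large", ]
  expect_equal(off_large$pcc_min, off_large$pcc_max)
  # empty categories are omitted
  expect_false("medium" %in% s$category)
  expect_error(summarize_by_spot_size(res[, -3]),
               class = "spikecode_invalid_argument")
})
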