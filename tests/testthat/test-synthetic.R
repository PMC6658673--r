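test_that("luminance series have the right length, seeding and no memory", {
  s1 <- gen_luminance(160, 8, seed = 1)
  expect_length(s1$values, 1280L)
  expect_equal(s1$duration, 8)
  expect_true(all(s1$values >= 0))
  expect_identical(gen_luminance(160, 8, seed = 1)$values, s1$values)
  s2 <- gen_luminance(160, 8, seed = 2)
  expect_false(identical(s1$values, s2$values))
  lag1 <- function(x) cor(x[-length(x)], x[-1])
  expect_lt(abs(lag1(s1$values)), 0.1)
  expect_lt(abs(lag1(s2$values)), 0.1)
  expect_error(gen_luminance(-1, 8), class = "spikecode_invalid_argument")
  expect_error(gen_luminance(160, 0), class = "spikecode_invalid_argument")
})

test_that("trial schedules interleave frozen repeats with fresh uniques", {
  p <- trial_protocol("RU", n_repeat_trials = 3, n_unique_trials = 3)
  sched <- gen_trial_stimuli(p, frame_rate = 40, seed = 5)
  expect_equal(vapply(sched, `[[`, character(1), "label"),
               c("R", "U", "R", "U", "R", "U"))
  r_vals <- lapply(sched[c(1, 3, 5)], function(e) e$stimulus$values)
  expect_identical(r_vals[[1]], r_vals[[2]])
  expect_identical(r_vals[[1]], r_vals[[3]])
  u_vals <- lapply(sched[c(2, 4, 6)], function(e) e$stimulus$values)
  expect_false(identical(u_vals[[1]], u_vals[[2]]))

  p2 <- trial_protocol("RRRRU", n_unique_trials = 2)
  sched2 <- gen_trial_stimuli(p2, frame_rate = 40, seed = 5)
  expect_equal(vapply(sched2, `[[`, character(1), "label"),
               rep(c("R", "R", "R", "R", "U"), 2))
  expect_equal(sum(vapply(sched2, `[[`, character(1), "label") == "U"),
               p2$n_unique_trials)
  expect_error(trial_protocol("XY"), class = "spikecode_invalid_argument")
  expect_error(trial_protocol("RU", n_repeat_trials = 3,
                              n_unique_trials = 5),
               class = "spikecode_invalid_argument")
})

test_that("markov simulation follows the transition law", {
  # deterministic alternation from a forced start
  alt <- simulate_markov_train(markov_spec(1, 1), 6, seed = 1,
                               start_state = 0)
  expect_identical(alt$bits, c(0L, 1L, 0L, 1L, 0L, 1L))
  # absorbing all-zero chain
  z <- simulate_markov_train(markov_spec(0, 0), 6, seed = 1, start_state = 0)
  expect_identical(z$bits, rep(0L, 6))
  expect_error(simulate_markov_train(markov_spec(0, 0), 6, seed = 1),
               class = "spikecode_invalid_argument")
  # stationary spike fraction of the near-periodic symmetric chain
  sq <- simulate_markov_train(markov_spec(0.95, 0.95), 1e5, seed = 7)
  expect_equal(mean(sq$bits), 0.5, tolerance = 0.01 / 0.5)
  expect_identical(simulate_markov_train(markov_spec(0.95, 0.95), 1e5,
                                         seed = 7)$bits, sq$bits)
  # empirical transition frequencies converge to (p01, p10)
  for (p in list(c(0.3, 0.4), c(0.8, 0.2))) {
    sq <- simulate_markov_train(markov_spec(p[1], p[2]), 1e5, seed = 11)
    b <- sq$bits
    from0 <- b[-length(b)] == 0L
    expect_equal(mean(b[-1][from0]), p[1], tolerance = 0.015 / p[1])
    expect_equal(mean(b[-1][!from0] == 0L), p[2], tolerance = 0.015 / p[2])
  }
})

test_that("rate-code cells are Poisson-like with refractoriness", {
  stim <- gen_luminance(160, 8, seed = 3)
  spec <- cell_spec("ON", "rate_code", mean_rate = 20, gain = 0,
                    refractory = 0)
  counts <- vapply(1:200, function(j)
    length(simulate_rate_code_cell(spec, stim, seed = j)$times), numeric(1))
  expect_lt(abs(mean(counts) - 160), 3)  # E = 20 spikes/s * 8 s
  spec_r <- cell_spec("ON", "rate_code", mean_rate = 20, gain = 0,
                      refractory = 0.004)
  tr <- simulate_rate_code_cell(spec_r, stim, seed = 1)
  expect_true(all(diff(tr$times) >= 0.004 - 1e-12))
  expect_error(simulate_rate_code_cell(cell_spec("ON", "temporal_code"),
                                       stim, seed = 1),
               class = "spikecode_invalid_argument")
})

test_that("ON and OFF rate-code cells respond with opposite sign", {
  stim <- gen_luminance(160, 8, seed = 9)
  on <- cell_spec("ON", "rate_code", mean_rate = 30, gain = 20)
  off <- cell_spec("OFF", "rate_code", mean_rate = 30, gain = 20)
  bin <- function(tr) tabulate(floor(tr$times / 0.25) + 1L, nbins = 32L)
  r_on <- rowMeans(vapply(1:30, function(j)
    bin(simulate_rate_code_cell(on, stim, seed = j)), numeric(32)))
  r_off <- rowMeans(vapply(1:30, function(j)
    bin(simulate_rate_code_cell(off, stim, seed = 100 + j)), numeric(32)))
  expect_lt(cor(r_on, r_off), 0)
})

test_that("temporal-code cells modulate pattern, not rate", {
  stim <- gen_luminance(160, 8, seed = 4)
  rate_at <- function(gain) {
    spec <- cell_spec("ON", "temporal_code", mean_rate = 15, gain = gain)
    mean(vapply(1:100, function(j)
      length(simulate_temporal_code_cell(spec, stim, seed = j)$times) / 8,
      numeric(1)))
  }
  r0 <- rate_at(0)
  r5 <- rate_at(5)
  expect_lt(abs(r5 - r0) / r0, 0.05)
  expect_lt(abs(r0 - 15) / 15, 0.05)

  # ISI irregularity follows the integrated stimulus level
  spec <- cell_spec("ON", "temporal_code", mean_rate = 15, gain = 5)
  eff <- cell_contrast(spec, stim)
  isis <- c(); levels <- c()
  for (j in 1:40) {
    tr <- simulate_temporal_code_cell(spec, stim, seed = 500 + j)
    if (length(tr$times) < 3) next
    isi <- diff(tr$times)
    lev <- eff[pmin(floor(tr$times[-length(tr$times)] * 160) + 1L, 1280L)]
    isis <- c(isis, isi); levels <- c(levels, lev)
  }
  terc <- cut(levels, quantile(levels, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  cv <- tapply(isis, terc, function(x) sd(x) / mean(x))
  expect_gt(diff(range(cv)), 0.3)

  tr <- simulate_temporal_code_cell(spec, stim, seed = 2)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$times >= 0 & tr$times < 8))
  expect_identical(simulate_temporal_code_cell(spec, stim, seed = 2)$times,
                   tr$times)
  expect_error(simulate_temporal_code_cell(cell_spec("ON", "rate_code"),
                                           stim, seed = 1),
               class = "spikecode_invalid_argument")
})

test_that("rate-code firing tracks the stimulus more strongly with gain", {
  stim <- gen_luminance(160, 8, seed = 6)
  binned_rate <- function(gain, seeds) {
    spec <- cell_spec("ON", "rate_code", mean_rate = 10, gain = gain,
                      spot_size = 2)
    rowMeans(vapply(seeds, function(j)
      tabulate(floor(simulate_rate_code_cell(spec, stim, seed = j)$times /
                       0.1) + 1L, nbins = 80L), numeric(80)))
  }
  stim_coarse <- colMeans(matrix(stim$values, nrow = 16))  # 0.1-s frames
  r_lo <- abs(cor(binned_rate(1, 1:40), stim_coarse))
  r_hi <- abs(cor(binned_rate(8, 41:80), stim_coarse))
  expect_gt(r_hi, r_lo)
})

test_that("spot-size attenuation is unimodal and normalized", {
  d <- c(0.3, 0.7, 1.5, 2, 3, 8, 20)
  a <- dog_attenuation(d)
  expect_true(all(a > 0 & a <= 1))
  expect_lt(a[1], a[4])            # small spots underdrive the center
  expect_lt(a[length(a)], max(a))  # very large spots recruit the surround
  expect_error(dog_attenuation(0), class = "spikecode_invalid_argument")
})
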