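test_that("IFF is the reciprocal interspike interval, one entry per ISI", {
  iff <- compute_iff(spike_train("B3", c(0, 0.1, 0.3)))
  expect_equal(iff$iff, c(10, 5))
  expect_equal(iff$t_start, c(0, 0.1))
  expect_equal(iff$t_end, c(0.1, 0.3))
  expect_equal(nrow(compute_iff(spike_train("B3", 1.0))), 0)
  reg <- compute_iff(regular_train(10, 2))
  expect_equal(nrow(reg), 20)
  expect_equal(reg$iff, rep(10, 20))
})

test_that("candidate scan follows the start/end threshold rule", {
  # constant 10 Hz train meets both B6/B9 thresholds throughout
  cand <- find_candidate_bursts(seq(0, 0.6, by = 0.1), 10, 5)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 0)
  expect_equal(cand$end, 0.6)
  expect_equal(cand$n_spikes, 7L)
  # B3 thresholds 8/2: burst ends when the IFF drops below 2 Hz and the
  # scan never restarts (no later ISI reaches 8 Hz)
  cand <- find_candidate_bursts(c(0, 0.1, 0.2, 0.8, 1.3), 8, 2)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 0)
  expect_equal(cand$end, 0.2)
  expect_equal(cand$n_spikes, 3L)
  # never reaches the start threshold
  expect_equal(nrow(find_candidate_bursts(c(0, 1, 2, 3), 8, 2)), 0)
  # two bursts separated by a long gap restart the scan
  cand <- find_candidate_bursts(c(seq(0, 0.5, 0.1), seq(3, 3.5, 0.1)), 8, 5)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$start, c(0, 3))
})

test_that("scanner agrees with the maximal-run oracle on random trains", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    times <- sort(cumsum(stats::rexp(n, rate = sample(c(2, 5, 10), 1))))
    f_end <- sample(c(2, 3, 5), 1)
    f_start <- f_end + sample(0:5, 1)
    got <- find_candidate_bursts(times, f_start, f_end)
    want <- oracle_candidates(times, f_start, f_end)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("burst detection is translation-equivariant", {
  set.seed(3)
  times <- sort(stats::runif(15, 0, 3))
  for (shift in c(-5, 2.5, 100)) {
    a <- find_candidate_bursts(times, 8, 5)
    b <- find_candidate_bursts(times + shift, 8, 5)
    expect_equal(b$start, a$start + shift, tolerance = 1e-9)
    expect_equal(b$end, a$end + shift, tolerance = 1e-9)
  }
})

test_that("discard applies to candidates, survivors are merged", {
  tr <- spike_train("B6/B9", c(seq(0, 0.6, 0.1), seq(1.0, 1.7, 0.1)))
  # 0.3 s candidate discarded by the duration filter
  short <- data.frame(start = 0, end = 0.3, n_spikes = 4L)
  expect_null(filter_and_merge(short, spike_train("x", c(0, .1, .2, .3))))
  # two-spike candidate discarded by the count filter
  two <- data.frame(start = 0, end = 0.6, n_spikes = 2L)
  expect_null(filter_and_merge(two, spike_train("x", c(0, 0.6))))
  # two surviving candidates merge into one burst spanning all spikes
  cand <- find_candidate_bursts(tr$times, 10, 5)
  expect_equal(nrow(cand), 2)
  b <- filter_and_merge(cand, tr)
  expect_equal(b$start, 0)
  expect_equal(b$end, 1.7)
  expect_equal(b$n_spikes, 15L)
  # all candidates discarded -> no burst even if their union is long
  frag <- spike_train("x", c(0, 0.1, 0.2, 2.0, 2.1, 2.2))
  cand <- find_candidate_bursts(frag$times, 8, 5)
  expect_null(filter_and_merge(cand, frag))
  # opposite order available for sensitivity analysis
  expect_s3_class(filter_and_merge(cand, frag, merge_first = TRUE), "burst")
})

test_that("final bursts satisfy the duration and spike-count floors", {
  set.seed(21)
  for (i in 1:100) {
    times <- sort(stats::runif(sample(3:30, 1), 0, 4))
    cand <- find_candidate_bursts(times, 8, 5)
    b <- filter_and_merge(cand, spike_train("u", times))
    if (!is.null(b)) {
      expect_gte(b$end - b$start, 0.5)
      expect_gte(b$n_spikes, 3)
    }
  }
})

test_that("B3 and B6/B9 combine by span union", {
  b69 <- burst("B6/B9", 1, 3, 21)
  expect_equal(combine_b3_b6b9(NULL, b69)$start, 1)
  expect_equal(combine_b3_b6b9(NULL, b69)$end, 3)
  expect_null(combine_b3_b6b9(NULL, NULL))
  b3 <- burst("B3", 1.5, 3.2, 10)
  t3 <- seq(1.5, 3.2, length.out = 10)
  t69 <- seq(1.0, 3.0, length.out = 21)
  comb <- combine_b3_b6b9(b3, burst("B6/B9", 1.0, 3.0, 21), t3, t69)
  expect_equal(comb$start, 1.0)
  expect_equal(comb$end, 3.2)
  expect_equal(comb$unit, "B3/B6/B9")
  expect_equal(comb$n_spikes, 31L)
})

test_that("mean burst rate is (n - 1) / duration", {
  expect_equal(mean_burst_rate(burst("u", 0, 3, 31)), 10)
  expect_equal(mean_burst_rate(burst("u", 0, 0.6, 7)), 10)
  expect_error(mean_burst_rate(burst("u", 0, 1, 1)), "degenerate")
})

test_that("smoothed rate has unit-mass kernels and conserves spike count", {
  one <- smooth_rate(spike_train("u", 0), grid_rate = 1000)
  expect_equal(max(one$rate), 1 / (0.2 * sqrt(2 * pi)), tolerance = 1e-4)
  expect_equal(one$time[which.max(one$rate)], 0, tolerance = 1e-3)
  none <- smooth_rate(spike_train("u", numeric()), from = 0, to = 1)
  expect_true(all(none$rate == 0))
  set.seed(9)
  times <- sort(stats::runif(100, 0, 10))
  sm <- smooth_rate(times, grid_rate = 100)
  integral <- sum(diff(sm$time) * (head(sm$rate, -1) + tail(sm$rate, -1)) / 2)
  expect_lt(abs(integral - 100) / 100, 0.01)
})
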