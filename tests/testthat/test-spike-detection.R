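test_that("zero-phase low-pass passes DC and is -3 dB at the cutoff", {
  sr <- 5000
  x <- rep(2.5, sr)
  expect_equal(lowpass(x, sr, 100), x, tolerance = 1e-6)
  tt <- (0:(4 * sr - 1)) / sr
  for (fc in c(50, 100)) {
    s <- sin(2 * pi * fc * tt)
    y <- lowpass(s, sr, fc)
    mid <- y[(sr):(3 * sr)]          # ignore filter edge transients
    ratio <- (max(mid) - min(mid)) / 2
    expect_equal(ratio, 1 / sqrt(2), tolerance = 0.02)
  }
  expect_error(lowpass(x, sr, 2500), "Nyquist")
})

test_that("a 300 Hz contaminant on an EMG-like burst is attenuated > 20 dB", {
  sr <- 5000
  tt <- (0:(2 * sr - 1)) / sr
  slow <- sin(2 * pi * 20 * tt) * exp(-((tt - 1) / 0.3)^2)  # burst envelope
  fast <- 0.5 * sin(2 * pi * 300 * tt)
  y <- lowpass(slow + fast, sr, 100)
  # residual 300 Hz power via quadrature projection
  proj <- function(x, f) {
    c(mean(x * sin(2 * pi * f * tt)), mean(x * cos(2 * pi * f * tt)))
  }
  before <- sum(proj(slow + fast, 300)^2)
  after <- sum(proj(y, 300)^2)
  expect_gt(10 * log10(before / after), 20)
  expect_length(y, length(tt))
})

test_that("window discriminators capture peaks in closed amplitude windows", {
  sr <- 5000
  rec <- toy_recording(sr, 1)
  rec$signals$BN2 <- render_spikes(rec$signals$BN2, c(0.2, 0.6), 50, sr)
  rec$signals$BN2 <- render_spikes(rec$signals$BN2, c(0.4, 0.8), 100, sr)
  big <- detect_spikes(rec, window_discriminator("u", "BN2", 80, 120))
  expect_equal(big$times, c(0.4, 0.8), tolerance = 1 / sr)
  # closed interval: a peak exactly at amp_lo is included
  at_lo <- detect_spikes(rec, window_discriminator("u", "BN2", 100, 120))
  expect_length(at_lo$times, 2)
  # empty amplitude overlap
  none <- detect_spikes(rec, window_discriminator("u", "BN2", 200, 300))
  expect_length(none$times, 0)
  # time window excludes the later peak
  early <- detect_spikes(rec,
                         window_discriminator("u", "BN2", 80, 120,
                                              t_lo = 0, t_hi = 0.5))
  expect_equal(early$times, 0.4, tolerance = 1 / sr)
  expect_error(detect_spikes(rec, window_discriminator("u", "XX", 0, 1)),
               "unknown channel")
})

test_that("noise-free synthetic spike counts match ground truth exactly", {
  cfg <- session_config(noise = c(nerve = 0, emg = 0, force = 0))
  ses <- generate_session(3, "loaded", cfg = cfg, seed = 4)
  trains <- apply_discriminator_set(ses$recording, default_discriminators())
  for (u in names(ses$unit_spikes)) {
    truth <- ses$unit_spikes[[u]]
    expect_equal(length(trains[[u]]$times), length(truth), label = u)
    expect_equal(trains[[u]]$times, truth, tolerance = 1.01 / 5000)
  }
})

test_that("detection ignores channels the discriminator does not reference", {
  sr <- 5000
  rec <- toy_recording(sr, 1)
  rec$signals$BN2 <- render_spikes(rec$signals$BN2, c(0.25, 0.5), 1, sr)
  d <- window_discriminator("u", "BN2", 0.8, 1.2)
  a <- detect_spikes(rec, d)
  rec$signals$EXTRA <- sin(2 * pi * 7 * (0:(n_samples(rec) - 1)) / sr)
  rec$roles <- c(rec$roles, EXTRA = "nerve")
  b <- detect_spikes(rec, d)
  expect_identical(a$times, b$times)
})

test_that("time windows exclude retraction-phase activity on the I2 channel", {
  sr <- 5000
  n <- 2 * sr
  rec <- recording(list(I2 = numeric(n)), c(I2 = "emg"), sr)
  # protraction-phase EMG peaks plus retraction-phase I4 crosstalk
  rec$signals$I2 <- render_spikes(rec$signals$I2, c(0.2, 0.3, 0.4), 1, sr,
                                  width = 0.012)
  rec$signals$I2 <- render_spikes(rec$signals$I2, c(1.2, 1.3, 1.4), 1, sr,
                                  width = 0.012)
  discs <- list(window_discriminator("I2", "I2", 0.2, 2,
                                     t_lo = 0, t_hi = 1.0))
  trains <- apply_discriminator_set(rec, discs, i2_prefilter = TRUE)
  expect_true(all(trains$I2$times <= 1.0))
  expect_length(trains$I2$times, 3)
})

test_that("disjoint discriminators partition all detected peaks", {
  sr <- 5000
  rec <- toy_recording(sr, 1)
  rec$signals$BN2 <- render_spikes(rec$signals$BN2, c(0.2, 0.6), 0.4, sr)
  rec$signals$BN2 <- render_spikes(rec$signals$BN2, c(0.4, 0.8), 1.0, sr)
  discs <- list(window_discriminator("small", "BN2", 0.3, 0.5),
                window_discriminator("large", "BN2", 0.8, 1.2))
  trains <- apply_discriminator_set(rec, discs, i2_prefilter = FALSE)
  all_times <- sort(c(trains$small$times, trains$large$times))
  everything <- detect_spikes(rec, window_discriminator("any", "BN2", 0.3,
                                                        1.2))
  expect_equal(all_times, everything$times)
})
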