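test_that("same seed gives identical sessions, different seeds differ", {
  a <- generate_session(2, "loaded", seed = 1)
  b <- generate_session(2, "loaded", seed = 1)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_session(2, "loaded", seed = 2)
  expect_false(identical(a$recording$signals$BN2, c$recording$signals$BN2))
})

test_that("a noise-free constant-rate burst renders to the exact spike count", {
  # one unit, 10 Hz for 1 s -> 11 spikes recovered by detection
  sr <- 5000
  rec <- recording(list(BN2 = numeric(2 * sr)), c(BN2 = "nerve"), sr)
  rec$signals$BN2 <- render_spikes(rec$signals$BN2, seq(0.5, 1.5, 0.1), 1, sr)
  st <- detect_spikes(rec, window_discriminator("u", "BN2", 0.5, 1.5))
  expect_length(st$times, 11)
  expect_equal(st$times, seq(0.5, 1.5, 0.1), tolerance = 1 / sr)
})

test_that("undefined-stage-I flags hit the requested fraction exactly", {
  expect_equal(sum(generate_undefined_stage1(20, 0)), 0)
  expect_equal(sum(generate_undefined_stage1(20, 1)), 20)
  flags <- generate_undefined_stage1(39, 7 / 39, seed = 5)
  expect_equal(sum(flags), 7)
  expect_identical(flags, generate_undefined_stage1(39, 7 / 39, seed = 5))
})

test_that("marked swallows lack the intermediate plateau and events 1/2", {
  cfg <- session_config(undefined_stage1_fraction = 1,
                        noise = c(nerve = 0, emg = 0, force = 0))
  ses <- generate_session(3, "loaded", cfg = cfg, seed = 6)
  expect_true(all(!vapply(ses$ground_truth, `[[`, logical(1),
                          "stage_I_defined")))
  expect_true(all(is.na(vapply(ses$ground_truth,
                               function(g) g$events[["e1"]], numeric(1)))))
  # the force between the preceding drop and the rise decays monotonically:
  # no dip-rise plateau structure
  f <- force_channel(ses$recording)
  sr <- ses$recording$sample_rate
  gt <- ses$ground_truth[[2]]
  i0 <- round(gt$v_start * sr) + 1L
  i1 <- round(gt$events[["e3"]] * sr) + 1L
  expect_true(all(diff(f[i0:i1]) <= 1e-9))
})

test_that("ground-truth bursts are recovered on noise-free renderings", {
  cfg <- session_config(noise = c(nerve = 0, emg = 0, force = 0))
  ses <- generate_session(2, "loaded", cfg = cfg, seed = 8)
  res <- analyze_session(ses$recording, ses$annotations)
  for (k in 1:2) {
    tb <- ses$ground_truth[[k]]$bursts
    for (i in seq_len(nrow(tb))) {
      u <- tb$unit[i]
      got <- res$measures[res$measures$unit == u &
                          res$measures$swallow == k, ]
      expect_equal(nrow(got), 1, label = paste(u, "swallow", k))
      # boundary error at most one interspike interval
      isi <- (tb$end[i] - tb$start[i]) / (tb$n_spikes[i] - 1)
      expect_lt(abs(got$start - tb$start[i]), isi + 1e-6)
      expect_lt(abs(got$end - tb$end[i]), isi + 1e-6)
    }
  }
})

test_that("configured retraction effects appear in the ground truth", {
  cfg <- session_config()
  nrep <- 12
  du <- dl <- ru <- rl <- numeric(nrep)
  for (i in seq_len(nrep)) {
    su <- generate_session(2, "unloaded", cfg = cfg, seed = 100 + i)
    sl <- generate_session(2, "loaded", cfg = cfg, seed = 200 + i)
    comb_u <- lapply(su$ground_truth, `[[`, "combined_b369")
    comb_l <- lapply(sl$ground_truth, `[[`, "combined_b369")
    du[i] <- mean(vapply(comb_u, function(cc) cc$end - cc$start, 1))
    dl[i] <- mean(vapply(comb_l, function(cc) cc$end - cc$start, 1))
    ru[i] <- mean(vapply(comb_u, `[[`, 1, "rate"))
    rl[i] <- mean(vapply(comb_l, `[[`, 1, "rate"))
  }
  expect_equal(mean(dl - du), cfg$delta_retraction, tolerance = 0.25)
  expect_equal(mean(rl - ru), cfg$delta_rate_b369, tolerance = 0.2)
})

test_that("different units never collide on a shared channel", {
  ses <- generate_session(3, "loaded", seed = 12)
  bn2 <- c("B38", "B6/B9", "B3")
  for (a in 1:2) for (b in (a + 1):3) {
    ta <- ses$unit_spikes[[bn2[a]]]; tb <- ses$unit_spikes[[bn2[b]]]
    if (!length(ta) || !length(tb)) next
    gap <- min(abs(outer(ta, tb, "-")))
    expect_gte(gap, 0.003)
  }
})

test_that("paired-table generator reproduces the configured effect", {
  tab <- generate_paired_table(2, 10, 1.65, between_sd = 0, within_sem = 0,
                               seed = 3)
  expect_equal(tab$loaded - tab$unloaded, c(1.65, 1.65))
  t1 <- generate_paired_table(5, 4, 1, 0.8, 0.2, seed = 9)
  t2 <- generate_paired_table(5, 4, 1, 0.8, 0.2, seed = 9)
  expect_identical(t1, t2)
  # effect recoverable on average
  diffs <- vapply(1:200, function(s)
    mean(with(generate_paired_table(5, 4, 1.65, 0.8, 0.2, seed = s),
              loaded - unloaded)), numeric(1))
  expect_equal(mean(diffs), 1.65, tolerance = 0.05)
})
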