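test_that("the five-stage worked example halves stage II and triples stage IV", {
  seg <- force_segmentation(e1 = 0, e2 = 1, e3 = 3, e4 = 5, e5 = 6,
                            v_end = 7)                     # stages 1,2,2,1,1
  m <- build_warp_loaded(seg, c(1, 1, 2, 3, 1))
  expect_equal(warp_times(m, c(0, 1, 3, 5, 6, 7)),
               c(0, 1, 2, 4, 7, 8))
  # stage II halved: a point 40% into stage II moves 40% into the 1 s target
  expect_equal(warp_times(m, 1.8), 1.4)
  # stage IV tripled
  expect_equal(warp_times(m, 5.5), 5.5)   # midpoint of IV -> midpoint of IV
  expect_equal(diff(warp_times(m, c(5, 6))), 3)
  # identity when source and target agree
  id <- build_warp_loaded(seg, c(1, 2, 2, 1, 1))
  xs <- seq(0, 7, by = 0.25)
  expect_equal(warp_times(id, xs), xs)
})

test_that("undefined stage I restricts the warp domain to the rise onward", {
  seg <- force_segmentation(e3 = 3, e4 = 5, e5 = 6, v_end = 7)
  m <- build_warp_loaded(seg, c(1, 1, 2, 3, 1))
  expect_equal(m$src[1], 3)
  expect_equal(warp_times(m, 3), 2)       # e3 aligned with every swallow
  expect_true(is.na(warp_times(m, 2.5)))  # pre-rise data dropped
  expect_error(warp_times(m, 2.5, clip = "error"), "domain")
})

test_that("unloaded warp rescales the whole swallow by the inward ratio", {
  ann <- data.frame(inward_start = 4, inward_end = 6)
  m <- build_warp_unloaded(ann, target_duration = 1)
  # 2 s of inward movement matched to 1 s: total duration halved
  expect_equal(warp_times_linear(m, c(4, 6)), c(0, 1))
  expect_equal(diff(warp_times_linear(m, c(2, 8))), 3)  # 6 s -> 3 s
  # burst at the inward midpoint maps to the target midpoint
  expect_equal(warp_times_linear(m, 5), 0.5)
  id <- build_warp_unloaded(ann, target_duration = 2)
  expect_equal(diff(warp_times_linear(id, c(0, 10))), 10)
  expect_error(build_warp_unloaded(data.frame(inward_start = NA,
                                              inward_end = NA), 1),
               "inward")
})

test_that("warps are order-preserving and exact at boundaries", {
  set.seed(14)
  for (i in 1:50) {
    nb <- sample(3:6, 1)
    src <- cumsum(c(0, stats::runif(nb - 1, 0.2, 3)))
    tgt <- cumsum(c(0, stats::runif(nb - 1, 0.2, 3)))
    m <- warp_map(src, tgt)
    expect_identical(warp_times(m, src), tgt)
    xs <- sort(stats::runif(20, min(src), max(src)))
    ys <- warp_times(m, xs)
    expect_true(all(diff(ys) >= 0))
  }
})

test_that("warped series are resampled correctly and bursts keep order", {
  seg <- force_segmentation(e1 = 0, e2 = 1, e3 = 3, e4 = 5, e5 = 6,
                            v_end = 7)
  m <- build_warp_loaded(seg, c(1, 1, 2, 3, 1))
  tt <- seq(0, 7, by = 0.01)
  out <- apply_warp(m, bursts = data.frame(unit = "B3", start = 3.2,
                                           end = 5.9),
                    series = data.frame(time = tt, value = tt))
  # series value at target time equals the source time that maps there
  expect_equal(out$series$value[out$series$time == 4], 5, tolerance = 1e-6)
  expect_lt(out$bursts$start, out$bursts$end)
  expect_equal(out$bursts$start, 2 + 0.2, tolerance = 1e-9)
})

test_that("aggregation of identical swallows is a fixed point", {
  seg <- force_segmentation(e1 = 0, e2 = 1, e3 = 2, e4 = 3, e5 = 4,
                            v_end = 5)
  td <- median_stage_durations(list(seg, seg, seg))
  expect_equal(unname(td), rep(1, 5))
  tt <- seq(0, 5, by = 0.01)
  w <- lapply(1:3, function(i) {
    m <- build_warp_loaded(seg, td)
    apply_warp(m, bursts = data.frame(unit = "u", start = 2.1, end = 3.9),
               series = data.frame(time = tt, value = sin(tt)))
  })
  agg <- aggregate_swallows(w)
  expect_equal(agg$traces$median, sin(agg$traces$time), tolerance = 1e-3)
  expect_equal(agg$traces$q25, agg$traces$q75)   # zero-width band
  expect_equal(agg$burst_timing$start_median, 2.1)
  expect_equal(agg$burst_timing$end_q75, 3.9)
})

test_that("pointwise quartiles follow the linear-interpolation convention", {
  w <- lapply(c(1, 2, 3), function(v) {
    list(bursts = NULL,
         series = data.frame(time = seq(0, 1, 0.1), value = rep(v, 11)))
  })
  agg <- aggregate_swallows(w)
  expect_true(all(abs(agg$traces$median - 2) < 1e-9))
  expect_true(all(abs(agg$traces$q25 - 1.5) < 1e-9))
  expect_true(all(abs(agg$traces$q75 - 2.5) < 1e-9))
  expect_true(all(agg$traces$q25 <= agg$traces$median &
                  agg$traces$median <= agg$traces$q75))
})

test_that("swallows with undefined stage I contribute no pre-rise data", {
  seg_full <- force_segmentation(e1 = 0, e2 = 1, e3 = 2, e4 = 3, e5 = 4,
                                 v_end = 5)
  seg_cut <- force_segmentation(e3 = 12, e4 = 13, e5 = 14, v_end = 15)
  segs <- list(seg_full, seg_full, seg_cut)
  bursts <- list(data.frame(unit = "u", start = 0.5, end = 3.5),
                 data.frame(unit = "u", start = 0.6, end = 3.6),
                 data.frame(unit = "u", start = 11.5, end = 13.5))
  agg <- normalize_loaded_cohort(segs, bursts)
  expect_equal(agg$n_dropped_pre_rise, 1)
  # the third swallow's burst starts before its warp domain -> NA start
  expect_equal(agg$burst_timing$n, 2)
})
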