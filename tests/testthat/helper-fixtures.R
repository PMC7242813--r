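# shared fixtures built in code

# perfectly regular spike train
regular_train <- function(rate, duration, unit = "B6/B9", start = 0) {
  spike_train(unit, seq(start, start + duration, by = 1 / rate))
}

# tiny two-channel recording with known peaks
toy_recording <- function(sample_rate = 5000, duration = 1) {
  n <- round(sample_rate * duration)
  ch1 <- numeric(n)
  recording(list(BN2 = ch1, RN = ch1), c(BN2 = "nerve", RN = "nerve"),
            sample_rate)
}

# independent oracle for the IFF-threshold burst scanner: maximal runs of
# consecutive ISIs with IFF >= f_end; each run containing at least one ISI
# with IFF >= f_start yields one candidate from the first such ISI's first
# spike to the run's last spike
oracle_candidates <- function(times, f_start, f_end) {
  if (length(times) < 2)
    return(data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer()))
  iff <- 1 / diff(times)
  r <- rle(iff >= f_end)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  out <- list()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    run <- starts[j]:stops[j]
    hit <- run[iff[run] >= f_start]
    if (!length(hit)) next
    s <- hit[1]               # candidate starts at this ISI's first spike
    e <- stops[j] + 1L        # ends at the run's last spike
    out[[length(out) + 1L]] <-
      data.frame(start = times[s], end = times[e], n_spikes = e - s + 1L)
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer()))
  do.call(rbind, out)
}

# independent naive Wilcoxon null: recursive distribution of the positive
# rank sum over all sign assignments
oracle_wilcoxon_p <- function(d, direction = "greater") {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(r)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    w <- sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    if (direction == "greater" && w >= W) total <- total + 1
    if (direction == "less" && w <= W) total <- total + 1
  }
  total / 2^n
}
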