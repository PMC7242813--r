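#' Default burst frequency thresholds per unit
#'
#' Start/end instantaneous-firing-frequency thresholds (Hz) used to delimit
#' bursts of each identified unit: B38 8/5, I2 10/5, B8a/b 3/3, B6/B9 10/5,
#' B3 8/2, B4/B5 3/3. A candidate burst begins when the IFF first reaches the
#' start frequency and ends when it later drops below the end frequency.
#' Values can be overridden per unit (some animals fire unusually slowly).
#'
#' @param overrides optional named list, e.g. \code{list("B3" = c(6, 2))},
#'   giving \code{c(f_start, f_end)} replacements.
#' @return data.frame with columns unit, f_start, f_end.
#' @export
default_thresholds <- function(overrides = NULL) {
  th <- data.frame(
    unit    = c("B38", "I2", "B8a/b", "B6/B9", "B3", "B4/B5"),
    f_start = c(8, 10, 3, 10, 8, 3),
    f_end   = c(5, 5, 3, 5, 2, 3))
  for (u in names(overrides)) {
    v <- overrides[[u]]
    if (u %in% th$unit) {
      th[th$unit == u, c("f_start", "f_end")] <- v
    } else {
      th <- rbind(th, data.frame(unit = u, f_start = v[1], f_end = v[2]))
    }
  }
  stopifnot(all(th$f_start >= th$f_end), all(th$f_end > 0))
  th
}

#' Read burst thresholds from a YAML file
#' @param path YAML file: a mapping unit -> [f_start, f_end].
#' @return data.frame as \code{\link{default_thresholds}}.
#' @export
read_thresholds <- function(path) {
  default_thresholds(yaml::read_yaml(path))
}

#' Instantaneous firing frequency series
#'
#' The IFF is the reciprocal of each interspike interval, assigned to that
#' interval: one entry per ISI, so a train of n spikes yields n − 1 values.
#'
#' @param train a \code{\link{spike_train}} or numeric vector of spike times.
#' @return data.frame with columns \code{t_start}, \code{t_end} (the two
#'   spikes bounding the interval) and \code{iff} (Hz).
#' @export
compute_iff <- function(train) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(t) < 2)
    return(data.frame(t_start = numeric(), t_end = numeric(), iff = numeric()))
  isi <- diff(t)
  data.frame(t_start = t[-length(t)], t_end = t[-1], iff = 1 / isi)
}

#' Candidate bursts from IFF threshold crossings
#'
#' Scans the IFF series: a candidate begins at the first spike of the first
#' interspike interval whose IFF reaches \code{f_start}, and ends at the later
#' spike of the last interval with IFF at or above \code{f_end} before an
#' interval drops below \code{f_end} (boundary equality is kept in-burst).
#' Scanning resumes after each candidate, so a train may yield several
#' candidates. A train still above threshold at its last spike closes the
#' candidate there. Candidates are raw: the duration and spike-count filters
#' of \code{\link{filter_and_merge}} have not yet been applied.
#'
#' @param train a \code{\link{spike_train}} or numeric vector of spike times.
#' @param f_start,f_end start/end frequency thresholds (Hz),
#'   \code{f_start >= f_end > 0}.
#' @return data.frame with columns start, end, n_spikes (possibly 0 rows).
#' @export
find_candidate_bursts <- function(train, f_start, f_end) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  stopifnot(f_start >= f_end, f_end > 0)
  empty <- data.frame(start = numeric(), end = numeric(), n_spikes = integer())
  if (length(t) < 2) return(empty)
  iff <- 1 / diff(t)          # iff[k] belongs to interval (t[k], t[k+1])
  n_isi <- length(iff)
  out <- list()
  k <- 1L
  while (k <= n_isi) {
    if (iff[k] >= f_start) {
      s <- k                                  # burst starts at spike s = t[k]
      e <- k
      while (e <= n_isi && iff[e] >= f_end) e <- e + 1L
      # last supra-threshold ISI is e-1; its later spike is t[e]
      out[[length(out) + 1L]] <-
        data.frame(start = t[s], end = t[e], n_spikes = e - s + 1L)
      k <- e + 1L                             # resume after the closing ISI
    } else {
      k <- k + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Discard short candidates and merge the survivors
#'
#' Candidates shorter than \code{min_duration} (default 0.5 s) or with fewer
#' than \code{min_spikes} (default 3) spikes are discarded. When more than one
#' candidate survives within the analysis window (sporadic firing separated by
#' short lulls), the survivors are merged into a single burst spanning the
#' entire set of spikes, from the first start to the last end; spikes of the
#' train falling inside that closed span are all counted. Muscle force is
#' plausibly maintained across such short lulls, which is why the burst is
#' taken to span them. Set \code{merge_first = TRUE} to apply the merge before
#' the discard filters (sensitivity analysis; not the default order).
#'
#' @param candidates data.frame from \code{\link{find_candidate_bursts}}.
#' @param train the originating \code{\link{spike_train}} (used to count
#'   spikes inside the merged span).
#' @param min_duration,min_spikes discard thresholds.
#' @param merge_first merge candidates before filtering instead of after.
#' @return a \code{\link{burst}} or \code{NULL} when nothing survives.
#' @export
filter_and_merge <- function(candidates, train,
                             min_duration = 0.5, min_spikes = 3L,
                             merge_first = FALSE) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  unit <- if (inherits(train, "spike_train")) train$unit else "unit"
  merge_span <- function(cand) {
    s <- min(cand$start); e <- max(cand$end)
    burst(unit, s, e, sum(t >= s & t <= e))
  }
  if (merge_first) {
    if (!nrow(candidates)) return(NULL)
    b <- merge_span(candidates)
    if (b$end - b$start < min_duration || b$n_spikes < min_spikes) return(NULL)
    return(b)
  }
  keep <- candidates$end - candidates$start >= min_duration &
          candidates$n_spikes >= min_spikes
  cand <- candidates[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  merge_span(cand)
}

#' Detect the burst of one unit within analysis windows
#'
#' Convenience wrapper: restricts the train to each window (the annotated
#' swallow cycle, so merging never crosses swallows), finds candidates,
#' filters and merges. One burst (or none) per window.
#'
#' @param train a \code{\link{spike_train}}.
#' @param f_start,f_end thresholds (Hz).
#' @param windows data.frame or matrix with two columns (start, end), one row
#'   per analysis window; closed intervals.
#' @param ... passed to \code{\link{filter_and_merge}}.
#' @return list of \code{\link{burst}} or NULL, one element per window.
#' @export
detect_bursts <- function(train, f_start, f_end, windows, ...) {
  w <- as.matrix(windows)[, 1:2, drop = FALSE]
  lapply(seq_len(nrow(w)), function(i) {
    sub <- train$times[train$times >= w[i, 1] & train$times <= w[i, 2]]
    if (length(sub) < 2) return(NULL)
    cand <- find_candidate_bursts(sub, f_start, f_end)
    filter_and_merge(cand, spike_train(train$unit, sub), ...)
  })
}

#' Combine B3 and B6/B9 bursts into the retractor-pool burst
#'
#' B3 and B6/B9 both drive the I1/I3 jaw muscle and are combined for some
#' analyses. The combined unit bursts if either component does; the combined
#' span runs from the earlier of the two starts to the later of the two ends.
#' The spike count is the number of distinct spikes of both trains inside the
#' combined closed span.
#'
#' @param b3,b6b9 \code{\link{burst}} objects or NULL (unit not bursting; B3
#'   is usually silent in unloaded swallows).
#' @param b3_train,b6b9_train the component \code{\link{spike_train}}s (or
#'   numeric times), used to count spikes in the combined span. Optional when
#'   one burst is NULL (the other burst is returned relabeled).
#' @return a \code{\link{burst}} labeled \code{"B3/B6/B9"}, or NULL when
#'   neither unit bursts.
#' @export
combine_b3_b6b9 <- function(b3, b6b9, b3_train = NULL, b6b9_train = NULL) {
  get_times <- function(x) {
    if (is.null(x)) numeric()
    else if (inherits(x, "spike_train")) x$times
    else as.numeric(x)
  }
  if (is.null(b3) && is.null(b6b9)) return(NULL)
  one <- function(b) burst("B3/B6/B9", b$start, b$end, b$n_spikes)
  if (is.null(b3) && is.null(b3_train)) return(one(b6b9))
  if (is.null(b6b9) && is.null(b6b9_train)) return(one(b3))
  s <- min(c(b3$start, b6b9$start))
  e <- max(c(b3$end, b6b9$end))
  spikes <- sort(c(get_times(b3_train), get_times(b6b9_train)))
  n <- sum(spikes >= s & spikes <= e)
  if (n < 2) n <- sum(c(b3$n_spikes, b6b9$n_spikes))
  burst("B3/B6/B9", s, e, n)
}

#' Mean firing rate during a burst
#'
#' (number of spikes − 1) / burst duration: the reciprocal of the mean
#' interspike interval, so a perfectly regular 10 Hz burst reports 10 Hz
#' regardless of its length.
#'
#' @param b a \code{\link{burst}}.
#' @return rate in Hz.
#' @export
mean_burst_rate <- function(b) {
  if (b$n_spikes < 2 || b$end <= b$start)
    stop("degenerate burst: need >= 2 spikes and positive duration")
  (b$n_spikes - 1) / (b$end - b$start)
}

#' Smoothed instantaneous firing rate
#'
#' Convolves the spike train with a Gaussian kernel of SD \code{sigma}
#' (default 200 ms) centered on each spike, evaluated on a uniform grid.
#' Each spike contributes unit mass, so the integral of the trace over all
#' time approximates the spike count. Kernels are truncated at ±5 SD
#' (mass loss < 1e-6).
#'
#' @param train a \code{\link{spike_train}} or numeric spike times.
#' @param from,to grid span in seconds; defaults pad the train by 5 SD.
#' @param grid_rate grid sampling rate in Hz (default 100).
#' @param sigma kernel SD in seconds (default 0.2).
#' @return data.frame with columns \code{time} and \code{rate} (Hz).
#' @export
smooth_rate <- function(train, from = NULL, to = NULL,
                        grid_rate = 100, sigma = 0.2) {
  stopifnot(sigma > 0, grid_rate > 0)
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (is.null(from)) from <- if (length(t)) min(t) - 5 * sigma else 0
  if (is.null(to))   to   <- if (length(t)) max(t) + 5 * sigma else 1
  grid <- seq(from, to, by = 1 / grid_rate)
  rate <- numeric(length(grid))
  for (tk in t) {
    lo <- findInterval(tk - 5 * sigma, grid) # truncate at +-5 sigma
    hi <- findInterval(tk + 5 * sigma, grid)
    idx <- max(1L, lo):min(length(grid), hi + 1L)
    rate[idx] <- rate[idx] + stats::dnorm(grid[idx], mean = tk, sd = sigma)
  }
  data.frame(time = grid, rate = rate)
}
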