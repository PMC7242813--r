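#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass, used to condition the
#' I2 EMG channel (100 Hz cutoff) before peak detection. Zero-phase filtering
#' preserves peak timing but applies the filter magnitude twice; the design
#' cutoff is widened by (sqrt(2) - 1)^(-1/(2n)) so that the net two-pass
#' response is -3 dB (amplitude ratio 1/sqrt(2)) at the requested cutoff.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate (Hz).
#' @param cutoff -3 dB cutoff frequency (Hz); must be below Nyquist.
#' @param order Butterworth order of each pass (default 4).
#' @return filtered signal, same length as \code{x}.
#' @export
lowpass <- function(x, sample_rate, cutoff, order = 4) {
  nyq <- sample_rate / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency")
  # widen so |H|^2 = 1/sqrt(2) at the nominal cutoff after two passes
  scale <- (sqrt(2) - 1)^(-1 / (2 * order))
  wc <- min(cutoff * scale / nyq, 0.99)
  bf <- signal::butter(order, wc, type = "low")
  # reflect-pad to suppress start/end transients of the forward-backward pass
  n <- length(x)
  np <- min(n - 1, ceiling(3 * sample_rate / cutoff))
  if (np > 0) {
    head_pad <- 2 * x[1] - x[(np + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    as.numeric(y[(np + 1):(np + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Window discriminator specification
#'
#' A window discriminator captures signal peaks on one channel occurring
#' within a given amplitude range and time window — the standard manual tool
#' for sorting identified units on extracellular nerve recordings, where each
#' unit has a reliable relative amplitude and phase of activity. A unit whose
#' spike amplitude varies (e.g. through spike collisions) may be covered by
#' several discriminators OR-combined under the same unit label.
#'
#' @param unit unit label the captured peaks belong to.
#' @param channel channel name to search.
#' @param amp_lo,amp_hi closed amplitude range (channel units; peak height for
#'   positive polarity, trough depth for negative).
#' @param t_lo,t_hi closed time window (s).
#' @param polarity \code{"positive"} or \code{"negative"}.
#' @return a list of class \code{"window_discriminator"}.
#' @export
window_discriminator <- function(unit, channel, amp_lo, amp_hi,
                                 t_lo = -Inf, t_hi = Inf,
                                 polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (amp_lo >= amp_hi) stop("amp_lo must be below amp_hi")
  if (t_lo >= t_hi) stop("t_lo must be below t_hi")
  structure(list(unit = unit, channel = channel,
                 amp_lo = amp_lo, amp_hi = amp_hi,
                 t_lo = t_lo, t_hi = t_hi, polarity = polarity),
            class = "window_discriminator")
}

# Strict local extrema with a refractory neighborhood: sample i is a peak of
# p if p[i] > p[j] for all earlier j and p[i] >= p[j] for all later j within
# +-refractory (ties break to the earliest sample). Candidates outside
# [lo, hi] are discarded before the (expensive) neighborhood check.
find_peaks <- function(p, refractory_samples, lo = -Inf, hi = Inf) {
  n <- length(p)
  if (n < 3) return(integer())
  cand <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  cand <- cand[p[cand] >= lo & p[cand] <= hi]
  w <- refractory_samples
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    before <- if (i > lo) p[lo:(i - 1L)] else numeric()
    after  <- if (i < hi) p[(i + 1L):hi] else numeric()
    (!length(before) || p[i] > max(before)) &&
      (!length(after) || p[i] >= max(after))
  }, logical(1))
  cand[keep]
}

#' Detect spikes on one channel with a window discriminator
#'
#' Peaks are strict local extrema over a 1 ms refractory neighborhood (ties
#' broken to the earliest sample). A peak is captured when its amplitude lies
#' in the closed range \code{[amp_lo, amp_hi]} and its time in the closed
#' window \code{[t_lo, t_hi]}. The spike time is the sample of the extremum.
#'
#' @param rec a \code{\link{recording}}.
#' @param disc a \code{\link{window_discriminator}}.
#' @param refractory refractory neighborhood half-width in seconds
#'   (default 0.001).
#' @return a \code{\link{spike_train}} for \code{disc$unit}.
#' @export
detect_spikes <- function(rec, disc, refractory = 0.001) {
  if (!disc$channel %in% names(rec$signals))
    stop("unknown channel: ", disc$channel)
  x <- rec$signals[[disc$channel]]
  p <- if (disc$polarity == "positive") x else -x
  idx <- find_peaks(p, max(1L, round(refractory * rec$sample_rate)),
                    lo = disc$amp_lo, hi = disc$amp_hi)
  times <- rec$t0 + (idx - 1) / rec$sample_rate
  keep <- times >= disc$t_lo & times <= disc$t_hi
  spike_train(disc$unit, times[keep])
}

#' Apply a set of window discriminators to a recording
#'
#' Runs every discriminator and groups captured peaks into one spike train
#' per unit. Channels with role \code{"emg"} are zero-phase low-pass filtered
#' at \code{i2_cutoff} (default 100 Hz) before detection when
#' \code{i2_prefilter} is TRUE; the per-discriminator time windows implement
#' exclusions such as retraction-phase activity on the I2 channel (which
#' reflects the nearby I4 muscle rather than I2). A peak captured by
#' discriminators of two different units is assigned to the unit whose
#' amplitude-window center is nearest, with a warning (the original analysis
#' resolved such overlaps manually).
#'
#' @param rec a \code{\link{recording}}.
#' @param discs list of \code{\link{window_discriminator}}s (several may share
#'   a unit label; their captures are OR-combined).
#' @param i2_prefilter low-pass the EMG channel(s) first (default TRUE).
#' @param i2_cutoff EMG prefilter cutoff in Hz.
#' @param refractory peak refractory half-width (s).
#' @return named list of \code{\link{spike_train}}, one per unit.
#' @export
apply_discriminator_set <- function(rec, discs, i2_prefilter = TRUE,
                                    i2_cutoff = 100, refractory = 0.001) {
  if (i2_prefilter) {
    for (ch in names(rec$roles)[rec$roles == "emg"])
      rec$signals[[ch]] <- lowpass(rec$signals[[ch]], rec$sample_rate,
                                   i2_cutoff)
  }
  caps <- lapply(discs, function(d) {
    st <- detect_spikes(rec, d, refractory = refractory)
    if (!length(st$times)) return(NULL)
    data.frame(unit = d$unit, channel = d$channel, time = st$times,
               center = (d$amp_lo + d$amp_hi) / 2)
  })
  caps <- do.call(rbind, Filter(Negate(is.null), caps))
  units <- unique(vapply(discs, `[[`, "", "unit"))
  if (is.null(caps))
    return(stats::setNames(lapply(units, spike_train, times = numeric()),
                           units))
  # resolve peaks captured by more than one unit on the same channel:
  # nearest amplitude-window center wins
  key <- paste(caps$channel, format(caps$time, digits = 12))
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    amb <- key %in% dup_keys
    multi <- tapply(caps$unit[amb], key[amb],
                    function(u) length(unique(u)) > 1)
    if (any(multi)) {
      warning(sum(multi), " peak(s) matched discriminators of multiple ",
              "units; assigned to nearest amplitude-window center")
      drop <- logical(nrow(caps))
      for (k in names(multi)[multi]) {
        rows <- which(key == k)
        ch <- caps$channel[rows[1]]
        x <- rec$signals[[ch]]
        s <- round((caps$time[rows[1]] - rec$t0) * rec$sample_rate) + 1
        amp <- abs(x[s])
        best <- rows[which.min(abs(caps$center[rows] - amp))]
        drop[setdiff(rows, best)] <- TRUE
      }
      caps <- caps[!drop, ]
      key <- key[!drop]
    }
  }
  caps <- caps[!duplicated(paste(caps$unit, key)), ]  # OR-combine per unit
  out <- lapply(units, function(u) {
    spike_train(u, sort(unique(caps$time[caps$unit == u])))
  })
  stats::setNames(out, units)
}

#' Read window discriminators from YAML
#'
#' @param path YAML file: a list of maps with keys unit, channel, amp_lo,
#'   amp_hi and optional t_lo, t_hi, polarity.
#' @return list of \code{\link{window_discriminator}}s.
#' @export
read_discriminators <- function(path) {
  specs <- yaml::read_yaml(path)
  lapply(specs, function(s) {
    window_discriminator(s$unit, s$channel, s$amp_lo, s$amp_hi,
                         t_lo = s$t_lo %||% -Inf, t_hi = s$t_hi %||% Inf,
                         polarity = s$polarity %||% "positive")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write spike trains to CSV
#' @param trains named list of \code{\link{spike_train}}s.
#' @param path output CSV (columns unit, time_s).
#' @return \code{path}, invisibly.
#' @export
write_spikes <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(st) {
    if (!length(st$times)) return(NULL)
    data.frame(unit = st$unit, time_s = st$times)
  }))
  if (is.null(df)) df <- data.frame(unit = character(), time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#' @param path CSV with columns unit, time_s.
#' @return named list of \code{\link{spike_train}}s.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path)
  units <- unique(df$unit)
  stats::setNames(
    lapply(units, function(u) spike_train(u, sort(df$time_s[df$unit == u]))),
    units)
}
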