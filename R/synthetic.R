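#' Session-level configuration of the synthetic swallowing generator
#'
#' The generator emulates the structure the analysis assumes: per-unit spike
#' trains with unit-specific amplitudes on shared nerve channels, burst
#' timing locked to the protraction/retraction skeleton of each swallow
#' cycle, condition-dependent prolongation of retraction and increase of
#' retractor firing rate under load, and a five-stage force waveform for each
#' loaded swallow. Defaults express the emulated regime: about 2 s of
#' protraction, about 1.9 s of unloaded retraction prolonged by 1 s under
#' load, a 20 Hz combined retractor-pool rate raised by 6 Hz under load, B3
#' recruited in all loaded but only ~26% of unloaded swallows, and an
#' intermediate partial-maintenance plateau missing from ~18% (7/39) of
#' loaded swallows. These are declared fixtures with the qualitative
#' structure of real sessions, not estimates of any animal.
#'
#' @param protraction_mean,protraction_sd protraction duration (s).
#' @param retraction_mean,retraction_sd unloaded retraction duration (s).
#' @param delta_retraction retraction prolongation under load (s).
#' @param rate_b369 unloaded combined B3/B6/B9 mean burst rate (Hz).
#' @param delta_rate_b369 combined-rate increase under load (Hz).
#' @param delta_dur_b4b5 B4/B5 burst prolongation under load (s).
#' @param stage_v duration of the major force drop (s).
#' @param f_min,f_int,f_max force landmarks (mN): cycle minimum, intermediate
#'   plateau, peak.
#' @param undefined_stage1_fraction fraction of loaded swallows whose force
#'   falls smoothly to its minimum with no intermediate plateau.
#' @param b3_p_unloaded probability that B3 is recruited in an unloaded
#'   swallow.
#' @param jitter interior spike-time jitter as a fraction of the interspike
#'   interval.
#' @param burst_jitter_sd SD (s) of the trial-to-trial jitter on each
#'   burst's onset and offset around its template anchors.
#' @param sample_rate digitization rate (Hz).
#' @param noise named additive Gaussian noise SDs per channel role
#'   (nerve/emg channel units; force in mN).
#' @return list of class \code{"session_config"}.
#' @export
session_config <- function(protraction_mean = 2.0, protraction_sd = 0.15,
                           retraction_mean = 1.9, retraction_sd = 0.2,
                           delta_retraction = 1.0,
                           rate_b369 = 20, delta_rate_b369 = 6,
                           delta_dur_b4b5 = 0.78,
                           stage_v = 0.6,
                           f_min = 2, f_int = 30, f_max = 80,
                           undefined_stage1_fraction = 7 / 39,
                           b3_p_unloaded = 6 / 23,
                           jitter = 0.1,
                           burst_jitter_sd = 0.05,
                           sample_rate = 5000,
                           noise = c(nerve = 0.05, emg = 0.05, force = 0.5)) {
  structure(as.list(environment()), class = "session_config")
}

#' Unit templates of the synthetic generator
#'
#' One template per identified unit: rendering channel and relative spike
#' amplitude (B3 largest on BN2, B6/B9 and B38 medium, separated by phase),
#' within-burst firing rate, and burst anchors expressed as offsets from the
#' cycle's force events (\code{prev_e5}, \code{e1}..\code{e5}). B6/B9 has no
#' fixed rate: its spike count is derived per swallow from the configured
#' combined B3/B6/B9 rate so that the configured condition effect holds
#' exactly in the ground truth.
#'
#' @param overrides optional named list of templates replacing or extending
#'   the defaults; each template is a list with fields unit, channel,
#'   amplitude, rate, start (event, offset), end (event, offset), and
#'   optional p_active (unloaded, loaded), delta_dur.
#' @return named list of unit templates.
#' @export
default_unit_templates <- function(overrides = NULL) {
  tpl <- list(
    "B38"   = list(unit = "B38", channel = "BN2", amplitude = 0.40,
                   rate = 11,
                   start = list("prev_e5", 0.05), end = list("e2", -0.40)),
    "I2"    = list(unit = "I2", channel = "I2", amplitude = 1.0,
                   rate = 14,
                   start = list("e1", 0.05), end = list("e2", 0.45)),
    "B8a/b" = list(unit = "B8a/b", channel = "RN", amplitude = 1.0,
                   rate = 15,
                   start = list("e2", 0.05), end = list("e5", -0.10)),
    "B6/B9" = list(unit = "B6/B9", channel = "BN2", amplitude = 0.60,
                   rate = NA,   # derived from the combined-rate target
                   start = list("e3", 0.05), end = list("e5", -0.05)),
    "B3"    = list(unit = "B3", channel = "BN2", amplitude = 1.05,
                   rate = 9,
                   start = list("e4", 0.00), end = list("e4", 0.70),
                   p_active = c(unloaded = NA, loaded = 1)),
    "B4/B5" = list(unit = "B4/B5", channel = "BN3", amplitude = 1.0,
                   rate = 12,
                   start = list("e2", 0.00), end = list("e3", 0.40),
                   delta_dur = NA))
  for (nm in names(overrides)) tpl[[nm]] <- overrides[[nm]]
  tpl
}

#' Flag swallows with an undefined partial-maintenance stage
#'
#' Marked swallows get a force record that decays smoothly from the peak of
#' the preceding swallow to the cycle minimum, with no intermediate plateau:
#' events 1 and 2 do not exist for them and stage I is undefined. Exactly
#' \code{round(fraction * n)} swallows are flagged, at seeded-random
#' positions.
#'
#' @param n number of swallows.
#' @param fraction proportion to flag, in [0, 1].
#' @param seed RNG seed.
#' @return logical vector of length \code{n}.
#' @export
generate_undefined_stage1 <- function(n, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round(fraction * n)
  flags <- rep(FALSE, n)
  if (k > 0) {
    set.seed(seed)
    flags[sample.int(n, k)] <- TRUE
  }
  flags
}

# evenly spaced spikes with jittered interior times; endpoints exact
spike_times_for_burst <- function(start, end, n, jitter) {
  if (n < 2) return(start)
  t <- seq(start, end, length.out = n)
  if (n > 2 && jitter > 0) {
    dt <- (end - start) / (n - 1)
    t[2:(n - 1)] <- t[2:(n - 1)] +
      stats::runif(n - 2, -jitter * dt, jitter * dt)
  }
  sort(t)
}

# biphasic spike waveform; peak value 1 at sample `peak_at`
spike_waveform <- function(width_samples) {
  sin(2 * pi * seq(0, width_samples - 1) / width_samples)
}

#' Render spike trains as biphasic waveforms on a signal
#'
#' Adds a fixed-shape biphasic template (one full sine period; positive peak
#' first), scaled by \code{amplitude}, at every spike time. The positive peak
#' sample coincides with the spike's sample, so window discriminators recover
#' the spike times exactly on noise-free renderings.
#'
#' @param x numeric signal vector to add spikes into.
#' @param times spike times (s, relative to the first sample of \code{x}).
#' @param amplitude peak amplitude.
#' @param sample_rate sampling rate (Hz).
#' @param width spike width in seconds (default 2.4 ms; use ~12 ms for EMG
#'   so a 100 Hz pre-filter passes the peak).
#' @return \code{x} with spikes added.
#' @export
render_spikes <- function(x, times, amplitude, sample_rate, width = 0.0024) {
  w <- max(4L, round(width * sample_rate))
  w <- w + (w %% 4L)              # multiple of 4: peak lands on a sample
  tpl <- amplitude * spike_waveform(w)
  peak_at <- w / 4L
  n <- length(x)
  for (tk in times) {
    i0 <- round(tk * sample_rate) + 1L - peak_at
    idx <- i0:(i0 + w - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl[ok]
  }
  x
}

# piecewise-linear force nodes for one cycle; returns data.frame(t, f)
force_nodes_cycle <- function(ev, cfg, undefined_I, d_iv) {
  with(as.list(ev), {
    if (!undefined_I) {
      data.frame(
        t = c(e1, e2, e3, e4, e4 + 0.4 * d_iv, e5),
        f = c(cfg$f_int, cfg$f_int - 4, cfg$f_min, cfg$f_max - 6,
              cfg$f_max, cfg$f_max - 1.5))
    } else {
      # no intermediate plateau: the preceding rapid decrease runs straight
      # down to near the minimum, then the force creeps smoothly to the
      # minimum reached at the start of the rise
      t_fall_end <- v_start + 0.55 * (e3 - v_start)
      data.frame(
        t = c(t_fall_end, e3, e4, e4 + 0.4 * d_iv, e5),
        f = c(cfg$f_min + 3, cfg$f_min, cfg$f_max - 6, cfg$f_max,
              cfg$f_max - 1.5))
    }
  })
}

#' Generate a synthetic feeding session
#'
#' Builds \code{n_swallows} consecutive swallow cycles of one condition:
#' draws the protraction/retraction skeleton (retraction prolonged by
#' \code{cfg$delta_retraction} under load), places unit bursts from the
#' templates, derives B6/B9 spike counts so the combined B3/B6/B9 burst rate
#' equals the configured target (+\code{cfg$delta_rate_b369} under load),
#' renders spikes as amplitude-scaled biphasic waveforms on their channels
#' (nudging spikes of different units on a shared channel at least 3 ms apart
#' so waveforms do not collide), synthesizes the five-stage force waveform
#' for loaded sessions, and adds per-channel Gaussian noise. Identical seeds
#' give identical output.
#'
#' @param n_swallows number of swallow cycles (>= 1).
#' @param condition \code{"unloaded"} or \code{"loaded"}.
#' @param templates unit templates (\code{\link{default_unit_templates}}).
#' @param cfg a \code{\link{session_config}}.
#' @param seed RNG seed.
#' @param animal animal identifier for the annotations.
#' @return list with elements \code{recording} (a \code{\link{recording}};
#'   loaded sessions have a force channel), \code{ground_truth} (one element
#'   per swallow: events, stage_I_defined, inward interval, per-unit true
#'   bursts, true combined B3/B6/B9 burst) and \code{annotations} (swallow
#'   annotation data.frame).
#' @export
generate_session <- function(n_swallows, condition = c("unloaded", "loaded"),
                             templates = default_unit_templates(),
                             cfg = session_config(), seed = 1,
                             animal = "A1") {
  condition <- match.arg(condition)
  stopifnot(n_swallows >= 1)
  set.seed(seed)
  loaded <- condition == "loaded"
  sr <- cfg$sample_rate

  undef <- if (loaded)
    generate_undefined_stage1(n_swallows, cfg$undefined_stage1_fraction,
                              seed = seed + 1L)
  else rep(FALSE, n_swallows)
  set.seed(seed + 2L)   # isolate skeleton draws from the flag draw

  # --- cycle skeleton -------------------------------------------------------
  P <- pmax(0.8, stats::rnorm(n_swallows, cfg$protraction_mean,
                              cfg$protraction_sd))
  R <- pmax(0.8, stats::rnorm(n_swallows, cfg$retraction_mean,
                              cfg$retraction_sd)) +
    if (loaded) cfg$delta_retraction else 0
  cycles <- vector("list", n_swallows)
  t_cursor <- 0.2                     # session warm-up drop begins here
  for (k in seq_len(n_swallows)) {
    v_start <- t_cursor               # preceding swallow's event 5
    e1 <- v_start + cfg$stage_v
    e2 <- e1 + 0.5 * P[k]
    e3 <- e2 + 0.5 * P[k]
    e4 <- e3 + 0.45 * R[k]
    e5 <- e4 + 0.55 * R[k]
    cycles[[k]] <- list(ev = c(v_start = v_start, prev_e5 = v_start, e1 = e1,
                               e2 = e2, e3 = e3, e4 = e4, e5 = e5),
                        P = P[k], R = R[k], d_iv = 0.55 * R[k])
    t_cursor <- e5
  }
  t_end <- t_cursor + cfg$stage_v + 0.5
  n_samp <- ceiling(t_end * sr) + 1L

  # --- per-swallow spikes and ground truth ----------------------------------
  anchor <- function(ev, a) ev[[a[[1]]]] + a[[2]]
  ground_truth <- vector("list", n_swallows)
  unit_spikes <- stats::setNames(
    vector("list", length(templates)), names(templates))
  combined_target <- cfg$rate_b369 + if (loaded) cfg$delta_rate_b369 else 0

  for (k in seq_len(n_swallows)) {
    cy <- cycles[[k]]
    ev <- as.list(cy$ev)
    b3_active <- if (loaded) TRUE else
      stats::runif(1) < cfg$b3_p_unloaded
    true_bursts <- list()
    # jittered burst anchors for every unit (trial-to-trial variability);
    # B3 is clamped inside the B6/B9 span so the combined-burst ground
    # truth stays exact
    bounds <- list()
    for (nm in names(templates)) {
      tp <- templates[[nm]]
      s <- anchor(ev, tp$start) + stats::rnorm(1, 0, cfg$burst_jitter_sd)
      e <- anchor(ev, tp$end) + stats::rnorm(1, 0, cfg$burst_jitter_sd)
      if (nm == "B4/B5" && loaded) {
        dd <- if (!is.null(tp$delta_dur) && !is.na(tp$delta_dur))
          tp$delta_dur else cfg$delta_dur_b4b5
        e <- e + dd
      }
      bounds[[nm]] <- c(s, e)
    }
    if (!is.null(bounds[["B3"]]) && !is.null(bounds[["B6/B9"]])) {
      bounds[["B3"]][1] <- max(bounds[["B3"]][1],
                               bounds[["B6/B9"]][1] + 0.02)
      bounds[["B3"]][2] <- min(bounds[["B3"]][2],
                               bounds[["B6/B9"]][2] - 0.02)
    }
    # B3 first: its count feeds the combined-rate bookkeeping
    n3 <- 0L
    t3 <- numeric()
    tb3 <- templates[["B3"]]
    if (!is.null(tb3) && b3_active) {
      s3 <- bounds[["B3"]][1]; e3b <- bounds[["B3"]][2]
      n3 <- round(tb3$rate * (e3b - s3)) + 1L
      t3 <- spike_times_for_burst(s3, e3b, n3, cfg$jitter)
      true_bursts[["B3"]] <- data.frame(unit = "B3", start = s3, end = e3b,
                                        n_spikes = n3)
    }
    comb <- NULL
    for (nm in names(templates)) {
      tp <- templates[[nm]]
      if (nm == "B3") { if (b3_active) unit_spikes[[nm]] <-
        c(unit_spikes[[nm]], t3); next }
      s <- bounds[[nm]][1]; e <- bounds[[nm]][2]
      if (nm == "B6/B9") {
        span <- e - s
        n <- round(combined_target * span) + 1L - n3
        comb <- list(start = s, end = e,
                     n = n + n3, rate = (n + n3 - 1) / span)
      } else {
        n <- round(tp$rate * (e - s)) + 1L
      }
      tt <- spike_times_for_burst(s, e, n, cfg$jitter)
      unit_spikes[[nm]] <- c(unit_spikes[[nm]], tt)
      true_bursts[[nm]] <- data.frame(unit = nm, start = s, end = e,
                                      n_spikes = n)
    }
    tb <- do.call(rbind, true_bursts)
    tb$mean_rate <- (tb$n_spikes - 1) / (tb$end - tb$start)
    ground_truth[[k]] <- list(
      swallow = k,
      events = c(e1 = if (undef[k]) NA_real_ else ev$e1,
                 e2 = if (undef[k]) NA_real_ else ev$e2,
                 e3 = ev$e3, e4 = ev$e4, e5 = ev$e5),
      v_start = ev$v_start,
      stage_I_defined = !undef[k],
      inward = c(ev$e3, ev$e5),
      bursts = tb,
      combined_b369 = comb)
  }

  # --- collision avoidance on shared channels -------------------------------
  chan_units <- split(names(templates),
                      vapply(templates, `[[`, "", "channel"))
  for (ch in names(chan_units)) {
    us <- chan_units[[ch]]
    if (length(us) < 2) next
    # later-listed (lower-priority) units yield: nudge their spikes off the
    # earlier units' spikes; counts are preserved
    placed <- sort(unlist(unit_spikes[us[1]]))
    for (u in us[-1]) {
      t_u <- unit_spikes[[u]]
      if (!length(t_u)) next
      for (i in seq_along(t_u)) {
        while (length(placed) && min(abs(placed - t_u[i])) < 0.003)
          t_u[i] <- t_u[i] + 0.0032
      }
      unit_spikes[[u]] <- t_u
      placed <- sort(c(placed, t_u))
    }
  }
  unit_spikes <- lapply(unit_spikes, function(t) sort(unique(t)))

  # --- render channels ------------------------------------------------------
  channels <- list(RN = numeric(n_samp), BN2 = numeric(n_samp),
                   BN3 = numeric(n_samp), I2 = numeric(n_samp))
  roles <- c(RN = "nerve", BN2 = "nerve", BN3 = "nerve", I2 = "emg")
  for (nm in names(templates)) {
    tp <- templates[[nm]]
    if (!length(unit_spikes[[nm]])) next
    wid <- if (roles[[tp$channel]] == "emg") 0.012 else 0.0024
    channels[[tp$channel]] <- render_spikes(
      channels[[tp$channel]], unit_spikes[[nm]], tp$amplitude, sr, wid)
  }
  if (loaded) {
    nodes <- do.call(rbind, lapply(seq_len(n_swallows), function(k) {
      gt <- ground_truth[[k]]
      ev <- c(as.list(cycles[[k]]$ev))
      force_nodes_cycle(ev, cfg, !gt$stage_I_defined, cycles[[k]]$d_iv)
    }))
    # session warm-up: the tail of a preceding swallow's force peak, so the
    # first cycle window starts mid major-drop like every later one
    nodes <- rbind(data.frame(t = c(0, 0.2), f = rep(cfg$f_max - 1.5, 2)),
                   nodes)
    # session tail: final major drop then hold
    last_e5 <- cycles[[n_swallows]]$ev[["e5"]]
    nodes <- rbind(nodes, data.frame(t = c(last_e5 + cfg$stage_v, t_end),
                                     f = c(cfg$f_int, cfg$f_int)))
    tt <- (seq_len(n_samp) - 1) / sr
    channels$Force <- suppressWarnings(
      stats::approx(nodes$t, nodes$f, xout = tt, rule = 2,
                    ties = "ordered")$y)
    roles <- c(roles, Force = "force")
  }
  for (ch in names(channels)) {
    sd_n <- unname(cfg$noise[roles[[ch]]])
    if (is.na(sd_n)) sd_n <- 0
    if (sd_n > 0)
      channels[[ch]] <- channels[[ch]] + stats::rnorm(n_samp, 0, sd_n)
  }

  # --- annotations ----------------------------------------------------------
  ann <- do.call(rbind, lapply(seq_len(n_swallows), function(k) {
    gt <- ground_truth[[k]]
    data.frame(animal = animal, condition = condition,
               cycle_start = gt$v_start,
               cycle_end = unname(gt$events[["e5"]]),
               inward_start = gt$inward[1], inward_end = gt$inward[2])
  }))

  list(recording = recording(channels, roles, sr, t0 = 0),
       ground_truth = ground_truth,
       annotations = ann,
       unit_spikes = unit_spikes,
       condition = condition, seed = seed)
}

#' Default window discriminators matching the generator's templates
#'
#' Amplitude windows separate units sharing a channel (B3 largest on BN2,
#' B6/B9 medium, B38 medium-small and phase-separated); the wide I2 window
#' accommodates attenuation of the EMG waveform by the 100 Hz pre-filter.
#'
#' @param templates unit templates (to pick up amplitude overrides).
#' @return list of \code{\link{window_discriminator}}s.
#' @export
default_discriminators <- function(templates = default_unit_templates()) {
  list(
    window_discriminator("B38",   "BN2", 0.25, 0.50),
    window_discriminator("I2",    "I2",  0.20, 2.00),
    window_discriminator("B8a/b", "RN",  0.60, 1.60),
    window_discriminator("B6/B9", "BN2", 0.50, 0.80),
    window_discriminator("B3",    "BN2", 0.85, 1.40),
    window_discriminator("B4/B5", "BN3", 0.60, 1.60))
}

#' Generate a synthetic per-animal paired table
#'
#' Fixture for the statistics battery: per-animal condition means with a
#' configured additive load effect, between-animal spread, and within-animal
#' measurement error on each condition mean. With two animals and zero noise
#' the per-animal difference is exactly \code{effect}.
#'
#' @param n_animals number of animals (>= 2).
#' @param base_mean unloaded population mean of the measure.
#' @param effect loaded − unloaded shift.
#' @param between_sd SD of true animal means around \code{base_mean}.
#' @param within_sem SEM of each observed condition mean.
#' @param seed RNG seed.
#' @param measure measure name.
#' @return a \code{\link{paired_table}}.
#' @export
generate_paired_table <- function(n_animals, base_mean, effect,
                                  between_sd = 0, within_sem = 0,
                                  seed = 1, measure = "measure") {
  stopifnot(n_animals >= 2)
  set.seed(seed)
  mu <- base_mean + stats::rnorm(n_animals, 0, between_sd)
  u <- mu + stats::rnorm(n_animals, 0, within_sem)
  l <- mu + effect + stats::rnorm(n_animals, 0, within_sem)
  paired_table(measure, paste0("A", seq_len(n_animals)), u, l)
}
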