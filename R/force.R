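#' Force-event detector parameters
#'
#' The five events of a loaded swallow's force record are, in the original
#' analyses, placed manually; this detector is an explicit, reproducible
#' heuristic whose output manual annotations always override
#' (\code{\link{load_manual_events}}). Slope thresholds are expressed as
#' fractions of the cycle's force range per second, so they transfer across
#' animals with different absolute force scales.
#'
#' @param smooth_width moving-average width for the force trace (s).
#' @param rise_thresh slope marking "rapid force increase" (fraction of range
#'   per s) — locates event 3.
#' @param decel_thresh slope below which the rise is considered decelerating —
#'   locates event 4.
#' @param fall_thresh negative-slope magnitude marking "rapid force decrease" —
#'   locates event 5.
#' @param fall_end_thresh negative-slope magnitude below which the preceding
#'   swallow's rapid decrease has ended — locates event 1.
#' @param dip_thresh negative-slope magnitude marking the start of the final
#'   drop to the minimum — locates event 2.
#' @param plateau_level force level (fraction of range above the cycle
#'   minimum) that an intermediate plateau must exceed for stage I to count
#'   as defined.
#' @param min_run minimum time (s) a slope condition must hold.
#' @return list of class \code{"event_detector_params"}.
#' @export
event_detector_params <- function(smooth_width = 0.05,
                                  rise_thresh = 0.25,
                                  decel_thresh = 0.35,
                                  fall_thresh = 0.4,
                                  fall_end_thresh = 0.3,
                                  dip_thresh = 0.2,
                                  plateau_level = 0.15,
                                  min_run = 0.05) {
  p <- list(smooth_width = smooth_width, rise_thresh = rise_thresh,
            decel_thresh = decel_thresh, fall_thresh = fall_thresh,
            fall_end_thresh = fall_end_thresh, dip_thresh = dip_thresh,
            plateau_level = plateau_level, min_run = min_run)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "event_detector_params")
}

#' Force segmentation of one loaded swallow
#'
#' Constructs the stage intervals from the five force events:
#' I "partial force maintenance" = [e1, e2] (undefined when the force fell
#' smoothly to its minimum with no intermediate plateau, in which case e1 and
#' e2 are NA), II "force dip" ending at e3, III "force rise" = [e3, e4],
#' IV "force maintenance" = [e4, e5], V "major force drop" from e5 to the
#' next swallow's event 1 (here: \code{v_end}).
#'
#' @param e1,e2 events 1 and 2 (s), or NA when stage I is undefined.
#' @param e3,e4,e5 events 3-5 (s), required.
#' @param v_end end of stage V (next swallow's event 1, or end of the
#'   analysis window).
#' @param ii_start start of stage II when e2 is NA but the dip onset is
#'   annotated; defaults to e2.
#' @return list of class \code{"force_segmentation"} with fields
#'   \code{events} (named e1..e5) and \code{stages} (named I..V intervals,
#'   NULL when undefined).
#' @export
force_segmentation <- function(e1 = NA, e2 = NA, e3, e4, e5, v_end = NA,
                               ii_start = NULL) {
  ev <- c(e1 = unname(e1), e2 = unname(e2), e3 = unname(e3),
          e4 = unname(e4), e5 = unname(e5))
  def <- ev[!is.na(ev)]
  if (is.unsorted(def, strictly = TRUE))
    stop("defined events must be strictly increasing")
  if (is.na(e1) != is.na(e2))
    stop("events 1 and 2 must be defined together or not at all")
  stage_I <- if (!is.na(e1)) c(e1, e2) else NULL
  ii_s <- if (!is.na(e2)) e2 else if (!is.null(ii_start)) ii_start else NA
  stage_II <- if (!is.na(ii_s)) c(ii_s, e3) else NULL
  stages <- list(I = stage_I, II = stage_II, III = c(e3, e4),
                 IV = c(e4, e5),
                 V = if (!is.na(v_end)) c(e5, v_end) else NULL)
  structure(list(events = ev, stages = stages), class = "force_segmentation")
}

#' @export
print.force_segmentation <- function(x, ...) {
  cat("<force_segmentation>\n events:",
      paste(names(x$events), sprintf("%.3f", x$events), sep = "=",
            collapse = " "), "\n")
  for (s in names(x$stages)) {
    iv <- x$stages[[s]]
    cat(sprintf("  stage %-3s %s\n", s,
                if (is.null(iv)) "undefined"
                else sprintf("[%.3f, %.3f]", iv[1], iv[2])))
  }
  invisible(x)
}

# first index >= from where cond holds for min_run_n consecutive samples
first_sustained <- function(cond, from, min_run_n) {
  n <- length(cond)
  if (from > n) return(NA_integer_)
  r <- rle(cond[from:n])
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_run_n)
  if (!length(hit)) return(NA_integer_)
  from + (ends[hit[1]] - r$lengths[hit[1]])
}

#' Detect force events 1-5 within one swallow's analysis window
#'
#' The window should span from the preceding swallow's event 5 (start of its
#' major force drop) through this swallow's event 5. Within it the detector:
#' smooths the force (moving average), takes the derivative, and locates
#' (3) the start of the sustained rapid rise out of the force minimum,
#' (4) the start of force deceleration as force approaches its maximum,
#' (5) the start of the rapid force decrease after force maintenance,
#' (1) the end of the preceding rapid decrease at an intermediate plateau and
#' (2) the start of the final drop from that plateau to the minimum. When the
#' force falls smoothly to its minimum with no intermediate plateau, events 1
#' and 2 are reported NA and stage I is undefined.
#'
#' @param force force samples (mN) covering the window.
#' @param sample_rate sampling rate (Hz).
#' @param window c(start, end) of the analysis window (s); \code{force} is
#'   assumed to start at \code{window[1]}.
#' @param params an \code{\link{event_detector_params}}.
#' @return a \code{\link{force_segmentation}} (stage V runs to the window
#'   end).
#' @export
segment_force <- function(force, sample_rate, window,
                          params = event_detector_params()) {
  p <- params
  n <- length(force)
  if (n < sample_rate * 0.5) stop("segmentation error: window too short")
  t <- window[1] + (seq_len(n) - 1) / sample_rate
  k <- max(1L, round(p$smooth_width * sample_rate))
  f <- as.numeric(stats::filter(force, rep(1 / k, k), sides = 2))
  # pad the ends lost to the centered moving average
  ok <- which(!is.na(f))
  f[seq_len(ok[1] - 1)] <- f[ok[1]]
  if (ok[length(ok)] < n) f[(ok[length(ok)] + 1):n] <- f[ok[length(ok)]]
  rng <- max(f) - min(f)
  if (rng <= 0 || !is.finite(rng))
    stop("segmentation error: flat force trace, no rise/fall structure")
  # slope by central differences over the smoothing width: robust to sample
  # noise, so sustained-run tests see the waveform geometry, not the noise
  m <- max(1L, round(k / 2))
  ihi <- pmin(seq_len(n) + m, n)
  ilo <- pmax(seq_len(n) - m, 1L)
  d <- (f[ihi] - f[ilo]) * sample_rate / (ihi - ilo) / rng
  run <- max(1L, round(p$min_run * sample_rate))
  imax <- which.max(f)
  imin <- which.min(f[1:imax])
  # event 3: sustained rapid rise out of the minimum
  i3 <- first_sustained(d > p$rise_thresh, imin, run)
  if (is.na(i3) || i3 >= imax)
    stop("segmentation error: event 3 (start of force rise) not found")
  # event 4: rise decelerates (wait until the rise is fully under way, then
  # find where the slope drops back below the deceleration threshold)
  i4a <- first_sustained(d > p$decel_thresh, i3, run)
  if (is.na(i4a)) i4a <- i3
  i4 <- first_sustained(d < p$decel_thresh, i4a + run, run)
  if (is.na(i4))
    stop("segmentation error: event 4 (start of force deceleration) not found")
  # event 5: rapid decrease at the end of retraction
  i5 <- first_sustained(d < -p$fall_thresh, i4 + run, run)
  if (is.na(i5))
    stop("segmentation error: event 5 (start of force decrease) not found")
  # events 1/2: intermediate plateau between the preceding fall and the dip
  lvl <- min(f[1:imax]) + p$plateau_level * rng
  i1 <- i2 <- NA_integer_
  ifall <- first_sustained(d < -p$fall_end_thresh, 1L, run)
  cand1 <- if (is.na(ifall) || ifall >= imin) NA_integer_ else
    first_sustained(d > -p$fall_end_thresh, ifall + run, run)
  if (!is.na(cand1) && cand1 < imin && f[cand1] > lvl) {
    i1 <- cand1
    i2 <- first_sustained(d < -p$dip_thresh, i1 + run, run)
    if (is.na(i2) || i2 >= i3) { i1 <- NA_integer_; i2 <- NA_integer_ }
  }
  ev_t <- function(i) if (is.na(i)) NA_real_ else t[i]
  force_segmentation(e1 = ev_t(i1), e2 = ev_t(i2), e3 = t[i3], e4 = t[i4],
                     e5 = t[i5], v_end = t[n])
}

#' Load manual force-event annotations
#'
#' Manual event placements are the authoritative segmentation; stage
#' intervals are derived from them exactly as for automatic events. Columns:
#' animal, swallow, e1, e2, e3, e4, e5, v_end (e1/e2 may be blank for
#' swallows without a partial-maintenance plateau; v_end optional).
#'
#' @param path CSV file of events.
#' @return list of \code{\link{force_segmentation}}, one per row, with
#'   attributes \code{animal} and \code{swallow} on each element.
#' @export
load_manual_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("animal", "swallow", "e3", "e4", "e5")
  if (!all(need %in% names(df)))
    stop("manual event CSV must have columns: ", paste(need, collapse = ", "))
  if (!"e1" %in% names(df)) df$e1 <- NA_real_
  if (!"e2" %in% names(df)) df$e2 <- NA_real_
  if (!"v_end" %in% names(df)) df$v_end <- NA_real_
  lapply(seq_len(nrow(df)), function(i) {
    seg <- force_segmentation(df$e1[i], df$e2[i], df$e3[i], df$e4[i],
                              df$e5[i], df$v_end[i])
    attr(seg, "animal") <- df$animal[i]
    attr(seg, "swallow") <- df$swallow[i]
    seg
  })
}

#' Write force segmentations to CSV
#'
#' @param segs list of \code{\link{force_segmentation}}s.
#' @param path output CSV path.
#' @param animal,swallow identifier vectors recycled across \code{segs};
#'   default to attributes stored on each element.
#' @return \code{path}, invisibly.
#' @export
write_segmentations <- function(segs, path, animal = NULL, swallow = NULL) {
  rows <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    data.frame(
      animal = if (!is.null(animal)) animal[[i]] else
        attr(s, "animal") %||% NA,
      swallow = if (!is.null(swallow)) swallow[[i]] else
        attr(s, "swallow") %||% i,
      e1 = s$events[["e1"]], e2 = s$events[["e2"]], e3 = s$events[["e3"]],
      e4 = s$events[["e4"]], e5 = s$events[["e5"]],
      v_end = if (is.null(s$stages$V)) NA_real_ else s$stages$V[2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
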