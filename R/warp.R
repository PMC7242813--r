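#' Piecewise-linear warp map
#'
#' Monotone piecewise-linear map taking source boundary times exactly onto
#' target boundary times; each segment between boundaries is linearly
#' stretched or compressed by the ratio of target to source duration. Used to
#' align swallows of different phase durations at every stage boundary.
#'
#' @param src,tgt strictly increasing boundary times (s) of equal length
#'   (>= 2).
#' @return object of class \code{"warp_map"}.
#' @export
warp_map <- function(src, tgt) {
  src <- as.numeric(src); tgt <- as.numeric(tgt)
  if (length(src) != length(tgt) || length(src) < 2)
    stop("src and tgt must be equal-length boundary vectors (>= 2)")
  if (is.unsorted(src, strictly = TRUE) || is.unsorted(tgt, strictly = TRUE))
    stop("boundaries must be strictly increasing in both frames")
  structure(list(src = src, tgt = tgt), class = "warp_map")
}

#' Apply a warp map to times
#'
#' @param map a \code{\link{warp_map}}.
#' @param times numeric times (s).
#' @param clip what to do with times outside the source domain:
#'   \code{"na"} (default) maps them to NA so callers can drop the objects
#'   (e.g. bursts before an undefined stage I), \code{"error"} stops.
#' @return warped times, same length.
#' @export
warp_times <- function(map, times, clip = c("na", "error")) {
  clip <- match.arg(clip)
  out <- stats::approx(map$src, map$tgt, xout = times, rule = 1)$y
  if (clip == "error" && anyNA(out[!is.na(times)]))
    stop("time outside warp domain [", map$src[1], ", ",
         map$src[length(map$src)], "]")
  out
}

#' Build the warp for a loaded swallow from its force segmentation
#'
#' Boundaries are the defined force events (plus the stage V end); each stage
#' is linearly stretched or compressed so that all swallows align at every
#' boundary between stages. Example: matching stage durations (1, 2, 2, 1, 1)
#' to (1, 1, 2, 3, 1) halves stage II and triples stage IV. Swallows with an
#' undefined partial-maintenance stage (no events 1/2) have no usable
#' boundary before event 3: their warp domain starts at event 3, and data
#' before it are dropped from aggregation.
#'
#' @param seg a \code{\link{force_segmentation}}.
#' @param target_durations named or positional numeric vector of target stage
#'   durations for stages I..V (seconds); entries for stages undefined in
#'   \code{seg} are ignored.
#' @param target_origin target time of the first defined boundary; defaults
#'   so that event 3 (the start of the force rise, defined for every swallow)
#'   always maps to the summed target durations of stages I and II, keeping
#'   all swallows on one common timeline.
#' @return a \code{\link{warp_map}}.
#' @export
build_warp_loaded <- function(seg, target_durations, target_origin = NULL) {
  td <- as.numeric(target_durations)
  if (length(td) != 5 || any(td[3:5] <= 0))
    stop("target_durations must give 5 stage durations (I..V)")
  ev <- seg$events
  v_end <- if (!is.null(seg$stages$V)) seg$stages$V[2] else NA_real_
  has_I <- !is.na(ev[["e1"]])
  if (has_I) {
    src <- c(ev[["e1"]], ev[["e2"]], ev[["e3"]], ev[["e4"]], ev[["e5"]])
    tgt <- cumsum(c(0, td[1], td[2], td[3], td[4]))
  } else {
    src <- c(ev[["e3"]], ev[["e4"]], ev[["e5"]])
    tgt <- cumsum(c(td[1] + td[2], td[3], td[4]))
  }
  if (!is.na(v_end)) {
    if (v_end <= src[length(src)]) stop("zero-duration stage V")
    src <- c(src, v_end)
    tgt <- c(tgt, tgt[length(tgt)] + td[5])
  }
  if (any(diff(src) <= 0)) stop("zero-duration stage in source swallow")
  if (!is.null(target_origin)) tgt <- tgt - tgt[1] + target_origin
  warp_map(src, tgt)
}

#' Build the warp for an unloaded swallow from its inward movement
#'
#' No force record exists for unloaded swallows; they are aligned on the
#' video-scored period of inward seaweed movement. The whole swallow is
#' rescaled by the single factor target/source inward duration, and shifted
#' so the inward start maps to \code{target_start}: inward endpoints align
#' exactly and a swallow with 2 s of inward movement matched to a 1 s target
#' has its total duration halved.
#'
#' @param annotation one row of a swallow annotation table (needs
#'   inward_start, inward_end).
#' @param target_duration target inward-movement duration (s).
#' @param target_start target time of inward-movement onset (default 0).
#' @return a \code{\link{warp_map}} whose two boundaries are the inward
#'   endpoints; because the map is globally linear, \code{\link{warp_times}}
#'   with \code{clip = "na"} would clip, so use \code{\link{warp_times_linear}}
#'   or the returned map's \code{scale}/\code{offset} attributes for points
#'   outside the inward interval.
#' @export
build_warp_unloaded <- function(annotation, target_duration,
                                target_start = 0) {
  s <- annotation$inward_start; e <- annotation$inward_end
  if (is.null(s) || is.na(s) || is.null(e) || is.na(e))
    stop("annotation has no inward-movement interval")
  scale <- target_duration / (e - s)
  m <- warp_map(c(s, e), c(target_start, target_start + target_duration))
  attr(m, "scale") <- scale
  attr(m, "offset") <- target_start - s * scale
  class(m) <- c("warp_map_linear", class(m))
  m
}

#' @rdname build_warp_unloaded
#' @param map a linear warp from \code{build_warp_unloaded}.
#' @param times times to map (any real time; the linear map extrapolates).
#' @export
warp_times_linear <- function(map, times) {
  attr(map, "scale") * times + attr(map, "offset")
}

#' Warp bursts and sampled series onto the common timeline
#'
#' Burst start/stop times are mapped through the warp; series (force or
#' smoothed firing rate, data.frames with \code{time} and a value column) are
#' resampled onto a uniform grid in the target frame by linear interpolation.
#' Ordering is preserved (the map is monotone). Bursts entirely outside the
#' warp domain are dropped with \code{warped = NA}.
#'
#' @param map a \code{\link{warp_map}} (linear unloaded maps extrapolate;
#'   loaded maps clip to their domain).
#' @param bursts optional data.frame with columns start, end (+ anything
#'   else, carried through).
#' @param series optional data.frame with columns time, value (second column
#'   used as value if named differently).
#' @param grid_rate target grid rate (Hz, default 100).
#' @return list with \code{bursts} (warped bounds) and \code{series}
#'   (data.frame time, value on the uniform target grid).
#' @export
apply_warp <- function(map, bursts = NULL, series = NULL, grid_rate = 100) {
  lin <- inherits(map, "warp_map_linear")
  wt <- function(x) if (lin) warp_times_linear(map, x) else warp_times(map, x)
  out <- list()
  if (!is.null(bursts) && nrow(bursts)) {
    b <- bursts
    b$start <- wt(bursts$start)
    b$end <- wt(bursts$end)
    out$bursts <- b
  } else out$bursts <- bursts
  if (!is.null(series) && nrow(series)) {
    tt <- wt(series$time)
    val <- series[[setdiff(names(series), "time")[1]]]
    ok <- !is.na(tt)
    grid <- seq(min(tt[ok]), max(tt[ok]), by = 1 / grid_rate)
    out$series <- data.frame(
      time = grid,
      value = stats::approx(tt[ok], val[ok], xout = grid)$y)
  } else out$series <- NULL
  out
}

#' Aggregate warped swallows: pointwise median and quartiles
#'
#' All swallows must have been warped onto the same target timeline (stage
#' boundaries at identical target times — use per-cohort median stage
#' durations as targets, so the aggregate timeline already has each stage at
#' its median observed duration). Produces the pointwise median and
#' lower/upper quartile of every series at each grid time (linear-interpolated
#' "type 7" quartiles), using the swallows that have data there (swallows with
#' an undefined stage I contribute nothing before the force rise), plus
#' median/quartile warped burst start and stop times per unit.
#'
#' @param warped list of results from \code{\link{apply_warp}} (one per
#'   swallow).
#' @param grid_rate grid rate (Hz) of the common timeline.
#' @return list with \code{traces} (data.frame time, median, q25, q75, n) and
#'   \code{burst_timing} (data.frame unit, start_median, start_q25, start_q75,
#'   end_median, end_q25, end_q75, n).
#' @export
aggregate_swallows <- function(warped, grid_rate = 100) {
  series <- Filter(Negate(is.null), lapply(warped, `[[`, "series"))
  traces <- NULL
  if (length(series)) {
    lo <- min(vapply(series, function(s) s$time[1], numeric(1)))
    hi <- max(vapply(series, function(s) s$time[nrow(s)], numeric(1)))
    grid <- seq(lo, hi, by = 1 / grid_rate)
    vals <- vapply(series, function(s)
      stats::approx(s$time, s$value, xout = grid)$y,
      numeric(length(grid)))
    vals <- matrix(vals, nrow = length(grid))
    qs <- t(apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA, NA, NA, 0))
      c(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7), length(v))
    }))
    traces <- data.frame(time = grid, median = qs[, 2], q25 = qs[, 1],
                         q75 = qs[, 3], n = qs[, 4])
  }
  bursts <- do.call(rbind, Filter(function(b) !is.null(b) && nrow(b),
                                  lapply(warped, `[[`, "bursts")))
  burst_timing <- NULL
  if (!is.null(bursts) && nrow(bursts)) {
    ok <- !is.na(bursts$start) & !is.na(bursts$end)
    bursts <- bursts[ok, , drop = FALSE]
    sp <- split(bursts, bursts$unit)
    burst_timing <- do.call(rbind, lapply(sp, function(b) {
      qS <- stats::quantile(b$start, c(0.25, 0.5, 0.75), type = 7)
      qE <- stats::quantile(b$end, c(0.25, 0.5, 0.75), type = 7)
      data.frame(unit = b$unit[1], start_median = qS[2], start_q25 = qS[1],
                 start_q75 = qS[3], end_median = qE[2], end_q25 = qE[1],
                 end_q75 = qE[3], n = nrow(b), row.names = NULL)
    }))
  }
  list(traces = traces, burst_timing = burst_timing)
}

#' Median stage durations of a loaded cohort
#'
#' Target durations for \code{\link{build_warp_loaded}}: the per-stage median
#' duration across all swallows (stages undefined in a swallow contribute
#' nothing to that stage's median).
#'
#' @param segs list of \code{\link{force_segmentation}}s.
#' @return numeric vector of 5 stage durations (I..V); a stage undefined in
#'   every swallow gets NA.
#' @export
median_stage_durations <- function(segs) {
  dur <- function(s, st) {
    iv <- s$stages[[st]]
    if (is.null(iv)) NA_real_ else iv[2] - iv[1]
  }
  vapply(c("I", "II", "III", "IV", "V"), function(st) {
    d <- vapply(segs, dur, numeric(1), st = st)
    stats::median(d, na.rm = TRUE)
  }, numeric(1))
}
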