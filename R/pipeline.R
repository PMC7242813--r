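#' Analyze one session: spikes, bursts, per-swallow measures
#'
#' Runs the detection and burst stages of the pipeline on one recording:
#' window discriminators (with the 100 Hz EMG pre-filter), IFF-threshold
#' burst identification within each annotated swallow cycle, combination of
#' B3 and B6/B9 into the retractor pool, and per-swallow burst duration and
#' mean-rate measures.
#'
#' @param rec a \code{\link{recording}}.
#' @param annotations swallow annotation data.frame (one row per cycle).
#' @param discriminators list of \code{\link{window_discriminator}}s.
#' @param thresholds threshold data.frame (\code{\link{default_thresholds}}).
#' @param combine_b369 combine B3 and B6/B9 into \code{"B3/B6/B9"}.
#' @return list with \code{trains} (per-unit spike trains), \code{bursts}
#'   (list per unit: one \code{\link{burst}} or NULL per swallow) and
#'   \code{measures} (data.frame: swallow, unit, duration, mean_rate,
#'   start, end).
#' @export
analyze_session <- function(rec, annotations,
                            discriminators = default_discriminators(),
                            thresholds = default_thresholds(),
                            combine_b369 = TRUE) {
  trains <- apply_discriminator_set(rec, discriminators)
  windows <- annotations[, c("cycle_start", "cycle_end")]
  bursts <- list()
  for (u in names(trains)) {
    th <- thresholds[thresholds$unit == u, ]
    if (!nrow(th)) next
    bursts[[u]] <- detect_bursts(trains[[u]], th$f_start, th$f_end, windows)
  }
  if (combine_b369 && all(c("B3", "B6/B9") %in% names(bursts))) {
    bursts[["B3/B6/B9"]] <- lapply(seq_len(nrow(windows)), function(k) {
      combine_b3_b6b9(bursts[["B3"]][[k]], bursts[["B6/B9"]][[k]],
                      trains[["B3"]], trains[["B6/B9"]])
    })
  }
  rows <- list()
  for (u in names(bursts)) {
    for (k in seq_along(bursts[[u]])) {
      b <- bursts[[u]][[k]]
      if (is.null(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        swallow = k, unit = u, duration = b$end - b$start,
        mean_rate = mean_burst_rate(b), start = b$start, end = b$end)
    }
  }
  measures <- if (length(rows)) do.call(rbind, rows) else
    data.frame(swallow = integer(), unit = character(), duration = numeric(),
               mean_rate = numeric(), start = numeric(), end = numeric())
  list(trains = trains, bursts = bursts, measures = measures)
}

#' Behavioral durations from swallow annotations
#'
#' Total cycle time (start of one inward movement to the start of the next),
#' inward-movement duration, and time between inward movements, per swallow.
#' The last swallow of a session has no following inward movement, so its
#' cycle time and between-movement duration are NA.
#'
#' @param annotations annotation data.frame ordered by cycle_start, one
#'   session/condition at a time.
#' @return data.frame: swallow, cycle_time, inward_duration, between_duration.
#' @export
behavioral_durations <- function(annotations) {
  a <- annotations[order(annotations$cycle_start), ]
  n <- nrow(a)
  nxt <- c(a$inward_start[-1], NA)
  data.frame(
    swallow = seq_len(n),
    cycle_time = nxt - a$inward_start,
    inward_duration = a$inward_end - a$inward_start,
    between_duration = nxt - a$inward_end)
}

#' Pipeline configuration
#'
#' @param n_animals number of synthetic animals.
#' @param n_swallows swallows per condition per animal.
#' @param seed master seed; per-session seeds are derived from it.
#' @param cfg generator configuration (\code{\link{session_config}}).
#' @param templates unit templates.
#' @param discriminators window discriminators.
#' @param thresholds burst thresholds.
#' @param seg_params force-event detector parameters.
#' @param seg_extension seconds of signal past each cycle end handed to the
#'   force-event detector (the rapid decrease marking event 5 begins at the
#'   cycle end).
#' @param grid_rate normalization grid rate (Hz).
#' @param out optional run directory; when given, every stage's output is
#'   written (recordings, spikes, segmentations, tables, JSON report).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(n_animals = 5, n_swallows = 5, seed = 1,
                            cfg = session_config(),
                            templates = default_unit_templates(),
                            discriminators = default_discriminators(),
                            thresholds = default_thresholds(),
                            seg_params = event_detector_params(),
                            seg_extension = 0.35,
                            grid_rate = 100, out = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic end-to-end study
#'
#' simulate -> detect -> bursts -> (segment) -> paired tables -> statistics.
#' For each animal, one unloaded and one loaded session are generated with
#' seeds derived from the master seed, analyzed, and reduced to per-animal
#' condition means of burst durations, mean burst rates, and behavioral
#' durations; the grouped statistical plan is then run on the resulting
#' tables. Deterministic for a fixed seed. With \code{config$out} set, all
#' intermediate artifacts and a structured log (one line per swallow and
#' stage, including dropped-swallow counts) are written under stage-numbered
#' subdirectories.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{tables} (named \code{\link{paired_table}}s),
#'   \code{stats} (plan results), \code{per_swallow} (long data.frame of all
#'   measures), \code{segmentations} (per animal, loaded swallows), and
#'   \code{log} (character vector).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log[[length(log) + 1L]] <<- msg
    invisible(msg)
  }
  out_dir <- cf$out
  stage_dir <- function(stage) {
    if (is.null(out_dir)) return(NULL)
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    d
  }
  unit_measures <- c("B38" = "b38", "I2" = "i2", "B8a/b" = "b8ab",
                     "B3/B6/B9" = "b369", "B4/B5" = "b4b5")
  per_swallow <- list()
  segmentations <- list()
  for (ai in seq_len(cf$n_animals)) {
    for (cond in c("unloaded", "loaded")) {
      sseed <- cf$seed * 1000L + ai * 10L + (cond == "loaded")
      ses <- generate_session(cf$n_swallows, cond, cf$templates, cf$cfg,
                              seed = sseed, animal = paste0("A", ai))
      say("simulate animal=%d cond=%s seed=%d swallows=%d", ai, cond,
          sseed, cf$n_swallows)
      if (!is.null(d <- stage_dir("01_simulate"))) {
        write_recording(ses$recording,
                        file.path(d, sprintf("A%d_%s.csv", ai, cond)))
        write_annotations(ses$annotations,
                          file.path(d, sprintf("A%d_%s_annotations.csv",
                                               ai, cond)))
      }
      res <- analyze_session(ses$recording, ses$annotations,
                             cf$discriminators, cf$thresholds)
      if (!is.null(d <- stage_dir("02_spikes")))
        write_spikes(res$trains, file.path(d, sprintf("A%d_%s_spikes.csv",
                                                      ai, cond)))
      beh <- behavioral_durations(ses$annotations)
      if (cond == "loaded") {
        if (!any(ses$recording$roles == "force"))
          stop("segmentation stage: no force channel in loaded session ",
               "animal ", ai)
        force <- force_channel(ses$recording)
        sr <- ses$recording$sample_rate
        segs <- lapply(seq_len(cf$n_swallows), function(k) {
          # extend past the cycle end so the post-retraction rapid force
          # decrease (event 5) is visible to the detector
          w <- c(ses$annotations$cycle_start[k],
                 min(ses$annotations$cycle_end[k] + cf$seg_extension,
                     rec_duration(ses$recording)))
          i0 <- round(w[1] * sr) + 1L
          i1 <- round(w[2] * sr) + 1L
          tryCatch(segment_force(force[i0:i1], sr, w, cf$seg_params),
                   error = function(e) {
                     stop("segmentation stage failed for animal ", ai,
                          " swallow ", k, ": ", conditionMessage(e))
                   })
        })
        n_undef <- sum(vapply(segs, function(s) is.null(s$stages$I),
                              logical(1)))
        say("segment animal=%d swallows=%d undefined_stage_I=%d", ai,
            cf$n_swallows, n_undef)
        segmentations[[paste0("A", ai)]] <- segs
        if (!is.null(d <- stage_dir("03_segment")))
          write_segmentations(segs, file.path(d, sprintf("A%d_stages.csv",
                                                         ai)),
                              animal = rep(paste0("A", ai), length(segs)),
                              swallow = seq_along(segs))
      }
      m <- res$measures
      m$animal <- ai
      m$condition <- cond
      m <- merge(m, beh, by = "swallow", all.x = TRUE)
      per_swallow[[length(per_swallow) + 1L]] <- m
      say("bursts animal=%d cond=%s detected=%d", ai, cond, nrow(res$measures))
    }
  }
  per_swallow <- do.call(rbind, per_swallow)

  # per-animal condition means -> paired tables
  tables <- list()
  agg <- function(value_col, unit = NULL, measure) {
    sub <- if (is.null(unit)) per_swallow[!duplicated(
      per_swallow[, c("animal", "condition", "swallow")]), ]
    else per_swallow[per_swallow$unit == unit, ]
    mean_of <- function(cond, ai) {
      v <- sub[[value_col]][sub$condition == cond & sub$animal == ai]
      v <- v[!is.na(v)]
      c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
    }
    u <- t(vapply(seq_len(cf$n_animals), function(ai) mean_of("unloaded", ai),
                  numeric(2)))
    l <- t(vapply(seq_len(cf$n_animals), function(ai) mean_of("loaded", ai),
                  numeric(2)))
    paired_table(measure, seq_len(cf$n_animals), u[, 1], l[, 1],
                 as.integer(u[, 2]), as.integer(l[, 2]))
  }
  tables$total_cycle_time <- agg("cycle_time", NULL, "total_cycle_time")
  tables$inward_movement <- agg("inward_duration", NULL, "inward_movement")
  tables$between_movements <- agg("between_duration", NULL,
                                  "between_movements")
  for (u in names(unit_measures)) {
    tables[[paste0(unit_measures[[u]], "_duration")]] <-
      agg("duration", u, paste0(unit_measures[[u]], "_duration"))
    tables[[paste0(unit_measures[[u]], "_frequency")]] <-
      agg("mean_rate", u, paste0(unit_measures[[u]], "_frequency"))
  }

  # the bivariate Hotelling tests need n > 2 animals
  if (cf$n_animals >= 3) {
    stats_res <- run_stats_plan(tables, default_stats_plan())
    say("stats groups=%d", length(default_stats_plan()))
  } else {
    stats_res <- NULL
    say("stats skipped: %d animal(s) cannot support the paired battery",
        cf$n_animals)
  }
  if (!is.null(d <- stage_dir("04_results"))) {
    write_results(tables, stats_res, d)
    writeLines(log, file.path(out_dir, "run.log"))
    jsonlite::write_json(list(seed = cf$seed, n_animals = cf$n_animals,
                              n_swallows = cf$n_swallows),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE)
  }
  list(tables = tables, stats = stats_res, per_swallow = per_swallow,
       segmentations = segmentations, log = log)
}

#' Normalize and aggregate a loaded cohort
#'
#' Builds per-swallow warps onto the cohort-median stage durations,
#' warps burst bounds and the force trace of every swallow, and aggregates
#' (pointwise median/quartiles plus burst-timing quartiles). Swallows with an
#' undefined stage I contribute no data before the force rise.
#'
#' @param segs list of \code{\link{force_segmentation}}s.
#' @param bursts_per_swallow list (one per swallow) of data.frames with
#'   columns unit, start, end.
#' @param force_series optional list (one per swallow) of data.frames
#'   time/value with the raw force samples of that swallow's window.
#' @param grid_rate common grid rate (Hz).
#' @return list from \code{\link{aggregate_swallows}} plus
#'   \code{target_durations} and \code{n_dropped_pre_rise}.
#' @export
normalize_loaded_cohort <- function(segs, bursts_per_swallow,
                                    force_series = NULL, grid_rate = 100) {
  td <- median_stage_durations(segs)
  if (anyNA(td[3:5])) stop("cannot form target durations: stages III-V ",
                           "undefined across the cohort")
  if (is.na(td[1])) td[1] <- 0.5
  if (is.na(td[2])) td[2] <- 0.5
  warped <- lapply(seq_along(segs), function(k) {
    m <- build_warp_loaded(segs[[k]], td)
    apply_warp(m, bursts = bursts_per_swallow[[k]],
               series = if (is.null(force_series)) NULL else
                 force_series[[k]],
               grid_rate = grid_rate)
  })
  out <- aggregate_swallows(warped, grid_rate)
  out$target_durations <- td
  out$n_dropped_pre_rise <- sum(vapply(segs, function(s)
    is.null(s$stages$I), logical(1)))
  out
}
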