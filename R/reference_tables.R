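#' Reference per-animal condition means for Aplysia swallowing under load
#'
#' Bundled summary data from in vivo recordings of five Aplysia californica
#' feeding on unloaded versus tension-loaded seaweed strips: per-animal mean
#' behavioral durations (total cycle time, inward-movement duration, time
#' between inward movements; seconds), per-unit burst durations (seconds) and
#' mean burst firing rates (Hz) for the identified units B38, I2, B8a/b, the
#' combined retractor pool B3/B6/B9, and B4/B5, under each condition, with
#' per-condition swallow counts. These tables are the worked-example inputs
#' for the paired statistical battery (\code{\link{run_stats_plan}}); the
#' means are as published, rounded to two decimals.
#'
#' @return named list of \code{\link{paired_table}}s with measures:
#'   \code{total_cycle_time}, \code{inward_movement},
#'   \code{between_movements}, \code{b38_duration}, \code{i2_duration},
#'   \code{b8ab_duration}, \code{b369_duration}, \code{b4b5_duration},
#'   \code{b38_frequency}, \code{i2_frequency}, \code{b8ab_frequency},
#'   \code{b369_frequency}, \code{b4b5_frequency}.
#' @export
reference_tables <- function() {
  an <- 1:5
  mk <- function(measure, u, l, n_u, n_l)
    paired_table(measure, an, u, l, n_u, n_l)
  n_beh_u <- c(4, 4, 4, 3, 6); n_beh_l <- c(4, 12, 4, 7, 4)
  n_inw_u <- c(4, 4, 4, 4, 7); n_inw_l <- c(5, 15, 5, 9, 5)
  n_unit_u <- c(10, 6, 6, 6, 11); n_unit_l <- c(5, 15, 5, 9, 5)
  list(
    total_cycle_time = mk("total_cycle_time",
      c(5.45, 5.97, 4.76, 4.65, 6.48), c(6.91, 7.48, 7.80, 6.39, 6.99),
      n_beh_u, n_beh_l),
    inward_movement = mk("inward_movement",
      c(1.35, 2.83, 2.02, 1.95, 1.56), c(3.00, 3.55, 2.80, 2.75, 2.68),
      n_inw_u, n_inw_l),
    between_movements = mk("between_movements",
      c(4.10, 3.15, 2.74, 2.78, 4.89), c(3.83, 3.80, 5.05, 3.51, 4.66),
      n_beh_u, n_beh_l),
    b38_duration = mk("b38_duration",
      c(1.44, 1.92, 0.50, 0.94, 1.45), c(1.72, 1.81, 0.49, 1.51, 1.24),
      n_unit_u, n_unit_l),
    i2_duration = mk("i2_duration",
      c(1.46, 1.63, 1.61, 1.58, 1.68), c(1.12, 1.83, 1.36, 1.16, 1.12),
      n_unit_u, n_unit_l),
    b8ab_duration = mk("b8ab_duration",
      c(3.13, 3.58, 2.73, 2.86, 3.34), c(3.99, 4.31, 4.31, 4.07, 3.70),
      n_unit_u, n_unit_l),
    b369_duration = mk("b369_duration",
      c(1.87, 1.66, 1.38, 1.72, 2.01), c(2.77, 2.71, 3.14, 2.98, 2.67),
      n_unit_u, n_unit_l),
    b4b5_duration = mk("b4b5_duration",
      c(1.58, 2.07, 0.00, 1.79, 2.85), c(1.84, 3.09, 0.65, 3.25, 3.36),
      n_unit_u, n_unit_l),
    b38_frequency = mk("b38_frequency",
      c(10.95, 10.44, 4.50, 11.88, 7.41), c(10.57, 11.40, 3.35, 13.57, 9.04),
      n_unit_u, n_unit_l),
    i2_frequency = mk("i2_frequency",
      c(15.17, 12.33, 12.80, 15.37, 12.92),
      c(15.71, 12.43, 15.66, 16.15, 14.68),
      n_unit_u, n_unit_l),
    b8ab_frequency = mk("b8ab_frequency",
      c(12.00, 18.22, 21.61, 22.20, 10.32),
      c(12.20, 22.91, 23.40, 21.46, 12.32),
      n_unit_u, n_unit_l),
    b369_frequency = mk("b369_frequency",
      c(38.99, 14.79, 27.85, 30.40, 9.12),
      c(42.27, 16.59, 37.90, 37.87, 15.66),
      n_unit_u, n_unit_l),
    b4b5_frequency = mk("b4b5_frequency",
      c(21.29, 7.43, 0.00, 10.47, 13.97), c(17.57, 9.27, 3.44, 13.81, 17.85),
      n_unit_u, n_unit_l))
}

#' The planned variable grouping of the statistical battery
#'
#' Total cycle time is tested first on its own; its two components (inward
#' movement, time between movements) at 0.05/2 each. Unit measures form
#' three groups per quantity (duration, frequency): the protraction pair
#' (B38, I2), the retraction pair (B8a/b, B3/B6/B9) — each a paired
#' Hotelling's T2 with Bonferroni post hoc t tests — and the univariate
#' multiaction B4/B5 via the normality-gated paired comparison.
#'
#' @return plan list for \code{\link{run_stats_plan}}.
#' @export
default_stats_plan <- function() {
  list(
    list(name = "cycle_time", measures = "total_cycle_time"),
    list(name = "protraction_durations",
         measures = c("b38_duration", "i2_duration")),
    list(name = "retraction_durations",
         measures = c("b8ab_duration", "b369_duration")),
    list(name = "b4b5_duration", measures = "b4b5_duration"),
    list(name = "protraction_frequencies",
         measures = c("b38_frequency", "i2_frequency")),
    list(name = "retraction_frequencies",
         measures = c("b8ab_frequency", "b369_frequency")),
    list(name = "b4b5_frequency", measures = "b4b5_frequency"))
}
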