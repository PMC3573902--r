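# Diel (nocturnal/diurnal) aggregation of growth time series.
#
# An experimental "day" starts at light-on and consists of one light
# period followed by the ensuing dark period, so each diurnal period is
# paired with its own night. Periods are half-open: a sample exactly at
# light-on is diurnal, a sample exactly at light-off is nocturnal.
# Standard errors are taken across replicate plants, never across time
# windows: windows within a period are first averaged per plant.

#' Light schedule of the growth chamber
#'
#' @param light_on,light_off Clock hours in [0, 24); the study default is
#'   a 12 h / 12 h light-dark cycle.
#' @return A list of class `light_schedule` with the derived photoperiod.
#' @export
light_schedule <- function(light_on = 8, light_off = 20) {
  if (light_on < 0 || light_on >= 24 || light_off < 0 || light_off >= 24)
    abort_pf("clock hours must lie in [0, 24)", "phytoflow_validation_error")
  photoperiod <- (light_off - light_on) %% 24
  if (photoperiod <= 0 || photoperiod >= 24)
    abort_pf("photoperiod must lie strictly between 0 and 24 h",
             "phytoflow_validation_error")
  structure(list(light_on = light_on, light_off = light_off,
                 photoperiod = photoperiod),
            class = "light_schedule")
}

#' Label samples as diurnal or nocturnal and assign day indices
#'
#' A sample is diurnal iff its clock time falls in `[light_on, light_off)`
#' (half-open, wrapping at midnight); the day index increments at each
#' light-on event, starting at 1 for the day the experiment begins in.
#' Windowed values should be passed by their window-centre time.
#'
#' @param elapsed_h Hours since experiment start (vector).
#' @param start_clock_time Clock time at `elapsed_h = 0`, hours.
#' @param schedule [light_schedule()].
#' @return Data frame with `elapsed_h`, `clock_h`, `period`
#'   (factor diurnal/nocturnal) and `day` (1-based).
#' @export
partition_periods <- function(elapsed_h, start_clock_time,
                              schedule = light_schedule()) {
  stopifnot(inherits(schedule, "light_schedule"))
  H <- start_clock_time + elapsed_h            # absolute, monotone hours
  clock_h <- H %% 24
  phase <- (clock_h - schedule$light_on) %% 24
  period <- factor(ifelse(phase < schedule$photoperiod,
                          "diurnal", "nocturnal"),
                   levels = c("diurnal", "nocturnal"))
  dayno <- floor((H - schedule$light_on) / 24)
  data.frame(elapsed_h = elapsed_h, clock_h = clock_h, period = period,
             day = as.integer(dayno - min(dayno) + 1L))
}

#' Per-day period means of a windowed series
#'
#' @param values Window values (same length as `labels` rows).
#' @param labels Output of [partition_periods()] for the window centres.
#' @return Data frame with `day`, `period`, `mean` and `n` (number of
#'   windows); period/day cells with no samples are absent.
#' @export
period_mean <- function(values, labels) {
  stopifnot(length(values) == nrow(labels))
  keep <- is.finite(values)
  if (!all(keep))
    message(sprintf("period_mean: ignoring %d missing window(s)", sum(!keep)))
  agg <- aggregate(list(mean = values[keep]),
                   by = list(day = labels$day[keep],
                             period = labels$period[keep]),
                   FUN = mean)
  cnt <- aggregate(list(n = values[keep]),
                   by = list(day = labels$day[keep],
                             period = labels$period[keep]),
                   FUN = length)
  out <- merge(agg, cnt, by = c("day", "period"))
  out[order(out$day, out$period), , drop = FALSE]
}

#' Normalise period means to the daily total
#'
#' Shares are `100 * mean_p / (mean_diurnal + mean_nocturnal)` so that
#' nocturnal + diurnal = 100 exactly for each day.
#'
#' @param diurnal_mean,nocturnal_mean Non-negative period means
#'   (vectorised over days).
#' @return Data frame with `diurnal_share` and `nocturnal_share` in
#'   percent; `NA` where both means are zero.
#' @export
normalize_daily <- function(diurnal_mean, nocturnal_mean) {
  stopifnot(length(diurnal_mean) == length(nocturnal_mean))
  if (any(diurnal_mean < 0 | nocturnal_mean < 0, na.rm = TRUE))
    abort_pf("period means must be non-negative", "phytoflow_validation_error")
  tot <- diurnal_mean + nocturnal_mean
  ds <- ifelse(tot > 0, 100 * diurnal_mean / tot, NA_real_)
  data.frame(diurnal_share = ds, nocturnal_share = 100 - ds)
}

#' Standard error across replicate plants
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n);
#' undefined (`NA`) for fewer than two replicates.
#'
#' @param values One value per replicate plant.
#' @return The standard error of the mean.
#' @export
replicate_sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) return(NA_real_)
  sd(values) / sqrt(n)
}

#' Percent treatment effect per (day, period) cell
#'
#' @param summary_control,summary_treatment Data frames with columns
#'   `day`, `period`, `mean` (as from [period_mean()] or
#'   [diel_summary()]).
#' @return Data frame with `day`, `period`, `control`, `treatment` and
#'   `percent_change` = 100 (treatment - control) / control (`NA` where
#'   the control mean is zero).
#' @export
treatment_effect <- function(summary_control, summary_treatment) {
  m <- merge(summary_control[, c("day", "period", "mean")],
             summary_treatment[, c("day", "period", "mean")],
             by = c("day", "period"), suffixes = c("_control", "_treatment"))
  if (nrow(m) == 0)
    abort_pf("no matched (day, period) cells between summaries",
             "phytoflow_validation_error")
  data.frame(day = m$day, period = m$period,
             control = m$mean_control, treatment = m$mean_treatment,
             percent_change = ifelse(m$mean_control != 0,
                                     100 * (m$mean_treatment - m$mean_control) /
                                       m$mean_control, NA_real_))
}

#' Diel summary across replicate plants
#'
#' For each replicate, window values are averaged within each (day,
#' period) cell; the summary then reports the across-replicate mean and
#' standard error of the period means, and of the daily normalised shares
#' (each replicate is normalised to its own daily total, so the mean
#' shares still sum to 100).
#'
#' @param series List of replicate data frames, each with columns
#'   `elapsed_h` (window centre, hours since start) and `value`.
#' @param start_clock_time Clock time at `elapsed_h = 0`.
#' @param schedule [light_schedule()].
#' @return Data frame with `day`, `period`, `mean`, `sem`, `n`,
#'   `share_pct`, `share_sem`.
#' @export
diel_summary <- function(series, start_clock_time,
                         schedule = light_schedule()) {
  stopifnot(is.list(series), length(series) >= 1)
  per_rep <- lapply(seq_along(series), function(r) {
    s <- series[[r]]
    lab <- partition_periods(s$elapsed_h, start_clock_time, schedule)
    pm <- period_mean(s$value, lab)
    pm$replicate <- r
    pm
  })
  cells <- do.call(rbind, per_rep)
  # per-replicate daily shares
  shares <- do.call(rbind, lapply(per_rep, function(pm) {
    days <- sort(unique(pm$day))
    do.call(rbind, lapply(days, function(d) {
      dm <- pm$mean[pm$day == d & pm$period == "diurnal"]
      nm <- pm$mean[pm$day == d & pm$period == "nocturnal"]
      if (length(dm) != 1 || length(nm) != 1) return(NULL)
      sh <- normalize_daily(dm, nm)
      data.frame(replicate = pm$replicate[1], day = d,
                 period = c("diurnal", "nocturnal"),
                 share = c(sh$diurnal_share, sh$nocturnal_share))
    }))
  }))
  keys <- unique(cells[, c("day", "period")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- keys$day[i]; p <- keys$period[i]
    v <- cells$mean[cells$day == d & cells$period == p]
    sh <- shares$share[shares$day == d & shares$period == p]
    data.frame(day = d, period = p,
               mean = mean(v), sem = replicate_sem(v), n = length(v),
               share_pct = if (length(sh)) mean(sh) else NA_real_,
               share_sem = replicate_sem(sh))
  }))
  out[order(out$day, out$period), , drop = FALSE]
}
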