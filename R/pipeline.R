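# End-to-end orchestration: simulate -> analyze -> summarize.
#
# These functions are the programmatic surface behind the command-line
# script (inst/cli/phytoflow.R); everything they do is available to
# interactive users as well.

#' Simulate a treatment preset to disk
#'
#' Renders the leaf scene and a diel series of re-staged root acquisition
#' bursts for one treatment preset, writes all stacks as multi-page TIFFs
#' with metadata sidecars, exports the ground truth as CSV and echoes the
#' configuration to YAML for reproducibility.
#'
#' @param preset `"control"`, `"cooling"` or `"illumination"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param schedule [light_schedule()].
#' @param leaf_duration_h Leaf stack duration (hours).
#' @param root_total_h Diel coverage of the root burst series (hours).
#' @param root_every_minutes Spacing of root bursts (minutes).
#' @param write_leaf Render and write the leaf scene (TRUE) or only the
#'   root series.
#' @return Invisibly, a manifest list with the file paths written.
#' @export
run_simulate <- function(preset, out_dir, seed = 1L,
                         schedule = light_schedule(),
                         leaf_duration_h = 24, root_total_h = 24,
                         root_every_minutes = 30, write_leaf = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_pf(sprintf("cannot create output directory '%s'", out_dir),
             "phytoflow_io_error")
  cfgs <- treatment_presets(preset, schedule, seed = seed)
  manifest <- list(preset = preset, seed = seed, dir = out_dir)

  if (write_leaf) {
    leaf_cfg <- cfgs$leaf
    leaf_cfg$duration_h <- leaf_duration_h
    leaf <- make_leaf_stack(leaf_cfg)
    leaf_tif <- file.path(out_dir, "leaf.tif")
    write_stack(leaf$stack, leaf_tif)
    export_truth(leaf$truth, out_dir, "leaf_truth")
    manifest$leaf_tif <- leaf_tif
  }

  rb <- make_root_burst_series(cfgs$root, total_h = root_total_h,
                               burst_minutes = 5,
                               every_minutes = root_every_minutes)
  root_tifs <- character(length(rb$bursts))
  truth_rows <- vector("list", length(rb$bursts))
  for (b in seq_along(rb$bursts)) {
    root_tifs[b] <- file.path(out_dir, sprintf("root_burst_%03d.tif", b))
    write_stack(rb$bursts[[b]]$stack, root_tifs[b])
    tr <- rb$bursts[[b]]$truth$frames
    tr$burst <- b
    tr$elapsed_h <- rb$schedule_df$elapsed_h[b] + tr$t_s / 3600
    truth_rows[[b]] <- tr
  }
  write.csv(do.call(rbind, truth_rows),
            file.path(out_dir, "root_truth_frames.csv"), row.names = FALSE)
  write.csv(rb$schedule_df, file.path(out_dir, "root_bursts.csv"),
            row.names = FALSE)
  manifest$root_tifs <- root_tifs
  manifest$root_bursts_csv <- file.path(out_dir, "root_bursts.csv")

  yaml::write_yaml(list(preset = preset, seed = seed,
                        light_on = schedule$light_on,
                        light_off = schedule$light_off,
                        leaf_duration_h = if (write_leaf) leaf_duration_h else NULL,
                        root_total_h = root_total_h,
                        root_every_minutes = root_every_minutes),
                   file.path(out_dir, "run_config.yaml"))
  invisible(manifest)
}

#' Analyze a leaf stack into an RGR series
#'
#' @param stack An `image_stack` or a TIFF path readable by
#'   [read_stack()].
#' @param aoi0 An [aoi()], or NULL to use a centred octagonal AOI
#'   covering 60% of the frame.
#' @param params [flow_params()]; the default uses a single pyramid level
#'   because leaf expansion displacements are well below 1 px/frame.
#' @param window_minutes RGR window (default 15).
#' @param out_csv Optional CSV output path.
#' @return The [rgr_series()] data frame.
#' @export
run_analyze_leaf <- function(stack, aoi0 = NULL,
                             params = flow_params(pyramid_levels = 1),
                             window_minutes = 15, out_csv = NULL) {
  if (is.character(stack)) stack <- read_stack(stack)
  if (is.null(aoi0)) {
    d <- dim(stack$frames[[1]])
    ang <- (seq_len(8) - 1) * pi / 4 + pi / 8
    r <- 0.3 * min(d)
    aoi0 <- aoi(cbind((d[2] - 1) / 2 + r * cos(ang),
                      (d[1] - 1) / 2 + r * sin(ang)))
  }
  out <- rgr_series(stack, aoi0, params, window_minutes = window_minutes)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Analyze root stacks into a velocity series
#'
#' Accepts either a single stack or a list of burst stacks (as produced
#' by [run_simulate()] / [make_root_burst_series()]); burst series are
#' concatenated on the diel time axis via `elapsed_offsets_h`.
#'
#' @param stacks An `image_stack`, a TIFF path, or a list/vector of
#'   either.
#' @param elapsed_offsets_h Hours since experiment start of each stack's
#'   first frame (default all 0; for simulated runs, read from the
#'   `root_bursts.csv` manifest).
#' @param window_minutes Velocity window (default 5).
#' @param out_csv Optional CSV output path.
#' @param ... Passed to [tip_velocity_series()].
#' @return Combined data frame of per-window velocities with a `burst`
#'   column.
#' @export
run_analyze_root <- function(stacks, elapsed_offsets_h = NULL,
                             window_minutes = 5, out_csv = NULL, ...) {
  if (inherits(stacks, "image_stack") || is.character(stacks) &&
      length(stacks) == 1 && !is.list(stacks))
    stacks <- list(stacks)
  if (is.character(stacks)) stacks <- as.list(stacks)
  elapsed_offsets_h <- elapsed_offsets_h %||% rep(0, length(stacks))
  stopifnot(length(elapsed_offsets_h) == length(stacks))
  rows <- vector("list", length(stacks))
  for (b in seq_along(stacks)) {
    s <- stacks[[b]]
    if (is.character(s)) s <- read_stack(s)
    ts <- tip_velocity_series(s, window_minutes = window_minutes, ...)
    ts$centre_elapsed_h <- ts$centre_elapsed_h + elapsed_offsets_h[b]
    ts$burst <- b
    rows[[b]] <- ts
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Summarize replicate series into a diel table
#'
#' @param series A data frame (one replicate) or list of data frames with
#'   columns `centre_elapsed_h` and the value column.
#' @param start_clock_time Clock time at elapsed hour 0.
#' @param schedule [light_schedule()].
#' @param value_col Column to aggregate (`"velocity_mm_h"` for roots,
#'   `"rgr_area_h"` or `"rgr_div_h"` for leaves).
#' @param out_csv Optional CSV output path.
#' @return The [diel_summary()] data frame.
#' @export
run_summarize <- function(series, start_clock_time,
                          schedule = light_schedule(),
                          value_col = "velocity_mm_h", out_csv = NULL) {
  if (is.data.frame(series)) series <- list(series)
  if (!length(series))
    abort_pf("no series to summarize", "phytoflow_validation_error")
  series <- lapply(series, function(s) {
    if (!all(c("centre_elapsed_h", value_col) %in% names(s)))
      abort_pf(sprintf("series must have columns centre_elapsed_h and %s",
                       value_col), "phytoflow_validation_error")
    data.frame(elapsed_h = s$centre_elapsed_h, value = s[[value_col]])
  })
  out <- diel_summary(series, start_clock_time, schedule)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
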