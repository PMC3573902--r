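# Reading, writing and validating grey-value time-lapse stacks.
#
# A stack is an ordered set of single-channel frames with per-frame
# timestamps (seconds from experiment start), a pixel calibration in mm/px
# and a clock anchor so samples can be placed in the light schedule.
# Coordinates are row-major with origin top-left: x = column, y = row,
# 0-based; grey values are held as floating point on the scale they were
# read (no renormalisation, so relative intensities are preserved).

#' Build an acquisition timeline
#'
#' A timeline describes a nominally uniform acquisition cadence: frame `i`
#' is taken at `i * interval_s` seconds after the start, and clock times
#' wrap modulo 24 h. Leaf stacks are typically taken every 90 s and root
#' stacks every 30 s.
#'
#' @param start_clock_time Clock time of frame 0 in hours (0--24).
#' @param interval_s Nominal frame interval in seconds (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param timestamps Optional explicit per-frame timestamps in seconds,
#'   overriding the uniform cadence (must be strictly increasing, length
#'   `n_frames`, starting at 0).
#' @return An object of class `pf_timeline`.
#' @examples
#' tl <- build_timeline(8, 90, 3)
#' timeline_clock(tl)  # 8.000, 8.025, 8.050 hours
#' @export
build_timeline <- function(start_clock_time, interval_s, n_frames,
                           timestamps = NULL) {
  if (!is.numeric(interval_s) || length(interval_s) != 1 || interval_s <= 0)
    abort_pf("interval_s must be a single positive number",
             "phytoflow_validation_error")
  if (!is.numeric(n_frames) || n_frames < 2)
    abort_pf("n_frames must be >= 2", "phytoflow_validation_error")
  if (start_clock_time < 0 || start_clock_time >= 24)
    abort_pf("start_clock_time must lie in [0, 24)",
             "phytoflow_validation_error")
  n_frames <- as.integer(n_frames)
  if (!is.null(timestamps)) {
    if (length(timestamps) != n_frames || any(diff(timestamps) <= 0))
      abort_pf("explicit timestamps must be strictly increasing and match n_frames",
               "phytoflow_validation_error")
  }
  structure(list(start_clock_time = start_clock_time,
                 interval_s = interval_s,
                 n_frames = n_frames,
                 timestamps = timestamps),
            class = "pf_timeline")
}

#' Expand a timeline to per-frame timestamps (seconds)
#' @param timeline A [build_timeline()] object.
#' @return Numeric vector of seconds from experiment start.
#' @export
timeline_times <- function(timeline) {
  stopifnot(inherits(timeline, "pf_timeline"))
  timeline$timestamps %||%
    ((seq_len(timeline$n_frames) - 1) * timeline$interval_s)
}

#' Per-frame clock times in hours (wrapping at midnight)
#' @inheritParams timeline_times
#' @return Numeric vector of clock hours in [0, 24).
#' @export
timeline_clock <- function(timeline) {
  (timeline$start_clock_time + timeline_times(timeline) / 3600) %% 24
}

#' Construct an image stack from frames in memory
#'
#' @param frames List of numeric matrices (all the same size) or a 3-D array
#'   with frames along the third dimension.
#' @param timeline A [build_timeline()] object (its `n_frames` must match).
#' @param pixel_size Physical pixel pitch in mm/px (> 0).
#' @param role `"leaf"` or `"root"` (metadata only).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, timeline, pixel_size, role = c("leaf", "root")) {
  role <- match.arg(role)
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  stk <- structure(list(frames = frames,
                        timestamps = timeline_times(timeline),
                        clock_times = timeline_clock(timeline),
                        pixel_size = pixel_size,
                        interval_s = timeline$interval_s,
                        start_clock_time = timeline$start_clock_time,
                        role = role),
                   class = "image_stack")
  validate_stack(stk)
  stk
}

#' Validate stack invariants
#'
#' Checks that a stack has at least two frames of identical size, strictly
#' increasing timestamps, a positive pixel size and finite non-negative
#' grey values. Returns the stack invisibly; signals a validation error
#' naming the first offending frame otherwise.
#'
#' @param stack An `image_stack`.
#' @export
validate_stack <- function(stack) {
  if (!inherits(stack, "image_stack"))
    abort_pf("not an image_stack", "phytoflow_validation_error")
  n <- length(stack$frames)
  if (n < 2)
    abort_pf("a stack needs at least 2 frames", "phytoflow_validation_error")
  if (length(stack$timestamps) != n)
    abort_pf("timestamps do not match frame count", "phytoflow_validation_error")
  if (any(diff(stack$timestamps) <= 0))
    abort_pf("timestamps must be strictly increasing", "phytoflow_validation_error")
  if (!is.numeric(stack$pixel_size) || stack$pixel_size <= 0)
    abort_pf("pixel_size must be > 0", "phytoflow_validation_error")
  d1 <- dim(stack$frames[[1]])
  for (k in seq_len(n)) {
    fk <- stack$frames[[k]]
    if (!is.matrix(fk) || !identical(dim(fk), d1))
      abort_pf(sprintf("frame %d differs in size from frame 1", k),
               "phytoflow_validation_error")
    if (anyNA(fk) || any(!is.finite(fk)) || any(fk < 0))
      abort_pf(sprintf("frame %d contains non-finite or negative grey values", k),
               "phytoflow_validation_error")
  }
  invisible(stack)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %s, %d frames of %dx%d px, %.0f s cadence, %.4g mm/px\n",
              x$role, length(x$frames), d[1], d[2],
              x$interval_s, x$pixel_size))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An `image_stack`.
#' @export
n_frames <- function(stack) length(stack$frames)

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a stack as a multi-page TIFF with a metadata sidecar
#'
#' One TIFF page per frame, in frame order, quantised to the requested bit
#' depth; the timeline, pixel calibration and role go to a plain-text YAML
#' sidecar (`<path>.meta.yaml`) because TIFF tags for timelines are
#' non-standard.
#'
#' @param stack An `image_stack` with grey values in [0, 1].
#' @param path Output TIFF path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  validate_stack(stack)
  if (!bits %in% c(8L, 16L))
    abort_pf("bits must be 8 or 16", "phytoflow_validation_error")
  rng <- range(unlist(lapply(stack$frames, range)))
  if (rng[2] > 1)
    abort_pf("grey values must lie in [0, 1] for TIFF export",
             "phytoflow_validation_error")
  ok <- tryCatch({
    tiff::writeTIFF(stack$frames, path, bits.per.sample = bits)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    abort_pf(sprintf("cannot write TIFF at '%s'", path), "phytoflow_io_error")
  meta <- list(start_clock_time = stack$start_clock_time,
               interval_s = stack$interval_s,
               n_frames = length(stack$frames),
               pixel_size = stack$pixel_size,
               role = stack$role,
               bits = as.integer(bits),
               timestamps = as.numeric(stack$timestamps))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a multi-page grey-value TIFF as an image stack
#'
#' Grey values are kept on the floating scale the TIFF reader produces
#' (linear in the stored integers); relative intensities are never
#' rescaled. If a metadata sidecar written by [write_stack()] sits next to
#' the file, the timeline, pixel size and role default to its contents.
#'
#' @param path TIFF path (>= 2 pages, single channel).
#' @param pixel_size mm/px; defaults to the sidecar value.
#' @param timeline A [build_timeline()]; defaults to the sidecar timeline.
#' @param role `"leaf"` or `"root"`; defaults to the sidecar value.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, pixel_size = NULL, timeline = NULL, role = NULL) {
  if (!file.exists(path))
    abort_pf(sprintf("no such file: '%s'", path), "phytoflow_io_error")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      abort_pf(sprintf("cannot read TIFF '%s': %s",
                                       path, conditionMessage(e)),
                               "phytoflow_io_error"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    abort_pf("stack TIFF must have at least 2 pages", "phytoflow_validation_error")
  pages <- lapply(seq_along(pages), function(k) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1]
      else abort_pf(sprintf("page %d is not single-channel (colour TIFFs unsupported)", k),
                    "phytoflow_validation_error")
    }
    p
  })
  d1 <- dim(pages[[1]])
  for (k in seq_along(pages))
    if (!identical(dim(pages[[k]]), d1))
      abort_pf(sprintf("page %d has different dimensions than page 1", k),
               "phytoflow_validation_error")
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else NULL
  if (is.null(timeline)) {
    if (is.null(meta))
      abort_pf("no timeline given and no metadata sidecar found",
               "phytoflow_validation_error")
    timeline <- build_timeline(meta$start_clock_time, meta$interval_s,
                               meta$n_frames,
                               timestamps = as.numeric(meta$timestamps))
  }
  pixel_size <- pixel_size %||% meta$pixel_size
  role <- role %||% (meta$role %||% "leaf")
  if (timeline$n_frames != length(pages))
    abort_pf("timeline n_frames does not match TIFF page count",
             "phytoflow_validation_error")
  image_stack(pages, timeline, pixel_size, role)
}

#' Pixel calibration from a known physical length
#'
#' @param known_length_mm Physical length of a reference object in mm.
#' @param measured_px Its measured extent in pixels.
#' @return Calibration in mm/px.
#' @examples
#' calibrate_scale(10, 500)  # 0.02 mm/px
#' @export
calibrate_scale <- function(known_length_mm, measured_px) {
  if (!is.numeric(known_length_mm) || known_length_mm <= 0 ||
      !is.numeric(measured_px) || measured_px <= 0)
    abort_pf("both lengths must be positive", "phytoflow_validation_error")
  known_length_mm / measured_px
}
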