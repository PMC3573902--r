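# Leaf relative growth rate over a tracked area of interest (AOI).
#
# RGR is computed two ways and reported side by side: (i) the mean
# divergence of the estimated velocity field over the AOI interior and
# (ii) the log-area formula (ln A1 - ln A0) / t on the advected polygon.
# On clean expansions the two must agree; their disagreement is a direct
# quality indicator for the flow.

#' Construct an area of interest polygon
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates (0-based,
#'   x = column, y = row), at least 3 vertices, simple (non-self-
#'   intersecting) and of positive area.
#' @param frame_index Frame this AOI instance refers to (metadata).
#' @return An object of class `aoi`.
#' @export
aoi <- function(vertices, frame_index = 1L) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    abort_pf("an AOI needs an n x 2 matrix with n >= 3", "phytoflow_validation_error")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    abort_pf("AOI vertices must be finite", "phytoflow_validation_error")
  colnames(vertices) <- c("x", "y")
  if (abs(shoelace(vertices)) <= 0)
    abort_pf("AOI polygon has zero area", "phytoflow_validation_error")
  if (!polygon_is_simple(vertices))
    abort_pf("AOI polygon is self-intersecting", "phytoflow_validation_error")
  structure(list(vertices = vertices, frame_index = as.integer(frame_index)),
            class = "aoi")
}

# Signed shoelace area (px^2).
shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Simple-polygon test: no two non-adjacent edges properly intersect.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Polygon area of an AOI
#'
#' Shoelace area, orientation-independent.
#'
#' @param aoi An [aoi()] (or bare vertex matrix).
#' @param pixel_size mm/px; if given, the mm^2 area is returned alongside.
#' @return List with `px2` and (if `pixel_size` given) `mm2`.
#' @export
polygon_area <- function(aoi, pixel_size = NULL) {
  v <- if (inherits(aoi, "aoi")) aoi$vertices else as.matrix(aoi)
  a <- abs(shoelace(v))
  if (a <= 0)
    abort_pf("degenerate polygon (area <= 0)", "phytoflow_validation_error")
  out <- list(px2 = a)
  if (!is.null(pixel_size)) out$mm2 <- a * pixel_size^2
  out
}

#' Rasterise an AOI to a boolean mask
#'
#' Pixel centres strictly inside the polygon are TRUE.
#'
#' @param aoi An [aoi()].
#' @param dim Frame dimensions `c(rows, cols)`.
#' @return Logical matrix.
#' @export
aoi_mask <- function(aoi, dim) {
  v <- aoi$vertices
  px <- rep(seq_len(dim[2]) - 1, each = dim[1])
  py <- rep(seq_len(dim[1]) - 1, times = dim[2])
  inside <- mgcv::in.out(rbind(v, v[1, , drop = FALSE]), cbind(px, py))
  matrix(inside, dim[1], dim[2])
}

#' Advect an AOI by a displacement field
#'
#' Each vertex is moved by the bilinearly interpolated displacement;
#' displacements at invalid flow pixels are expected to have been filled
#' from nearest valid neighbours upstream (as [displacement_between()]
#' does). A polygon that comes back self-intersecting is repaired by
#' convex-hull simplification with a warning; a degenerate result is a
#' tracking-lost error.
#'
#' @param aoi An [aoi()].
#' @param dx,dy Displacement matrices in px.
#' @param frame_index Frame index of the advected AOI.
#' @return The advected [aoi()].
#' @export
advect_aoi <- function(aoi, dx, dy, frame_index = aoi$frame_index + 1L) {
  v <- aoi$vertices
  ddx <- cpp_bilinear(dx, v[, 1], v[, 2])
  ddy <- cpp_bilinear(dy, v[, 1], v[, 2])
  ddx[is.na(ddx)] <- 0; ddy[is.na(ddy)] <- 0
  nv <- cbind(x = v[, 1] + ddx, y = v[, 2] + ddy)
  if (abs(shoelace(nv)) <= 1e-9)
    abort_pf(sprintf("AOI degenerated while advecting to frame %d (tracking lost)",
                     frame_index), "phytoflow_tracking_error")
  if (!polygon_is_simple(nv)) {
    warning(sprintf("advected AOI self-intersects at frame %d; repaired by convex-hull simplification",
                    frame_index), call. = FALSE)
    nv <- nv[chull(nv), , drop = FALSE]
  }
  aoi(nv, frame_index)
}

#' Leaf RGR by the log-area formula
#'
#' RGR = (ln A1 - ln A0) / dt.
#'
#' @param A0,A1 AOI areas at the window start and end (any fixed unit).
#' @param dt_h Window duration in hours.
#' @return RGR in 1/h.
#' @export
rgr_area_method <- function(A0, A1, dt_h) {
  if (any(A0 <= 0) || any(A1 <= 0) || any(dt_h <= 0))
    abort_pf("areas and duration must be positive", "phytoflow_validation_error")
  (log(A1) - log(A0)) / dt_h
}

#' Leaf RGR as the mean divergence of the velocity field
#'
#' The velocity field is lightly smoothed inside the confidence-masked
#' AOI (mask-normalised Gaussian, so invalid pixels never bleed in),
#' the divergence du/dx + dv/dy is taken by central differences, and
#' pixels adjacent to invalid ones are excluded from the mean.
#'
#' @param field A `velocity_field` (px/frame).
#' @param aoi An [aoi()].
#' @param frame_interval_s Seconds per frame (defaults to the field's).
#' @param min_valid Minimum number of usable interior pixels.
#' @param smooth_sigma Gaussian scale of the pre-smoothing, px.
#' @return RGR in 1/h.
#' @export
rgr_divergence_method <- function(field, aoi, frame_interval_s = NULL,
                                  min_valid = 100L, smooth_sigma = 1.0) {
  stopifnot(inherits(field, "velocity_field"))
  frame_interval_s <- frame_interval_s %||% field$interval_s
  m <- aoi_mask(aoi, dim(field$u)) & field$valid
  # masked smoothing: sm(u * w) / sm(w)
  w <- matrix(as.numeric(m), nrow(m), ncol(m))
  k <- gauss_kernel(smooth_sigma, 0L)
  wsm <- cpp_sepconv2(w, k, k)
  u0 <- field$u; u0[!m] <- 0
  v0 <- field$v; v0[!m] <- 0
  us <- cpp_sepconv2(u0, k, k) / pmax(wsm, 1e-12)
  vs <- cpp_sepconv2(v0, k, k) / pmax(wsm, 1e-12)
  nr <- nrow(m); nc <- ncol(m)
  # restrict to pixels whose smoothing kernel has (near) full support in
  # the mask: mask-normalised smoothing is unbiased only there, and a
  # clipped kernel at the AOI rim would bias the divergence low
  ok <- m & (wsm > 0.99)
  ok[c(1, nr), ] <- FALSE; ok[, c(1, nc)] <- FALSE
  core <- ok
  core[2:(nr - 1), 2:(nc - 1)] <-
    ok[2:(nr - 1), 2:(nc - 1)] &
    ok[1:(nr - 2), 2:(nc - 1)] & ok[3:nr, 2:(nc - 1)] &
    ok[2:(nr - 1), 1:(nc - 2)] & ok[2:(nr - 1), 3:nc]
  n_ok <- sum(core)
  if (n_ok < min_valid)
    abort_pf(sprintf("only %d valid AOI-interior flow pixels (need >= %d)",
                     n_ok, min_valid), "phytoflow_quality_error")
  dudx <- matrix(0, nr, nc); dvdy <- matrix(0, nr, nc)
  dudx[, 2:(nc - 1)] <- (us[, 3:nc] - us[, 1:(nc - 2)]) / 2
  dvdy[2:(nr - 1), ] <- (vs[3:nr, ] - vs[1:(nr - 2), ]) / 2
  div_frame <- mean(dudx[core] + dvdy[core])   # 1/frame
  structure(div_frame * 3600 / frame_interval_s, n_valid = n_ok)
}

#' Windowed leaf RGR series by both methods
#'
#' The AOI is advected frame-to-frame through the stack along the
#' estimated flow; windows are tiled from the first frame (the study
#' default window is about 15 min). Per window, the area-method RGR comes
#' from the advected-AOI areas at the window boundaries and the
#' divergence-method RGR is the average of the per-frame divergences.
#'
#' @param stack An `image_stack`.
#' @param aoi0 The AOI on the first frame ([aoi()]).
#' @param params [flow_params()].
#' @param window_minutes Analysis window length (default 15).
#' @param min_valid Passed to [rgr_divergence_method()].
#' @return Data frame with one row per window: `window_start_s`,
#'   `window_end_s`, `centre_elapsed_h`, `centre_clock_h`, `A0_mm2`,
#'   `A1_mm2`, `rgr_area_h`, `rgr_div_h`, `n_valid_px`. If tracking is
#'   lost the series is truncated with a warning; the failing frame is in
#'   `attr(, "lost_frame")`.
#' @export
rgr_series <- function(stack, aoi0, params = flow_params(),
                       window_minutes = 15, min_valid = 100L) {
  validate_stack(stack)
  stopifnot(inherits(aoi0, "aoi"))
  n <- n_frames(stack)
  hw <- params$temporal_halfwidth
  w_frames <- max(2L, round(window_minutes * 60 / stack$interval_s))
  if (n < w_frames + 1)
    abort_pf("stack shorter than one analysis window", "phytoflow_validation_error")

  # flow field at every admissible centre, computed once
  fields <- vector("list", n)
  for (k in (hw + 1):(n - hw)) fields[[k]] <- estimate_flow_field(stack, k, params)

  # advect the AOI through all frames (clamped centres at the stack ends)
  aois <- vector("list", n)
  aois[[1]] <- aoi0
  lost_frame <- NA_integer_
  for (k in 1:(n - 1)) {
    fld <- fields[[clamp_centre(k, n, hw)]]
    nxt <- tryCatch(
      advect_aoi(aois[[k]], fld$u_fill, fld$v_fill, frame_index = k + 1L),
      phytoflow_tracking_error = function(e) e)
    if (inherits(nxt, "error")) {
      warning(sprintf("AOI tracking lost at frame %d; truncating series", k + 1),
              call. = FALSE)
      lost_frame <- k + 1L
      break
    }
    aois[[k + 1]] <- nxt
  }
  n_ok <- if (is.na(lost_frame)) n else lost_frame - 1L

  starts <- seq(1L, n_ok - w_frames, by = w_frames)
  rows <- lapply(starts, function(s0) {
    s1 <- s0 + w_frames
    A0 <- polygon_area(aois[[s0]], stack$pixel_size)
    A1 <- polygon_area(aois[[s1]], stack$pixel_size)
    dt_h <- (stack$timestamps[s1] - stack$timestamps[s0]) / 3600
    centres <- intersect(s0:s1, (hw + 1):(n - hw))
    divs <- nvals <- rep(NA_real_, length(centres))
    for (ci in seq_along(centres)) {
      k <- centres[ci]
      val <- tryCatch(
        rgr_divergence_method(fields[[k]], aois[[k]],
                              frame_interval_s = stack$interval_s,
                              min_valid = min_valid),
        phytoflow_quality_error = function(e) NA_real_)
      divs[ci] <- as.numeric(val)
      nvals[ci] <- attr(val, "n_valid") %||% NA_real_
    }
    tc <- (stack$timestamps[s0] + stack$timestamps[s1]) / 2
    data.frame(window_start_s = stack$timestamps[s0],
               window_end_s = stack$timestamps[s1],
               centre_elapsed_h = tc / 3600,
               centre_clock_h = (stack$start_clock_time + tc / 3600) %% 24,
               A0_mm2 = A0$mm2, A1_mm2 = A1$mm2,
               rgr_area_h = rgr_area_method(A0$mm2, A1$mm2, dt_h),
               rgr_div_h = mean(divs, na.rm = TRUE),
               n_valid_px = mean(nvals, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  attr(out, "lost_frame") <- lost_frame
  attr(out, "aois") <- aois[seq_len(n_ok)]
  out
}
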