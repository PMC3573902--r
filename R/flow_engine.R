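# Structure-tensor optical flow.
#
# Velocities are recovered from the brightness-constancy constraint
# g_x u + g_y v + g_t = 0 in the total-least-squares sense: the 3x3
# spatiotemporal structure tensor J (Gaussian-windowed outer product of the
# gradient) is diagonalised per pixel and the eigenvector of the smallest
# eigenvalue, which is parallel to (u, v, 1) where the constraint is
# solvable, yields the velocity in px/frame. Pixels where the two smallest
# eigenvalues are not separated carry only normal flow (aperture problem)
# and are flagged invalid instead of being assigned a biased estimate.

#' Parameters of the structure-tensor flow estimator
#'
#' @param grad_sigma Gaussian scale of the spatial derivative kernels (px).
#' @param grad_sigma_t Gaussian scale of the temporal kernels (frames).
#' @param window_sigma Gaussian scale of the spatial tensor-averaging
#'   window (px).
#' @param temporal_halfwidth Frames on each side of the centre frame used
#'   for the temporal kernels (>= 1).
#' @param confidence_threshold Minimum coherence in [0, 1] for a pixel to
#'   count as valid.
#' @param pyramid_levels Coarse-to-fine levels (>= 1); displacements well
#'   above ~1 px/frame need more than one level.
#' @param sep_rel_tol Aperture gate: a pixel is invalid when the two
#'   smallest tensor eigenvalues differ by less than `sep_rel_tol` times
#'   the largest one.
#' @param eps Regulariser used in all ratio denominators.
#' @return A list of class `flow_params`.
#' @export
flow_params <- function(grad_sigma = 1.0, grad_sigma_t = 1.0,
                        window_sigma = 4.0, temporal_halfwidth = 2L,
                        confidence_threshold = 0.3, pyramid_levels = 2L,
                        sep_rel_tol = 1e-3, eps = 1e-12) {
  stopifnot(grad_sigma > 0, grad_sigma_t > 0, window_sigma > 0,
            temporal_halfwidth >= 1, confidence_threshold >= 0,
            confidence_threshold <= 1, pyramid_levels >= 1)
  structure(list(grad_sigma = grad_sigma, grad_sigma_t = grad_sigma_t,
                 window_sigma = window_sigma,
                 temporal_halfwidth = as.integer(temporal_halfwidth),
                 confidence_threshold = confidence_threshold,
                 pyramid_levels = as.integer(pyramid_levels),
                 sep_rel_tol = sep_rel_tol, eps = eps),
            class = "flow_params")
}

check_centre_window <- function(n, centre, hw) {
  if (centre - hw < 1 || centre + hw > n)
    abort_pf(sprintf(
      "frame window [%d, %d] exceeds stack bounds [1, %d]; shrink temporal_halfwidth or skip this centre",
      centre - hw, centre + hw, n), "phytoflow_window_error")
}

#' Spatiotemporal Gaussian-derivative gradients
#'
#' Estimates the partial derivatives of the grey-value volume with respect
#' to x, y (px) and t (frames) at the centre frame, using separable
#' Gaussian derivative kernels at scale `grad_sigma` / `grad_sigma_t`.
#' Border pixels inside the kernel radius are reported in `margin` and
#' should be treated as invalid rather than extrapolated.
#'
#' @param stack An `image_stack` (or plain list of frames).
#' @param centre 1-based centre frame index.
#' @param params [flow_params()].
#' @return List with matrices `gx`, `gy`, `gt` and the invalid border
#'   width `margin` (px).
#' @export
spatiotemporal_gradients <- function(stack, centre, params = flow_params()) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  hw <- params$temporal_halfwidth
  check_centre_window(length(frames), centre, hw)
  k0t <- gauss_kernel(params$grad_sigma_t, 0L, radius = hw)
  k1t <- gauss_kernel(params$grad_sigma_t, 1L, radius = hw)
  d <- dim(frames[[centre]])
  sm0 <- matrix(0, d[1], d[2])  # temporally smoothed volume
  sm1 <- matrix(0, d[1], d[2])  # temporal derivative
  for (j in -hw:hw) {
    f <- frames[[centre + j]]
    sm0 <- sm0 + k0t[j + hw + 1] * f
    sm1 <- sm1 + k1t[j + hw + 1] * f
  }
  k0 <- gauss_kernel(params$grad_sigma, 0L)
  k1 <- gauss_kernel(params$grad_sigma, 1L)
  list(gx = cpp_sepconv2(sm0, k1, k0),
       gy = cpp_sepconv2(sm0, k0, k1),
       gt = cpp_sepconv2(sm1, k0, k0),
       margin = max(1L, ceiling(3 * params$grad_sigma)))
}

#' Build the per-pixel spatiotemporal structure tensor
#'
#' Gaussian-averages (scale `window_sigma`) the outer products of the
#' gradient vector, giving the six distinct components of the symmetric
#' positive semi-definite 3x3 tensor at every pixel. Temporal integration
#' is carried by the temporally smoothed gradients themselves.
#'
#' @param gx,gy,gt Gradient matrices from [spatiotemporal_gradients()].
#' @param params [flow_params()].
#' @return List of matrices `Jxx`, `Jxy`, `Jxt`, `Jyy`, `Jyt`, `Jtt`.
#' @export
build_structure_tensor <- function(gx, gy, gt, params = flow_params()) {
  if (!identical(dim(gx), dim(gy)) || !identical(dim(gx), dim(gt)))
    abort_pf("gradient grids must share dimensions", "phytoflow_validation_error")
  k <- gauss_kernel(params$window_sigma, 0L)
  sm <- function(m) cpp_sepconv2(m, k, k)
  list(Jxx = sm(gx * gx), Jxy = sm(gx * gy), Jxt = sm(gx * gt),
       Jyy = sm(gy * gy), Jyt = sm(gy * gt), Jtt = sm(gt * gt))
}

#' Per-pixel flow confidence (coherence)
#'
#' With tensor eigenvalues l1 >= l2 >= l3 >= 0, confidence is
#' (l2 - l3) / (l2 + l3 + eps): 0 for isotropic or degenerate tensors,
#' approaching 1 for well-conditioned motion.
#'
#' @param tensor Output of [build_structure_tensor()].
#' @param params [flow_params()].
#' @return Matrix of confidences in [0, 1].
#' @export
flow_confidence <- function(tensor, params = flow_params()) {
  sol <- cpp_flow_solve(tensor$Jxx, tensor$Jxy, tensor$Jxt,
                        tensor$Jyy, tensor$Jyt, tensor$Jtt,
                        params$eps, params$sep_rel_tol)
  sol$confidence
}

# Single-level tensor flow on a list of frames.
flow_single_level <- function(frames, centre, params) {
  g <- spatiotemporal_gradients(frames, centre, params)
  tens <- build_structure_tensor(g$gx, g$gy, g$gt, params)
  sol <- cpp_flow_solve(tens$Jxx, tens$Jxy, tens$Jxt,
                        tens$Jyy, tens$Jyt, tens$Jtt,
                        params$eps, params$sep_rel_tol)
  sol$margin <- g$margin + ceiling(3 * params$window_sigma)
  sol
}

apply_margin <- function(valid, margin) {
  nr <- nrow(valid); nc <- ncol(valid)
  m <- min(margin, floor((min(nr, nc) - 1) / 2))
  if (m >= 1) {
    valid[c(seq_len(m), nr - seq_len(m) + 1), ] <- FALSE
    valid[, c(seq_len(m), nc - seq_len(m) + 1)] <- FALSE
  }
  valid
}

#' Estimate a dense velocity field at one time point
#'
#' Runs the structure-tensor total-least-squares flow, optionally
#' coarse-to-fine: the flow found on a downsampled copy pre-warps the
#' frames so that only the sub-pixel residual must be recovered at full
#' resolution. Velocities are in px/frame at full resolution.
#'
#' @param stack An `image_stack`.
#' @param centre 1-based centre frame index; the temporal window
#'   `centre +/- temporal_halfwidth` must lie inside the stack.
#' @param params [flow_params()].
#' @return An object of class `velocity_field`: matrices `u`, `v`
#'   (px/frame), `confidence`, logical `valid`, plus `centre_time` (s) and
#'   `interval_s`.
#' @export
estimate_flow_field <- function(stack, centre, params = flow_params()) {
  validate_stack(stack)
  hw <- params$temporal_halfwidth
  check_centre_window(n_frames(stack), centre, hw)
  block <- stack$frames[centre + (-hw:hw)]
  d <- dim(block[[1]])

  # pyramid of frame blocks (level 1 = full resolution)
  levels <- params$pyramid_levels
  while (levels > 1 && min(d) / 2^(levels - 1) < 24) levels <- levels - 1
  pyr <- vector("list", levels)
  pyr[[1]] <- block
  if (levels > 1)
    for (l in 2:levels) pyr[[l]] <- lapply(pyr[[l - 1]], pyr_down)

  u0 <- v0 <- NULL
  for (l in levels:1) {
    fr <- pyr[[l]]
    dl <- dim(fr[[1]])
    if (!is.null(u0)) {
      u0 <- resize_bilinear(u0, dl[1], dl[2]) * 2
      v0 <- resize_bilinear(v0, dl[1], dl[2]) * 2
      warped <- fr
      for (j in seq_along(fr)) {
        off <- j - hw - 1  # frame offset relative to centre
        if (off == 0) next
        w <- cpp_warp(fr[[j]], off * u0, off * v0)
        nas <- is.na(w)
        if (any(nas)) w[nas] <- fr[[j]][nas]
        warped[[j]] <- w
      }
      fr <- warped
    }
    sol <- flow_single_level(fr, hw + 1, params)
    if (is.null(u0)) {
      u0 <- cpp_fill_nearest(sol$u, sol$valid)
      v0 <- cpp_fill_nearest(sol$v, sol$valid)
      u0[is.na(u0)] <- 0; v0[is.na(v0)] <- 0
    } else {
      u0 <- u0 + cpp_fill_nearest(sol$u, sol$valid)
      v0 <- v0 + cpp_fill_nearest(sol$v, sol$valid)
      u0[is.na(u0)] <- 0; v0[is.na(v0)] <- 0
    }
  }
  valid <- sol$valid & (sol$confidence >= params$confidence_threshold)
  valid <- apply_margin(valid, sol$margin)
  if (!any(valid))
    warning("no valid flow pixels (textureless or globally constant scene)",
            call. = FALSE)
  u <- u0; v <- v0
  u[!valid] <- NA_real_; v[!valid] <- NA_real_
  structure(list(u = u, v = v, confidence = sol$confidence, valid = valid,
                 u_fill = u0, v_fill = v0,
                 centre_index = centre,
                 centre_time = stack$timestamps[centre],
                 interval_s = stack$interval_s,
                 pixel_size = stack$pixel_size),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %dx%d px at t = %.0f s, %.1f%% valid\n",
              nrow(x$u), ncol(x$u), x$centre_time, 100 * mean(x$valid)))
  invisible(x)
}

# Centre index usable for a step starting at frame k (clamped to bounds).
clamp_centre <- function(k, n, hw) min(max(k, hw + 1), n - hw)

#' Integrated displacement between two frames
#'
#' Sums per-step flow fields along advected positions (forward Euler along
#' the flow), so material structures can be followed across multi-frame
#' analysis windows. Invalid pixels are filled from their nearest valid
#' neighbours before interpolation; a warning is emitted for steps with
#' less than 50% valid flow.
#'
#' @param stack An `image_stack`.
#' @param frame_a,frame_b 1-based frame indices, `frame_a < frame_b`.
#' @param params [flow_params()].
#' @param points Optional n x 2 matrix of (x, y) positions (0-based px) to
#'   track instead of the full pixel grid.
#' @param fields Optional pre-computed list of `velocity_field` objects
#'   indexed by centre frame, to avoid recomputation.
#' @return If `points` is NULL, list of matrices `dx`, `dy` (px) giving
#'   the displacement of the material point starting at each pixel;
#'   otherwise the displaced n x 2 point matrix.
#' @export
displacement_between <- function(stack, frame_a, frame_b,
                                 params = flow_params(), points = NULL,
                                 fields = NULL) {
  validate_stack(stack)
  if (!(frame_a < frame_b))
    abort_pf("frame_a must be < frame_b", "phytoflow_validation_error")
  n <- n_frames(stack)
  hw <- params$temporal_halfwidth
  d <- dim(stack$frames[[1]])
  if (is.null(points)) {
    px <- rep(seq_len(d[2]) - 1, each = d[1])
    py <- rep(seq_len(d[1]) - 1, times = d[2])
  } else {
    px <- points[, 1]; py <- points[, 2]
  }
  x <- px; y <- py
  cache <- list()
  for (k in frame_a:(frame_b - 1)) {
    cc <- clamp_centre(k, n, hw)
    key <- as.character(cc)
    fld <- fields[[key]] %||% cache[[key]]
    if (is.null(fld)) {
      fld <- estimate_flow_field(stack, cc, params)
      cache[[key]] <- fld
    }
    if (mean(fld$valid) < 0.5)
      warning(sprintf("step %d: only %.0f%% of flow pixels valid; filling from nearest valid neighbours",
                      k, 100 * mean(fld$valid)), call. = FALSE)
    du <- cpp_bilinear(fld$u_fill, x, y)
    dv <- cpp_bilinear(fld$v_fill, x, y)
    du[is.na(du)] <- 0; dv[is.na(dv)] <- 0
    x <- x + du; y <- y + dv
  }
  if (is.null(points)) {
    list(dx = matrix(x - px, d[1], d[2]), dy = matrix(y - py, d[1], d[2]))
  } else {
    cbind(x = x, y = y)
  }
}
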