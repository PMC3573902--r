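# Root-tip velocity from segmentation and skeleton tracking.
#
# Root velocity is the speed at which the tip is dislocated from the
# fully mature, spatially fixed part of the root. The tip is located
# geometrically (skeleton endpoint farthest from the anchor along the
# root) rather than from the flow field, because flow at the advancing
# tip edge is unreliable; frame-to-frame tip steps are projected on the
# local growth direction, so curved growth is not under-reported.

otsu_threshold <- function(x) {
  EBImage::otsu(EBImage::Image(x), range = range(0, 1, x))
}

moment_elongation <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(0)
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Segment the root from a single frame
#'
#' Automatic (Otsu) thresholding followed by small-object removal and
#' selection of the largest connected component; whether the root is
#' darker or brighter than the background is auto-detected from which
#' side of the threshold forms an elongated component.
#'
#' @param frame Numeric matrix with grey values in [0, 1].
#' @param min_size Minimum component size in px.
#' @param min_elongation Minimum major/minor axis ratio for a component
#'   to qualify as a root.
#' @return Logical root mask with attributes `polarity` (`"dark"` /
#'   `"bright"`) and `threshold`.
#' @export
segment_root <- function(frame, min_size = 100L, min_elongation = 3) {
  if (diff(range(frame)) < 1e-4)
    abort_pf("frame has no contrast; cannot segment root",
             "phytoflow_segmentation_error")
  thr <- otsu_threshold(frame)
  best <- NULL
  for (pol in c("dark", "bright")) {
    cand <- if (pol == "dark") frame < thr else frame > thr
    if (!any(cand)) next
    lab <- EBImage::bwlabel(cand)
    sizes <- tabulate(lab[lab > 0])
    if (!length(sizes) || max(sizes) < min_size) next
    comp <- lab == which.max(sizes)
    el <- moment_elongation(comp)
    if (el >= min_elongation && (is.null(best) || el > best$el))
      best <- list(mask = comp, el = el, pol = pol)
  }
  if (is.null(best))
    abort_pf(sprintf("no connected component with elongation >= %g found on either side of the threshold (%.3f)",
                     min_elongation, thr), "phytoflow_segmentation_error")
  structure(best$mask, polarity = best$pol, threshold = thr)
}

neighbour_count <- function(skel) {
  m <- matrix(as.numeric(skel), nrow(skel), ncol(skel))
  k <- c(1, 1, 1)
  s <- cpp_sepconv2(m, k, k) - m
  s[!skel] <- 0
  round(s)
}

# Moving-average smoothing of a path's coordinates; end points kept.
smooth_path <- function(path, half = 2L) {
  n <- nrow(path)
  if (n <= 2 * half + 1) return(path)
  out <- path
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(path[lo:hi, , drop = FALSE])
  }
  out
}

#' Locate the root tip on a segmented mask
#'
#' The mask is thinned to a one-pixel skeleton; the tip is the skeleton
#' endpoint with the largest geodesic (along-skeleton) distance from the
#' anchor, so strongly curved roots resolve to the correct end rather
#' than the Euclidean-farthest one. Several endpoints at essentially the
#' same maximal distance (e.g. equal lateral branches) raise an ambiguity
#' error listing the candidates.
#'
#' @param mask Logical root mask (from [segment_root()]).
#' @param anchor `c(x, y)` anchor point in 0-based px, inside or adjacent
#'   to the mature end of the root.
#' @param ambiguity_tol Distance band (px) within which two endpoints
#'   count as tied.
#' @return List: `tip` (x, y), `arc_px` (smoothed along-path length from
#'   anchor to tip), `tangent` (unit growth direction at the tip),
#'   `path` (n x 2 anchor-to-tip coordinates), `skeleton`.
#' @export
locate_tip <- function(mask, anchor, ambiguity_tol = 1.0) {
  skel <- cpp_thin(mask)
  sk_pts <- which(skel, arr.ind = TRUE)
  if (nrow(sk_pts) < 3)
    abort_pf("skeleton too small to locate a tip", "phytoflow_segmentation_error")
  d2 <- (sk_pts[, 2] - 1 - anchor[1])^2 + (sk_pts[, 1] - 1 - anchor[2])^2
  src <- sk_pts[which.min(d2), ]
  geo <- cpp_geodesic(skel, src[1] - 1L, src[2] - 1L)
  nbc <- neighbour_count(skel)
  ep <- which(skel & nbc == 1, arr.ind = TRUE)
  if (nrow(ep) == 0) ep <- sk_pts  # closed loop fallback
  epd <- geo$dist[cbind(ep[, 1], ep[, 2])]
  ep <- ep[is.finite(epd), , drop = FALSE]
  epd <- epd[is.finite(epd)]
  if (!length(epd))
    abort_pf("no skeleton endpoint reachable from the anchor",
             "phytoflow_segmentation_error")
  o <- order(epd, decreasing = TRUE)
  ep <- ep[o, , drop = FALSE]; epd <- epd[o]
  if (length(epd) >= 2 && (epd[1] - epd[2]) < ambiguity_tol &&
      sqrt(sum((ep[1, ] - ep[2, ])^2)) > 5)
    abort_pf(sprintf(
      "ambiguous tip: endpoints at (%d,%d) and (%d,%d) have equal geodesic distance (%.1f vs %.1f px); lateral root?",
      ep[1, 2] - 1, ep[1, 1] - 1, ep[2, 2] - 1, ep[2, 1] - 1, epd[1], epd[2]),
      "phytoflow_ambiguity_error")
  ti <- ep[1, 1]; tj <- ep[1, 2]
  # walk predecessors tip -> anchor, then reverse
  path <- matrix(NA_real_, 0, 2)
  ci <- ti; cj <- tj
  repeat {
    path <- rbind(path, c(cj - 1, ci - 1))  # (x, y)
    pi <- geo$pred_i[ci, cj]; pj <- geo$pred_j[ci, cj]
    if (pi < 0) break
    ci <- pi + 1L; cj <- pj + 1L
  }
  path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  sp <- smooth_path(path)
  arc <- sum(sqrt(rowSums(diff(sp)^2)))
  # growth direction at the tip: principal axis of the last stretch of the
  # skeleton (robust to single-pixel wiggle), oriented outward
  nlast <- min(15L, nrow(sp))
  seg <- sp[(nrow(sp) - nlast + 1):nrow(sp), , drop = FALSE]
  pc <- eigen(stats::cov(seg), symmetric = TRUE)$vectors[, 1]
  chord <- sp[nrow(sp), ] - seg[1, ]
  if (sum(pc * chord) < 0) pc <- -pc
  tang <- pc / max(sqrt(sum(pc^2)), 1e-12)
  list(tip = c(tj - 1, ti - 1), arc_px = arc, tangent = tang,
       path = sp, skeleton = skel)
}

# Sub-pixel refinement of the tip along the growth direction: the
# skeleton endpoint of a rounded cap sits about half a root-width behind
# the physical tip and jumps in whole pixels, so the soft root edge is
# sampled along the tangent ray well past the cap and the threshold
# crossing is interpolated linearly. Returns the signed offset (px) to
# add to the integer tip along the tangent; NA when no edge crossing is
# found in range.
refine_tip <- function(frame, tip, tangent, threshold, polarity = "dark",
                       max_reach = 15) {
  s <- seq(-3, max_reach, by = 0.1)
  xs <- tip[1] + s * tangent[1]
  ys <- tip[2] + s * tangent[2]
  inten <- cpp_bilinear(frame, xs, ys)
  ok <- !is.na(inten)
  if (sum(ok) < 5) return(0)
  s <- s[ok]; inten <- inten[ok]
  if (length(inten) >= 3)  # light denoising
    inten <- stats::filter(inten, rep(1 / 3, 3), sides = 2) |>
      (\(z) { z[is.na(z)] <- inten[is.na(z)]; as.numeric(z) })()
  covered <- if (polarity == "dark") inten < threshold else inten > threshold
  if (!covered[1]) return(0)        # ray starts off the root; no refinement
  idx <- which(!covered)[1]
  if (is.na(idx)) return(NA_real_)  # no edge crossing in reach
  i0 <- idx - 1L
  denom <- inten[idx] - inten[i0]
  frac <- if (abs(denom) < 1e-12) 0.5 else (threshold - inten[i0]) / denom
  s[i0] + frac * (s[idx] - s[i0])
}

#' Track a fixed anchor patch across the stack
#'
#' Verifies the fixed-frame assumption for the mature root region: a
#' small patch around the anchor is followed by normalised
#' cross-correlation with quadratic sub-pixel refinement. If the maximum
#' drift stays below 2 px the anchor is treated as fixed (mean position);
#' larger drift raises a registration warning and downstream velocities
#' are corrected by subtracting the anchor motion.
#'
#' @param stack An `image_stack`.
#' @param anchor0 `c(x, y)` anchor on frame 1 (0-based px), inside a
#'   textured region.
#' @param patch_radius Patch half-size in px.
#' @param search_radius Maximum shift searched per frame, px.
#' @return n x 2 matrix of per-frame anchor positions with attributes
#'   `max_drift` and `fixed`.
#' @export
register_anchor <- function(stack, anchor0, patch_radius = 10L,
                            search_radius = 3L) {
  validate_stack(stack)
  f1 <- stack$frames[[1]]
  i0 <- round(anchor0[2]) + 1L; j0 <- round(anchor0[1]) + 1L
  pr <- patch_radius; sr <- search_radius
  if (i0 - pr - sr < 1 || j0 - pr - sr < 1 ||
      i0 + pr + sr > nrow(f1) || j0 + pr + sr > ncol(f1))
    abort_pf("anchor patch (plus search range) exceeds the frame",
             "phytoflow_validation_error")
  patch <- f1[(i0 - pr):(i0 + pr), (j0 - pr):(j0 + pr)]
  if (sd(patch) < 1e-4)
    abort_pf("anchor patch is textureless; cross-correlation undefined",
             "phytoflow_degenerate_error")
  pv <- as.vector(patch - mean(patch))
  pn <- sqrt(sum(pv^2))
  n <- n_frames(stack)
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- anchor0
  best_cc <- rep(NA_real_, n)
  for (k in 2:n) {
    fk <- stack$frames[[k]]
    cc <- matrix(-Inf, 2 * sr + 1, 2 * sr + 1)
    for (dy in -sr:sr) for (dx in -sr:sr) {
      q <- fk[(i0 + dy - pr):(i0 + dy + pr), (j0 + dx - pr):(j0 + dx + pr)]
      qv <- as.vector(q - mean(q))
      qn <- sqrt(sum(qv^2))
      cc[dy + sr + 1, dx + sr + 1] <-
        if (qn < 1e-12) -Inf else sum(pv * qv) / (pn * qn)
    }
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    best_cc[k] <- max(cc)
    dy <- best[1] - sr - 1L; dx <- best[2] - sr - 1L
    sub <- c(0, 0)  # quadratic peak interpolation where the peak is interior
    if (best[1] > 1 && best[1] < nrow(cc)) {
      a <- cc[best[1] - 1, best[2]]; b <- cc[best[1], best[2]]
      cch <- cc[best[1] + 1, best[2]]
      den <- a - 2 * b + cch
      if (is.finite(den) && abs(den) > 1e-12) sub[2] <- 0.5 * (a - cch) / den
    }
    if (best[2] > 1 && best[2] < ncol(cc)) {
      a <- cc[best[1], best[2] - 1]; b <- cc[best[1], best[2]]
      cch <- cc[best[1], best[2] + 1]
      den <- a - 2 * b + cch
      if (is.finite(den) && abs(den) > 1e-12) sub[1] <- 0.5 * (a - cch) / den
    }
    pos[k, ] <- anchor0 + c(dx + sub[1], dy + sub[2])
  }
  # a patch without repeatable structure (e.g. uniform background plus
  # sensor noise) matches at chance level; refuse rather than report drift
  if (median(best_cc, na.rm = TRUE) < 0.4)
    abort_pf("anchor patch matches at chance level (textureless background?)",
             "phytoflow_degenerate_error")
  drift <- sqrt(rowSums((pos - matrix(anchor0, n, 2, byrow = TRUE))^2))
  fixed <- max(drift) < 2
  if (!fixed)
    warning(sprintf("anchor drift up to %.2f px exceeds 2 px; velocities will be anchor-corrected",
                    max(drift)), call. = FALSE)
  structure(pos, max_drift = max(drift), fixed = fixed)
}

#' Windowed root-tip velocity series
#'
#' Per analysis window (default 5 min, i.e. 10 frames at 30 s cadence),
#' velocity is the along-path displacement of the tip - the sum of
#' frame-to-frame tip steps projected on the local growth direction, with
#' outlier steps beyond `outlier_factor` times the window median replaced
#' by interpolation - divided by the window duration and converted to
#' mm/h. The straight-line (chord) velocity is reported alongside.
#'
#' @param stack An `image_stack` (role "root").
#' @param anchor0 `c(x, y)` anchor in the mature region on frame 1;
#'   default: the skeleton endpoint closest to the root base (top of the
#'   frame) on frame 1.
#' @param window_minutes Window length (default 5).
#' @param outlier_factor Steps larger than this multiple of the window
#'   median step are replaced by interpolation.
#' @param min_seg_frac Minimum fraction of segmentable frames before a
#'   quality warning is raised.
#' @param register Track the anchor patch and correct for its motion;
#'   silently skipped when the anchor patch is textureless or too close
#'   to the frame border for correlation.
#' @return Data frame with one row per window: `window_start_s`,
#'   `window_end_s`, `centre_elapsed_h`, `centre_clock_h`,
#'   `velocity_mm_h`, `straight_mm_h`, `path_mm`, `n_valid_frames`.
#'   The per-frame tip track is in `attr(, "tips")`.
#' @export
tip_velocity_series <- function(stack, anchor0 = NULL, window_minutes = 5,
                                outlier_factor = 5, min_seg_frac = 0.9,
                                register = TRUE) {
  validate_stack(stack)
  n <- n_frames(stack)
  w <- max(2L, round(window_minutes * 60 / stack$interval_s))
  if (n < w + 1)
    abort_pf("stack shorter than one analysis window", "phytoflow_validation_error")

  seg1 <- segment_root(stack$frames[[1]])
  if (is.null(anchor0)) {
    skel1 <- cpp_thin(seg1)
    nb1 <- neighbour_count(skel1)
    ep <- which(skel1 & nb1 == 1, arr.ind = TRUE)
    if (nrow(ep) == 0) ep <- which(skel1, arr.ind = TRUE)
    b <- ep[which.min(ep[, 1]), ]           # closest to the top = base
    anchor0 <- c(b[2] - 1, b[1] - 1)
  }
  anchors <- if (register) {
    tryCatch(register_anchor(stack, anchor0),
             phytoflow_degenerate_error = function(e) NULL,
             phytoflow_validation_error = function(e) NULL)
  } else NULL
  anchor_at <- function(k) if (is.null(anchors)) anchor0 else anchors[k, ]
  anchor_corr <- function(k) {
    if (is.null(anchors) || attr(anchors, "fixed")) c(0, 0)
    else anchors[k, ] - anchor0
  }

  tips <- matrix(NA_real_, n, 2)
  tangents <- matrix(NA_real_, n, 2)
  valid <- logical(n)
  ksm <- gauss_kernel(0.75, 0L)  # denoise the edge profile for sub-pixel work
  for (k in seq_len(n)) {
    res <- tryCatch({
      m <- segment_root(stack$frames[[k]])
      lt <- locate_tip(m, anchor_at(k))
      delta <- refine_tip(cpp_sepconv2(stack$frames[[k]], ksm, ksm),
                          lt$tip, lt$tangent,
                          attr(m, "threshold"), attr(m, "polarity"))
      if (is.na(delta)) NULL
      else list(tip = lt$tip + delta * lt$tangent - anchor_corr(k),
                tangent = lt$tangent)
    }, phytoflow_segmentation_error = function(e) NULL,
       phytoflow_ambiguity_error = function(e) NULL)
    if (!is.null(res)) {
      tips[k, ] <- res$tip
      tangents[k, ] <- res$tangent
      valid[k] <- TRUE
    }
  }
  if (mean(valid) < min_seg_frac)
    warning(sprintf("only %.0f%% of frames segmentable; series will have gaps",
                    100 * mean(valid)), call. = FALSE)
  if (mean(valid) < 0.5)
    abort_pf("root unsegmentable in most frames", "phytoflow_segmentation_error")

  starts <- seq(1L, n - w, by = w)
  rows <- lapply(starts, function(s0) {
    s1 <- s0 + w
    nv <- sum(valid[s0:s1])
    # stable growth direction for this window: skeleton tangents jitter
    # frame to frame, but the true direction changes negligibly within a
    # 5-min window, so projecting on the window-mean tangent cancels
    # lateral tip-localisation noise to first order
    tw <- colMeans(tangents[s0:s1, , drop = FALSE][valid[s0:s1], , drop = FALSE])
    tw <- tw / max(sqrt(sum(tw^2)), 1e-12)
    proj <- as.numeric(tips[s0:s1, , drop = FALSE] %*% tw)
    st <- diff(proj)
    med <- median(abs(st), na.rm = TRUE)
    if (is.finite(med) && med > 0) {
      bad <- !is.na(st) & abs(st) > outlier_factor * med
      st[bad] <- NA
    }
    if (anyNA(st) && sum(!is.na(st)) >= 2)
      st <- approx(seq_along(st)[!is.na(st)], st[!is.na(st)],
                   xout = seq_along(st), rule = 2)$y
    dur_h <- (stack$timestamps[s1] - stack$timestamps[s0]) / 3600
    path_px <- sum(st)
    chord <- if (valid[s0] && valid[s1])
      sqrt(sum((tips[s1, ] - tips[s0, ])^2)) else NA_real_
    tc <- (stack$timestamps[s0] + stack$timestamps[s1]) / 2
    data.frame(window_start_s = stack$timestamps[s0],
               window_end_s = stack$timestamps[s1],
               centre_elapsed_h = tc / 3600,
               centre_clock_h = (stack$start_clock_time + tc / 3600) %% 24,
               velocity_mm_h = path_px * stack$pixel_size / dur_h,
               straight_mm_h = chord * stack$pixel_size / dur_h,
               path_mm = path_px * stack$pixel_size,
               n_valid_frames = nv)
  })
  out <- do.call(rbind, rows)
  attr(out, "tips") <- data.frame(frame = seq_len(n), t_s = stack$timestamps,
                                  x_px = tips[, 1], y_px = tips[, 2],
                                  valid = valid)
  out
}
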