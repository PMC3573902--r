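# Synthetic leaf and root time-lapse scenes with exact ground truth.
#
# Frames are always derived from a continuous scene model (a fixed master
# texture warped by the analytic material map, or an arc-length
# parametrised root curve), never by iterated resampling, so the exported
# truth is exact by construction and parameter-recovery tests stay honest.

# ---- master texture ------------------------------------------------------

# Band-limited speckle texture: white noise smoothed at `scale` px and
# standardised to mean 0.5 / sd `contrast`. Sampled bilinearly at
# `oversample`-fold resolution over [x0, x0+width] x [y0, y0+height].
make_master_texture <- function(width, height, x0, y0, scale = 1.5,
                                contrast = 0.15, oversample = 2L) {
  nr <- ceiling(height * oversample) + 1L
  nc <- ceiling(width * oversample) + 1L
  noise <- matrix(rnorm(nr * nc), nr, nc)
  sm <- gauss_smooth2(noise, scale * oversample)
  sm <- (sm - mean(sm)) / sd(sm) * contrast + 0.5
  structure(list(grid = clamp(sm, 0.02, 0.98),
                 x0 = x0, y0 = y0, oversample = oversample),
            class = "pf_texture")
}

# Evaluate the texture at continuous scene coordinates (x, y), in px.
sample_texture <- function(tex, x, y) {
  out <- cpp_bilinear(tex$grid,
                      (x - tex$x0) * tex$oversample,
                      (y - tex$y0) * tex$oversample)
  out[is.na(out)] <- 0.5
  out
}

# ---- growth / velocity profiles ------------------------------------------

#' Piecewise diel leaf RGR profile
#'
#' High nocturnal and lower diurnal relative growth rate with an optional
#' transient dip at light-on (growth briefly interrupted when illumination
#' switches on) and an optional day-by-day decline applied as a per-day
#' scale factor.
#'
#' @param night,day RGR plateaus in 1/h for the nocturnal and diurnal
#'   period.
#' @param schedule [light_schedule()].
#' @param dip_depth Fraction of the diurnal plateau removed during the
#'   light-on transient (1 = full stop).
#' @param dip_minutes Duration of the transient in minutes.
#' @param day_decline Multiplicative factor applied per completed
#'   experimental day (1 = none).
#' @return Function of (clock hours, elapsed hours) returning RGR in 1/h.
#' @export
leaf_rgr_profile <- function(night = 0.040, day = 0.016,
                             schedule = light_schedule(),
                             dip_depth = 1.0, dip_minutes = 20,
                             day_decline = 1.0) {
  force(night); force(day); force(schedule)
  function(clock_h, elapsed_h = 0) {
    phase <- (clock_h - schedule$light_on) %% 24
    r <- ifelse(phase < schedule$photoperiod, day, night)
    in_dip <- phase < dip_minutes / 60
    r[in_dip] <- day * (1 - dip_depth)
    r * day_decline^(floor(elapsed_h / 24))
  }
}

#' Diel root-tip velocity profile
#'
#' Baseline elongation velocity with optional transients tied to the light
#' schedule: an exponentially recovering trough after light-on and a
#' shorter dip after light-off.
#'
#' @param baseline Velocity plateau in mm/h.
#' @param schedule [light_schedule()].
#' @param on_dip_depth,on_dip_tau_h Depth (mm/h) and recovery time
#'   constant (h) of the post-light-on trough.
#' @param off_dip_depth,off_dip_tau_h Same for the post-light-off dip.
#' @param on_dip_minutes If `on_dip_tau_h` is `NULL`, use a rectangular
#'   dip of this duration instead of an exponential one.
#' @return Function of (clock hours, elapsed hours) returning mm/h.
#' @export
root_velocity_profile <- function(baseline, schedule = light_schedule(),
                                  on_dip_depth = 0, on_dip_tau_h = NULL,
                                  on_dip_minutes = 30,
                                  off_dip_depth = 0, off_dip_tau_h = 1) {
  force(baseline); force(schedule)
  function(clock_h, elapsed_h = 0) {
    phase_on <- (clock_h - schedule$light_on) %% 24
    phase_off <- (clock_h - schedule$light_off) %% 24
    v <- rep(baseline, length(clock_h))
    if (on_dip_depth > 0) {
      if (is.null(on_dip_tau_h)) {
        v <- v - on_dip_depth * (phase_on < on_dip_minutes / 60)
      } else {
        day <- phase_on < schedule$photoperiod
        v <- v - ifelse(day, on_dip_depth * exp(-phase_on / on_dip_tau_h), 0)
      }
    }
    if (off_dip_depth > 0) {
      night <- phase_off < (24 - schedule$photoperiod)
      v <- v - ifelse(night, off_dip_depth * exp(-phase_off / off_dip_tau_h), 0)
    }
    pmax(v, 0)
  }
}

# ---- leaf scene ----------------------------------------------------------

#' Configuration of a synthetic expanding-leaf scene
#'
#' The scene is a speckle-textured lamina undergoing isotropic areal
#' expansion about a fixed centroid with a prescribed time-varying RGR
#' r(t): material points follow x(t) = c + exp(S(t)/2) (x0 - c) with
#' S(t) the time integral of r, so the true area grows exactly as
#' exp(S(t)).
#'
#' @param image_size Frame size in px, `c(rows, cols)` or a scalar.
#' @param rgr_profile Function of (clock hours, elapsed hours) returning
#'   RGR in 1/h (see [leaf_rgr_profile()]), or a single number for a
#'   constant rate.
#' @param duration_h Stack duration in hours.
#' @param interval_s Frame cadence in seconds (leaf default 90).
#' @param start_clock_time Clock time of frame 0 in hours.
#' @param centroid Expansion centre (x, y) in px; default frame centre.
#' @param aoi_radius Radius of the default octagonal area of interest, px.
#' @param texture_scale Speckle correlation length in px.
#' @param contrast Texture standard deviation in grey units.
#' @param noise_sigma Additive Gaussian sensor noise s.d. in grey units.
#' @param pixel_size mm/px.
#' @param seed Integer seed fixing the render bit-exactly.
#' @return A list of class `leaf_scene_config`.
#' @export
leaf_scene_config <- function(image_size = 192, rgr_profile = 0.015,
                              duration_h = 4, interval_s = 90,
                              start_clock_time = 8, centroid = NULL,
                              aoi_radius = NULL, texture_scale = 1.5,
                              contrast = 0.15, noise_sigma = 0.006,
                              pixel_size = 0.02, seed = 1L) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  if (is.numeric(rgr_profile)) {
    rate <- rgr_profile
    rgr_profile <- function(clock_h, elapsed_h = 0) rep(rate, length(clock_h))
  }
  centroid <- centroid %||% c((image_size[2] - 1) / 2, (image_size[1] - 1) / 2)
  aoi_radius <- aoi_radius %||% (0.3 * min(image_size))
  structure(list(image_size = image_size, rgr_profile = rgr_profile,
                 duration_h = duration_h, interval_s = interval_s,
                 start_clock_time = start_clock_time, centroid = centroid,
                 aoi_radius = aoi_radius, texture_scale = texture_scale,
                 contrast = contrast, noise_sigma = noise_sigma,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "leaf_scene_config")
}

#' Render a synthetic leaf stack with ground truth
#'
#' @param config A [leaf_scene_config()].
#' @return List with `stack` (an `image_stack`) and `truth`: a per-frame
#'   data frame (`frame`, `t_s`, `clock_h`, `rgr_h`, `area_scale`), the
#'   true AOI polygon per frame (`aoi`), the initial polygon (`aoi0`),
#'   the centroid and the exact between-frame displacement fields as a
#'   function `displacement(k)`.
#' @export
make_leaf_stack <- function(config) {
  stopifnot(inherits(config, "leaf_scene_config"))
  with_seed(config$seed, {
    nr <- config$image_size[1]; nc <- config$image_size[2]
    n <- max(2L, floor(config$duration_h * 3600 / config$interval_s) + 1L)
    tl <- build_timeline(config$start_clock_time, config$interval_s, n)
    t_s <- timeline_times(tl); clock_h <- timeline_clock(tl)
    elapsed_h <- t_s / 3600
    r <- config$rgr_profile(clock_h, elapsed_h)          # 1/h at frame times
    # cumulative integral S(t) by trapezoid
    S <- c(0, cumsum((head(r, -1) + tail(r, -1)) / 2 * diff(elapsed_h)))
    scl <- exp(S / 2)                                    # linear scale factor
    cx <- config$centroid[1]; cy <- config$centroid[2]

    margin <- 16
    tex <- make_master_texture(nc + 2 * margin, nr + 2 * margin,
                               x0 = -margin, y0 = -margin,
                               scale = config$texture_scale,
                               contrast = config$contrast)
    # default AOI: octagon of given radius around the centroid
    ang <- (seq_len(8) - 1) * pi / 4 + pi / 8
    aoi0 <- cbind(x = cx + config$aoi_radius * cos(ang),
                  y = cy + config$aoi_radius * sin(ang))
    aois <- lapply(seq_len(n), function(k)
      cbind(x = cx + (aoi0[, 1] - cx) * scl[k],
            y = cy + (aoi0[, 2] - cy) * scl[k]))
    for (k in seq_len(n)) {
      a <- aois[[k]]
      if (any(a[, 1] < 2 | a[, 1] > nc - 3 | a[, 2] < 2 | a[, 2] > nr - 3))
        abort_pf(sprintf("leaf grows out of frame at frame %d; shorten duration_h or enlarge image_size", k),
                 "phytoflow_config_error")
    }
    px <- rep(seq_len(nc) - 1, each = nr)
    py <- rep(seq_len(nr) - 1, times = nc)
    frames <- vector("list", n)
    for (k in seq_len(n)) {
      # inverse material map: frame pixel -> texture coordinate
      xs <- cx + (px - cx) / scl[k]
      ys <- cy + (py - cy) / scl[k]
      f <- matrix(sample_texture(tex, xs, ys), nr, nc)
      if (config$noise_sigma > 0)
        f <- f + matrix(rnorm(nr * nc, 0, config$noise_sigma), nr, nc)
      frames[[k]] <- clamp(f, 0, 1)
    }
    stack <- image_stack(frames, tl, config$pixel_size, role = "leaf")
    displacement <- function(k) {
      stopifnot(k >= 1, k < n)
      fac <- scl[k + 1] / scl[k] - 1
      list(dx = matrix((px - cx) * scl[k] * fac, nr, nc),
           dy = matrix((py - cy) * scl[k] * fac, nr, nc))
    }
    truth <- list(frames = data.frame(frame = seq_len(n), t_s = t_s,
                                      clock_h = clock_h, rgr_h = r,
                                      area_scale = exp(S)),
                  aoi0 = aoi0, aoi = aois,
                  centroid = c(cx, cy), displacement = displacement)
    list(stack = stack, truth = truth)
  })
}

#' Render a rigidly translating textured stack
#'
#' A flow-benchmark scene: the same speckle texture translated by a
#' constant velocity per frame, with optional additive noise.
#'
#' @param velocity `c(vx, vy)` in px/frame.
#' @param image_size Frame size in px (scalar or `c(rows, cols)`).
#' @param n_frames Number of frames.
#' @param interval_s Cadence in seconds.
#' @param texture_scale,contrast,noise_sigma As in [leaf_scene_config()].
#' @param pixel_size mm/px.
#' @param seed Integer seed.
#' @return List with `stack` and `truth` (`velocity` in px/frame).
#' @export
make_translation_stack <- function(velocity = c(1, 0), image_size = 256,
                                   n_frames = 20, interval_s = 90,
                                   texture_scale = 1.5, contrast = 0.15,
                                   noise_sigma = 0, pixel_size = 0.02,
                                   seed = 1L) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  with_seed(seed, {
    nr <- image_size[1]; nc <- image_size[2]
    margin <- ceiling(max(abs(velocity)) * n_frames) + 4
    tex <- make_master_texture(nc + 2 * margin, nr + 2 * margin,
                               x0 = -margin, y0 = -margin,
                               scale = texture_scale, contrast = contrast)
    px <- rep(seq_len(nc) - 1, each = nr)
    py <- rep(seq_len(nr) - 1, times = nc)
    frames <- lapply(seq_len(n_frames), function(k) {
      f <- matrix(sample_texture(tex, px - velocity[1] * (k - 1),
                                 py - velocity[2] * (k - 1)), nr, nc)
      if (noise_sigma > 0)
        f <- f + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
      clamp(f, 0, 1)
    })
    tl <- build_timeline(8, interval_s, n_frames)
    list(stack = image_stack(frames, tl, pixel_size, role = "leaf"),
         truth = list(velocity = velocity))
  })
}

# ---- root scene ----------------------------------------------------------

#' Configuration of a synthetic elongating-root scene
#'
#' A root of constant width grows along an arc-length parametrised path
#' (constant-curvature arc) from a fixed base: between frames the tip
#' advances along the path tangent by v(t) dt / pixel_size px while all
#' mature-region pixels stay fixed. The root is rendered dark on a bright
#' uniform background (or inverted) with a soft edge, so the tip position
#' is defined to sub-pixel precision.
#'
#' @param image_size Frame size in px, `c(rows, cols)` or a scalar.
#' @param velocity_profile Function of (clock hours, elapsed hours)
#'   returning mm/h (see [root_velocity_profile()]), or a single number.
#' @param duration_h Stack duration in hours.
#' @param interval_s Frame cadence in seconds (root default 30).
#' @param start_clock_time Clock time of frame 0 in hours.
#' @param base Root base (x, y) px; default top-centre.
#' @param phi0 Initial growth direction in radians (pi/2 = straight down).
#' @param curvature Path curvature in rad/px (0 = straight).
#' @param root_width Root width in px.
#' @param initial_length Arc length already grown at frame 0, px.
#' @param polarity `"dark"` (dark root, bright background) or `"bright"`.
#' @param bg Background grey level; the root sits `depth` below it.
#' @param depth Root-background contrast in grey units.
#' @param edge_width Width of the soft edge ramp, px.
#' @param noise_sigma Additive Gaussian noise s.d.
#' @param pixel_size mm/px (root default 0.01).
#' @param seed Integer seed.
#' @return A list of class `root_scene_config`.
#' @export
root_scene_config <- function(image_size = c(256, 160), velocity_profile = 0.6,
                              duration_h = 1, interval_s = 30,
                              start_clock_time = 8, base = NULL,
                              phi0 = pi / 2, curvature = 0,
                              root_width = 11, initial_length = 110,
                              polarity = c("dark", "bright"),
                              bg = 0.85, depth = 0.55, edge_width = 1.5,
                              noise_sigma = 0.02, pixel_size = 0.01,
                              seed = 1L) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  polarity <- match.arg(polarity)
  if (is.numeric(velocity_profile)) {
    v0 <- velocity_profile
    velocity_profile <- function(clock_h, elapsed_h = 0) rep(v0, length(clock_h))
  }
  base <- base %||% c((image_size[2] - 1) / 2, 6)
  structure(list(image_size = image_size, velocity_profile = velocity_profile,
                 duration_h = duration_h, interval_s = interval_s,
                 start_clock_time = start_clock_time, base = base,
                 phi0 = phi0, curvature = curvature, root_width = root_width,
                 initial_length = initial_length, polarity = polarity,
                 bg = bg, depth = depth, edge_width = edge_width,
                 noise_sigma = noise_sigma, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "root_scene_config")
}

# Point on the constant-curvature path at arc length s (px).
root_path_point <- function(config, s) {
  x0 <- config$base[1]; y0 <- config$base[2]
  phi0 <- config$phi0; c0 <- config$curvature
  if (abs(c0) < 1e-12) {
    cbind(x = x0 + s * cos(phi0), y = y0 + s * sin(phi0))
  } else {
    cbind(x = x0 + (sin(phi0 + c0 * s) - sin(phi0)) / c0,
          y = y0 - (cos(phi0 + c0 * s) - cos(phi0)) / c0)
  }
}

root_path_tangent <- function(config, s) {
  phi <- config$phi0 + config$curvature * s
  cbind(cos(phi), sin(phi))
}

#' Render a synthetic root stack with ground truth
#'
#' @param config A [root_scene_config()].
#' @return List with `stack` (an `image_stack`) and `truth`: per-frame
#'   data frame (`frame`, `t_s`, `clock_h`, `velocity_mm_h`,
#'   `arc_length_px`, `tip_x`, `tip_y`), a function `mask(k)` returning
#'   the true root mask of frame `k`, and the scene `config`.
#' @export
make_root_stack <- function(config) {
  stopifnot(inherits(config, "root_scene_config"))
  with_seed(config$seed, {
    nr <- config$image_size[1]; nc <- config$image_size[2]
    n <- max(2L, floor(config$duration_h * 3600 / config$interval_s) + 1L)
    tl <- build_timeline(config$start_clock_time, config$interval_s, n)
    t_s <- timeline_times(tl); clock_h <- timeline_clock(tl)
    elapsed_h <- t_s / 3600
    v <- config$velocity_profile(clock_h, elapsed_h)       # mm/h
    dL <- (head(v, -1) + tail(v, -1)) / 2 *
      diff(elapsed_h) / config$pixel_size                  # px per step
    L <- config$initial_length + c(0, cumsum(dL))          # arc length, px
    tips <- root_path_point(config, L)
    w2 <- config$root_width / 2
    guard <- w2 + config$edge_width + 2
    if (any(tips[, 1] < guard | tips[, 1] > nc - 1 - guard |
            tips[, 2] < guard | tips[, 2] > nr - 1 - guard))
      abort_pf(sprintf("root tip leaves the frame at frame %d; shorten duration_h or enlarge image_size",
                       which(tips[, 1] < guard | tips[, 1] > nc - 1 - guard |
                             tips[, 2] < guard | tips[, 2] > nr - 1 - guard)[1]),
               "phytoflow_config_error")

    # distance of every pixel to the full path, plus closest arc length
    ds <- 2
    sgrid <- seq(0, max(L), by = ds)
    if (sgrid[length(sgrid)] < max(L)) sgrid <- c(sgrid, max(L))
    pts <- root_path_point(config, sgrid)
    px <- rep(seq_len(nc) - 1, each = nr)
    py <- rep(seq_len(nr) - 1, times = nc)
    d2_full <- rep(Inf, nr * nc)
    s_close <- rep(0, nr * nc)
    for (i in seq_len(nrow(pts) - 1)) {
      ax <- pts[i, 1]; ay <- pts[i, 2]
      bx <- pts[i + 1, 1]; by <- pts[i + 1, 2]
      abx <- bx - ax; aby <- by - ay
      ab2 <- abx^2 + aby^2
      tt <- clamp(((px - ax) * abx + (py - ay) * aby) / ab2, 0, 1)
      d2 <- (px - (ax + tt * abx))^2 + (py - (ay + tt * aby))^2
      upd <- d2 < d2_full
      d2_full[upd] <- d2[upd]
      s_close[upd] <- sgrid[i] + tt[upd] * (sgrid[i + 1] - sgrid[i])
    }
    d_full <- sqrt(d2_full)

    edge <- config$edge_width
    frames <- vector("list", n)
    masks_env <- new.env(parent = emptyenv())
    render_cover <- function(k) {
      d <- d_full
      beyond <- s_close > L[k]
      if (any(beyond)) {
        tx <- tips[k, 1]; ty <- tips[k, 2]
        d[beyond] <- sqrt((px[beyond] - tx)^2 + (py[beyond] - ty)^2)
      }
      clamp(0.5 + (w2 - d) / edge, 0, 1)
    }
    for (k in seq_len(n)) {
      cover <- render_cover(k)
      f <- config$bg - config$depth * cover
      if (config$polarity == "bright") f <- 1 - f
      if (config$noise_sigma > 0)
        f <- f + rnorm(nr * nc, 0, config$noise_sigma)
      frames[[k]] <- matrix(clamp(f, 0, 1), nr, nc)
    }
    stack <- image_stack(frames, tl, config$pixel_size, role = "root")
    truth <- list(frames = data.frame(frame = seq_len(n), t_s = t_s,
                                      clock_h = clock_h, velocity_mm_h = v,
                                      arc_length_px = L,
                                      tip_x = tips[, 1], tip_y = tips[, 2]),
                  mask = function(k) matrix(render_cover(k) >= 0.5, nr, nc),
                  config = config)
    list(stack = stack, truth = truth)
  })
}

#' Render a diel series of re-staged root acquisition bursts
#'
#' Real rigs follow the advancing root tip with a movable camera stage, so
#' a full diel record is a sequence of short acquisitions in which the tip
#' is always in view. This helper emulates that: every `every_minutes` a
#' fresh burst of `burst_minutes` (plus one frame) is rendered with the
#' camera re-centred (arc length reset to `initial_length`), while the
#' velocity profile is evaluated at the burst's absolute clock time.
#'
#' @param config A [root_scene_config()]; its `duration_h` is ignored.
#' @param total_h Total diel coverage in hours.
#' @param burst_minutes Duration of each burst (one analysis window).
#' @param every_minutes Spacing between burst starts.
#' @return List with `bursts` (list of `make_root_stack()` results) and
#'   `schedule_df`: data frame (`burst`, `start_clock_h`, `elapsed_h`).
#' @export
make_root_burst_series <- function(config, total_h = 24, burst_minutes = 5,
                                   every_minutes = 30) {
  stopifnot(inherits(config, "root_scene_config"))
  starts_h <- seq(0, total_h - burst_minutes / 60, by = every_minutes / 60)
  bursts <- vector("list", length(starts_h))
  for (b in seq_along(starts_h)) {
    cfg <- config
    cfg$duration_h <- burst_minutes / 60 + cfg$interval_s / 3600
    cfg$start_clock_time <- (config$start_clock_time + starts_h[b]) %% 24
    cfg$seed <- config$seed + 7919L * b
    base_profile <- config$velocity_profile
    elapsed0 <- starts_h[b]
    cfg$velocity_profile <- local({
      e0 <- elapsed0; f <- base_profile
      function(clock_h, elapsed_h = 0) f(clock_h, elapsed_h + e0)
    })
    bursts[[b]] <- make_root_stack(cfg)
  }
  list(bursts = bursts,
       schedule_df = data.frame(burst = seq_along(starts_h),
                                start_clock_h = (config$start_clock_time +
                                                   starts_h) %% 24,
                                elapsed_h = starts_h))
}

# ---- treatment presets ---------------------------------------------------

#' Synthetic scene presets for the three root-zone treatments
#'
#' Fully specified leaf and root scene configurations mirroring the study
#' conditions: `control` (root-zone dark, ~0.6 mm/h with a small light-on
#' dip), `cooling` (root-zone cooled, constant ~0.3 mm/h) and
#' `illumination` (root-zone in the light schedule, a deep slowly
#' recovering morning trough plus a brief post-dusk dip, diel mean
#' ~0.4 mm/h). The leaf profile is identical across presets (nocturnal
#' plateau about 2.5x the diurnal one with a light-on transient),
#' reflecting that leaf growth is insensitive to the root-zone treatment.
#'
#' @param name One of `"control"`, `"cooling"`, `"illumination"`.
#' @param schedule [light_schedule()].
#' @param seed Integer seed for both scenes.
#' @return List with elements `leaf` ([leaf_scene_config()]), `root`
#'   ([root_scene_config()]) and `name`.
#' @export
treatment_presets <- function(name, schedule = light_schedule(), seed = 1L) {
  valid <- c("control", "cooling", "illumination")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    abort_pf(sprintf("unknown preset '%s'; valid presets: %s",
                     as.character(name)[1], paste(valid, collapse = ", ")),
             "phytoflow_validation_error")
  root_profile <- switch(name,
    control = root_velocity_profile(0.6, schedule,
                                    on_dip_depth = 0.09, on_dip_tau_h = NULL,
                                    on_dip_minutes = 30),
    cooling = root_velocity_profile(0.3, schedule),
    illumination = root_velocity_profile(0.43, schedule,
                                         on_dip_depth = 0.18,
                                         on_dip_tau_h = 4,
                                         off_dip_depth = 0.15,
                                         off_dip_tau_h = 1))
  # light-on RGR transient is less pronounced under root illumination
  leaf_profile <- leaf_rgr_profile(night = 0.040, day = 0.016,
                                   schedule = schedule,
                                   dip_depth = if (name == "illumination") 0.5 else 1.0,
                                   dip_minutes = 20, day_decline = 0.85)
  list(name = name,
       leaf = leaf_scene_config(image_size = 192, rgr_profile = leaf_profile,
                                duration_h = 24, interval_s = 90,
                                start_clock_time = schedule$light_on,
                                aoi_radius = 48, noise_sigma = 0.006,
                                pixel_size = 0.02, seed = seed),
       root = root_scene_config(image_size = c(256, 160),
                                velocity_profile = root_profile,
                                duration_h = 1, interval_s = 30,
                                start_clock_time = schedule$light_on,
                                noise_sigma = 0.02, pixel_size = 0.01,
                                seed = seed))
}

#' Export ground truth as plain-text tables
#'
#' Writes the per-frame truth of a synthetic scene to CSV (and the AOI
#' polygons to a simple `x,y` text format), schema-matched to the
#' analysis outputs so the two can be diffed directly.
#'
#' @param truth The `truth` element of [make_leaf_stack()] /
#'   [make_root_stack()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of files written, invisibly.
#' @export
export_truth <- function(truth, dir, prefix = "truth") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    abort_pf(sprintf("cannot create directory '%s'", dir), "phytoflow_io_error")
  files <- character(0)
  f <- file.path(dir, paste0(prefix, "_frames.csv"))
  write.csv(truth$frames, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(truth$aoi)) {
    f <- file.path(dir, paste0(prefix, "_aoi.csv"))
    poly <- do.call(rbind, lapply(seq_along(truth$aoi), function(k)
      data.frame(frame = k, vertex = seq_len(nrow(truth$aoi[[k]])),
                 x = truth$aoi[[k]][, 1], y = truth$aoi[[k]][, 2])))
    write.csv(poly, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
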