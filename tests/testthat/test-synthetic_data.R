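test_that("renders are bit-identical under the same seed", {
  a <- tiny_leaf(seed = 11, duration_h = 0.25)
  b <- tiny_leaf(seed = 11, duration_h = 0.25)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$frames, b$truth$frames)
  ra <- tiny_root(seed = 12, duration_h = 0.05)
  rb <- tiny_root(seed = 12, duration_h = 0.05)
  expect_identical(ra$stack$frames, rb$stack$frames)
  c <- tiny_leaf(seed = 13, duration_h = 0.25)
  expect_false(identical(a$stack$frames[[1]], c$stack$frames[[1]]))
})

test_that("zero growth renders identical frames; truth areas close exactly", {
  still <- make_leaf_stack(leaf_scene_config(image_size = 96, rgr_profile = 0,
                                             duration_h = 0.25,
                                             noise_sigma = 0, seed = 14))
  expect_equal(still$stack$frames[[1]],
               still$stack$frames[[length(still$stack$frames)]])
  # r = 0.01/h for 10 h: true area ratio exactly exp(0.1)
  grow <- make_leaf_stack(leaf_scene_config(image_size = 256, rgr_profile = 0.01,
                                            duration_h = 10, interval_s = 1800,
                                            aoi_radius = 40,
                                            noise_sigma = 0, seed = 15))
  n <- length(grow$stack$frames)
  expect_equal(grow$truth$frames$area_scale[n], exp(0.1), tolerance = 1e-12)
  a_ratio <- polygon_area(grow$truth$aoi[[n]])$px2 /
    polygon_area(grow$truth$aoi[[1]])$px2
  expect_equal(a_ratio, exp(0.1), tolerance = 1e-12)
})

test_that("the exported displacement truth reproduces the next frame", {
  sc <- tiny_leaf(rgr = 0.03, size = 96, duration_h = 0.5, seed = 16,
                  noise = 0.006)
  k <- 5
  disp <- sc$truth$displacement(k)
  f0 <- sc$stack$frames[[k]]; f1 <- sc$stack$frames[[k + 1]]
  px <- rep(0:95, each = 96); py <- rep(0:95, times = 96)
  # material point x in frame k appears at x + d(x) in frame k+1
  moved <- phytoflow:::cpp_bilinear(f1, px + as.vector(disp$dx),
                                    py + as.vector(disp$dy))
  ok <- !is.na(moved)
  rms <- sqrt(mean((moved[ok] - as.vector(f0)[ok])^2))
  expect_lt(rms, 2 * 0.006)
})

test_that("root truth obeys the velocity-to-pixels conversion", {
  sc <- make_root_stack(root_scene_config(velocity_profile = 0.6,
                                          duration_h = 0.05, interval_s = 30,
                                          pixel_size = 0.01, noise_sigma = 0,
                                          seed = 17))
  dL <- diff(sc$truth$frames$arc_length_px)
  expect_equal(dL, rep(0.5, length(dL)), tolerance = 1e-9)  # 0.5 px/frame
  step <- sqrt(diff(sc$truth$frames$tip_x)^2 + diff(sc$truth$frames$tip_y)^2)
  expect_equal(step, rep(0.5, length(step)), tolerance = 1e-6)
  # v = 0: static stack
  sc0 <- make_root_stack(root_scene_config(velocity_profile = 0,
                                           duration_h = 0.05,
                                           noise_sigma = 0, seed = 18))
  expect_identical(sc0$stack$frames[[1]],
                   sc0$stack$frames[[length(sc0$stack$frames)]])
  # curvature: along-path displacement exceeds the straight-line chord
  scc <- make_root_stack(root_scene_config(velocity_profile = 0.8,
                                           duration_h = 1, curvature = 0.01,
                                           image_size = c(230, 230),
                                           base = c(170, 8),
                                           initial_length = 130,
                                           noise_sigma = 0, seed = 19))
  tf <- scc$truth$frames
  n <- nrow(tf)
  arc <- tf$arc_length_px[n] - tf$arc_length_px[1]
  chord <- sqrt((tf$tip_x[n] - tf$tip_x[1])^2 + (tf$tip_y[n] - tf$tip_y[1])^2)
  expect_gt(arc, chord)
})

test_that("scene configs reject geometry that leaves the frame", {
  expect_error(make_leaf_stack(leaf_scene_config(image_size = 64,
                                                 rgr_profile = 2,
                                                 duration_h = 4,
                                                 aoi_radius = 25, seed = 20)),
               class = "phytoflow_config_error")
  expect_error(make_root_stack(root_scene_config(velocity_profile = 1,
                                                 duration_h = 6, seed = 21)),
               class = "phytoflow_config_error")
})

test_that("treatment presets encode the study's velocity regimes", {
  sch <- light_schedule(8, 20)
  clock <- seq(8, 31.9, by = 0.05) %% 24
  elapsed <- seq(0, 23.9, by = 0.05)
  # cooling: constant 0.3 mm/h
  cool <- treatment_presets("cooling", sch)
  vc <- cool$root$velocity_profile(clock, elapsed)
  expect_true(all(vc == 0.3))
  # control: diel mean within 2% of 0.6 mm/h
  ctl <- treatment_presets("control", sch)
  v0 <- ctl$root$velocity_profile(clock, elapsed)
  expect_lt(abs(mean(v0) - 0.6) / 0.6, 0.02)
  # illumination: nocturnal and diurnal means within 15% of each other,
  # overall mean about 0.4 mm/h
  ill <- treatment_presets("illumination", sch)
  vi <- ill$root$velocity_profile(clock, elapsed)
  lab <- partition_periods(elapsed, 8, sch)
  md <- mean(vi[lab$period == "diurnal"])
  mn <- mean(vi[lab$period == "nocturnal"])
  expect_lt(abs(md - mn) / mn, 0.15)
  expect_lt(abs(mean(vi) - 0.4) / 0.4, 0.05)
  # the leaf profile is shared across presets: nocturnal plateau ~2.5x day
  rl <- ctl$leaf$rgr_profile(clock, elapsed)
  expect_equal(max(rl) / rl[which.min(abs(clock - 9))], 2.5, tolerance = 1e-9)
  expect_error(treatment_presets("freezing"),
               class = "phytoflow_validation_error")
  err <- tryCatch(treatment_presets("freezing"), error = function(e) e)
  expect_match(conditionMessage(err), "control, cooling, illumination")
})

test_that("ground-truth export is schema-matched and idempotent", {
  sc <- tiny_leaf(duration_h = 0.25, seed = 22)
  dir <- tempfile()
  files <- export_truth(sc$truth, dir)
  expect_true(all(file.exists(files)))
  tr <- read.csv(file.path(dir, "truth_frames.csv"))
  expect_equal(nrow(tr), length(sc$stack$frames))
  expect_true(all(c("frame", "t_s", "clock_h", "rgr_h") %in% names(tr)))
  first <- readLines(file.path(dir, "truth_frames.csv"))
  export_truth(sc$truth, dir)
  expect_identical(readLines(file.path(dir, "truth_frames.csv")), first)
})
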