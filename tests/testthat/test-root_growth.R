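test_that("root segmentation matches the rendered mask for both polarities", {
  sc <- tiny_root(v = 0.6, duration_h = 0.1, seed = 5)
  m <- segment_root(sc$stack$frames[[1]])
  truth <- sc$truth$mask(1)
  jac <- sum(m & truth) / sum(m | truth)
  expect_gt(jac, 0.9)
  expect_equal(attr(m, "polarity"), "dark")
  # inverted polarity gives the same mask
  sc2 <- tiny_root(v = 0.6, duration_h = 0.1, seed = 5, polarity = "bright")
  m2 <- segment_root(sc2$stack$frames[[1]])
  expect_equal(attr(m2, "polarity"), "bright")
  expect_gt(sum(m2 & truth) / sum(m2 | truth), 0.9)
  # blank frame: nothing to segment
  expect_error(segment_root(matrix(0.5, 64, 64)),
               class = "phytoflow_segmentation_error")
})

test_that("geodesic distances follow the mask, not the chord", {
  # L-shaped skeleton; oracle = plain Dijkstra in R over the same graph
  m <- matrix(FALSE, 12, 12)
  m[2, 2:9] <- TRUE   # horizontal arm
  m[2:10, 9] <- TRUE  # vertical arm
  geo <- phytoflow:::cpp_geodesic(m, 1L, 1L)  # start (row 2, col 2), 0-based
  pts <- which(m, arr.ind = TRUE)
  idx <- function(i, j) which(pts[, 1] == i & pts[, 2] == j)
  n <- nrow(pts)
  dist <- rep(Inf, n); dist[idx(2, 2)] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    done[u] <- TRUE
    for (w in seq_len(n)) {
      dd <- max(abs(pts[w, ] - pts[u, ]))
      if (dd == 1) {
        step <- sqrt(sum((pts[w, ] - pts[u, ])^2))
        if (dist[u] + step < dist[w]) dist[w] <- dist[u] + step
      }
    }
  }
  got <- geo$dist[cbind(pts[, 1], pts[, 2])]
  expect_equal(got, dist, tolerance = 1e-12)
  # far end of the L: along-path distance, well above the Euclidean chord
  expect_equal(geo$dist[10, 9], 7 + 8, tolerance = 1.5)
  expect_gt(geo$dist[10, 9], sqrt(7^2 + 8^2))
})

test_that("tip location picks the geodesically farthest endpoint", {
  sc <- tiny_root(v = 0.6, duration_h = 0.1, seed = 5, curvature = 0)
  m <- segment_root(sc$stack$frames[[1]])
  lt <- locate_tip(m, anchor = c(sc$truth$config$base[1], 6))
  tru <- c(sc$truth$frames$tip_x[1], sc$truth$frames$tip_y[1])
  # skeleton endpoint sits about half a width behind the rounded cap
  expect_lt(abs(lt$tip[1] - tru[1]), 2)
  expect_lt(tru[2] - lt$tip[2], 8)
  expect_gt(lt$tip[2], tru[2] - 8)
  expect_equal(lt$tangent[2], 1, tolerance = 0.05)  # growing downwards
  # strongly curved root: geodesic metric still finds the advancing end
  scc <- tiny_root(v = 0.6, duration_h = 0.1, seed = 6, curvature = 0.012,
                   initial_length = 150, image_size = c(220, 220),
                   base = c(170, 8))
  mc <- segment_root(scc$stack$frames[[1]])
  ltc <- locate_tip(mc, anchor = c(170, 8))
  truc <- c(scc$truth$frames$tip_x[1], scc$truth$frames$tip_y[1])
  expect_lt(sqrt(sum((ltc$tip - truc)^2)), 8)
  expect_equal(ltc$arc_px, scc$truth$frames$arc_length_px[1], tolerance = 10)
})

test_that("two equal branches raise an ambiguity error", {
  m <- matrix(FALSE, 40, 40)
  m[5:20, 19:21] <- TRUE             # stem
  for (k in 0:14) {                  # two symmetric branches
    m[20 + k, (19:21) - k] <- TRUE
    m[20 + k, (19:21) + k] <- TRUE
  }
  expect_error(locate_tip(m, anchor = c(19, 5)),
               class = "phytoflow_ambiguity_error")
})

test_that("anchor registration detects drift and textureless patches", {
  sc <- tiny_root(v = 0, duration_h = 0.05, seed = 7, noise = 0.01)
  anchor <- c(sc$truth$config$base[1], 30)
  pos <- register_anchor(sc$stack, anchor)
  expect_lt(attr(pos, "max_drift"), 0.3)
  expect_true(attr(pos, "fixed"))
  # inject 1-px global jitter into one frame
  jit <- sc$stack
  f <- jit$frames[[3]]
  jit$frames[[3]] <- cbind(f[, 1], f[, -ncol(f)])  # shift 1 px in x
  posj <- register_anchor(jit, anchor)
  expect_gt(attr(posj, "max_drift"), 0.6)
  # textureless patch: correlation undefined
  expect_error(register_anchor(sc$stack, c(30, 200)),
               class = "phytoflow_degenerate_error")
})

test_that("tip velocity recovers constant elongation and is invariant", {
  sc <- tiny_root(v = 0.6, duration_h = 0.5, seed = 8)
  ts <- tip_velocity_series(sc$stack)
  expect_equal(nrow(ts), 6)
  expect_lt(max(abs(ts$velocity_mm_h - 0.6) / 0.6), 0.05)
  # window additivity: total path equals the sum of per-window paths
  tp <- attr(ts, "tips")
  expect_true(all(tp$valid))
  # intensity scaling invariance
  scl <- sc$stack
  scl$frames <- lapply(scl$frames, function(m) m * 0.8)
  tss <- tip_velocity_series(scl)
  expect_equal(tss$velocity_mm_h, ts$velocity_mm_h, tolerance = 0.02)
  # polarity inversion invariance
  scb <- tiny_root(v = 0.6, duration_h = 0.5, seed = 8, polarity = "bright")
  tsb <- tip_velocity_series(scb$stack)
  expect_lt(max(abs(tsb$velocity_mm_h - 0.6) / 0.6), 0.05)
})

test_that("a static root reads as (near) zero velocity", {
  sc <- tiny_root(v = 0, duration_h = 0.25, seed = 9, noise = 0.0275)
  ts <- tip_velocity_series(sc$stack)
  expect_lt(max(abs(ts$velocity_mm_h)), 0.01)
})

test_that("curved growth is not under-reported by the along-path estimate", {
  sc <- tiny_root(v = 0.6, duration_h = 0.5, seed = 10, curvature = 0.01,
                  initial_length = 130, image_size = c(230, 230),
                  base = c(170, 8))
  ts <- tip_velocity_series(sc$stack)
  expect_lt(max(abs(ts$velocity_mm_h - 0.6) / 0.6), 0.05)
  # chord velocity underestimates on a curved path
  expect_true(all(ts$straight_mm_h <= ts$velocity_mm_h + 0.02))
})
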