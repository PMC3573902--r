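make_stack_from <- function(frames, interval_s = 90) {
  image_stack(frames, build_timeline(8, interval_s, length(frames)), 0.02)
}

test_that("spatiotemporal gradients match analytic derivatives", {
  p <- flow_params()
  # constant sequence: all gradients vanish
  const <- lapply(1:5, function(k) matrix(0.5, 32, 32))
  g <- spatiotemporal_gradients(const, 3, p)
  expect_lt(max(abs(g$gx)), 1e-12)
  expect_lt(max(abs(g$gy)), 1e-12)
  expect_lt(max(abs(g$gt)), 1e-12)
  # static ramp g(x, y) = x: gx = 1, gy = 0, gt = 0 in the interior
  ramp <- matrix(rep(0:31, each = 32), 32, 32) / 31
  g <- spatiotemporal_gradients(lapply(1:5, function(k) ramp), 3, p)
  interior <- 6:27
  expect_equal(max(abs(g$gx[interior, interior] - 1 / 31)), 0, tolerance = 1e-10)
  expect_lt(max(abs(g$gy[interior, interior])), 1e-12)
  expect_lt(max(abs(g$gt[interior, interior])), 1e-12)
  # sinusoid translating at 1 px/frame: g_t = -g_x in the interior
  sine <- lapply(1:5, function(k) {
    x <- matrix(rep(0:47, each = 48), 48, 48)
    0.5 + 0.3 * sin(2 * pi * (x - (k - 1)) / 16)
  })
  g <- spatiotemporal_gradients(sine, 3, p)
  interior <- 8:41
  resid <- g$gt[interior, interior] + g$gx[interior, interior]
  expect_lt(max(abs(resid)), 0.05 * max(abs(g$gx[interior, interior])))
  # window bounds are enforced
  expect_error(spatiotemporal_gradients(const, 1, p),
               class = "phytoflow_window_error")
})

test_that("structure tensor is PSD and degenerates as expected", {
  p <- flow_params(window_sigma = 2)
  z <- matrix(0, 24, 24)
  tens <- build_structure_tensor(z, z, z, p)
  expect_true(all(abs(unlist(tens)) < 1e-15))
  # single gradient direction: rank-1 tensor, two (near) zero eigenvalues
  gx <- matrix(1, 24, 24)
  tens <- build_structure_tensor(gx, z, z, p)
  J <- matrix(c(tens$Jxx[12, 12], tens$Jxy[12, 12], tens$Jxt[12, 12],
                tens$Jxy[12, 12], tens$Jyy[12, 12], tens$Jyt[12, 12],
                tens$Jxt[12, 12], tens$Jyt[12, 12], tens$Jtt[12, 12]), 3, 3)
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1], 1, tolerance = 1e-6)
  expect_lt(max(abs(ev[2:3])), 1e-12)
  # random gradients: dense per-pixel eigendecomposition stays PSD
  set.seed(1)
  gx <- matrix(rnorm(24^2), 24, 24)
  gy <- matrix(rnorm(24^2), 24, 24)
  gt <- matrix(rnorm(24^2), 24, 24)
  tens <- build_structure_tensor(gx, gy, gt, p)
  for (idx in list(c(5, 5), c(12, 18), c(20, 3))) {
    i <- idx[1]; j <- idx[2]
    J <- matrix(c(tens$Jxx[i, j], tens$Jxy[i, j], tens$Jxt[i, j],
                  tens$Jxy[i, j], tens$Jyy[i, j], tens$Jyt[i, j],
                  tens$Jxt[i, j], tens$Jyt[i, j], tens$Jtt[i, j]), 3, 3)
    expect_gt(min(eigen(J, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
  expect_error(build_structure_tensor(gx, gy[1:10, ], gt, p),
               class = "phytoflow_validation_error")
})

test_that("flow confidence equals the eigenvalue coherence", {
  p <- flow_params()
  z <- matrix(0, 8, 8)
  tens <- list(Jxx = z, Jxy = z, Jxt = z, Jyy = z, Jyt = z, Jtt = z)
  expect_true(all(flow_confidence(tens, p) == 0))
  # rank-2 tensor with l3 = 0, l2 > 0: coherence 1
  tens <- list(Jxx = z + 2, Jxy = z, Jxt = z, Jyy = z + 1, Jyt = z, Jtt = z)
  expect_equal(flow_confidence(tens, p)[4, 4], 1, tolerance = 1e-9)
  # random PSD tensor: matches direct eigen computation
  set.seed(2)
  A <- crossprod(matrix(rnorm(9), 3, 3))
  tens <- list(Jxx = z + A[1, 1], Jxy = z + A[1, 2], Jxt = z + A[1, 3],
               Jyy = z + A[2, 2], Jyt = z + A[2, 3], Jtt = z + A[3, 3])
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(flow_confidence(tens, p)[2, 2],
               (ev[2] - ev[3]) / (ev[2] + ev[3] + 1e-12), tolerance = 1e-9)
})

test_that("flow recovers known translations and flags degenerate scenes", {
  ts <- tiny_translation(c(1, 0), size = 128, n = 9)
  f <- estimate_flow_field(ts$stack, 5)
  expect_lt(abs(median(f$u[f$valid]) - 1), 0.05)
  expect_lt(abs(median(f$v[f$valid])), 0.05)
  # integer block matching as an independent oracle on the same scene
  f1 <- ts$stack$frames[[1]]; f2 <- ts$stack$frames[[2]]
  patch <- f1[40:80, 40:80]
  scores <- sapply(-3:3, function(s)
    stats::cor(as.vector(patch), as.vector(f2[40:80, (40:80) + s])))
  expect_equal((-3:3)[which.max(scores)], 1)

  # static scene: median speed below 0.01 px/frame
  ts0 <- tiny_translation(c(0, 0), size = 128, n = 9)
  f0 <- estimate_flow_field(ts0$stack, 5)
  expect_lt(median(sqrt(f0$u[f0$valid]^2 + f0$v[f0$valid]^2)), 0.01)

  # textureless scene: all invalid with a warning, never silent numbers
  un <- lapply(1:5, function(k) matrix(0.5, 48, 48))
  expect_warning(fu <- estimate_flow_field(make_stack_from(un), 3),
                 "textureless|constant")
  expect_false(any(fu$valid))
})

test_that("flow is invariant to intensity scaling and antisymmetric in time", {
  ts <- tiny_translation(c(0.4, 0.2), size = 96, n = 9)
  f <- estimate_flow_field(ts$stack, 5)
  scaled <- ts$stack
  scaled$frames <- lapply(scaled$frames, function(m) m * 1.7)
  fs <- estimate_flow_field(scaled, 5)
  expect_equal(fs$u[fs$valid & f$valid], f$u[fs$valid & f$valid],
               tolerance = 1e-6)
  rev_stack <- ts$stack
  rev_stack$frames <- rev(rev_stack$frames)
  fr <- estimate_flow_field(rev_stack, 5)
  expect_equal(median(fr$u[fr$valid]), -median(f$u[f$valid]), tolerance = 0.02)
  expect_equal(median(fr$v[fr$valid]), -median(f$v[f$valid]), tolerance = 0.02)
})

test_that("integrated displacement follows material points", {
  ts <- tiny_translation(c(0.3, 0), size = 128, n = 11)
  pts <- cbind(x = c(50, 70), y = c(64, 50))
  moved <- displacement_between(ts$stack, 1, 11, points = pts)
  expect_equal(moved[, "x"] - pts[, "x"], c(3, 3), tolerance = 0.1)
  expect_equal(moved[, "y"] - pts[, "y"], c(0, 0), tolerance = 0.1)
  expect_error(displacement_between(ts$stack, 5, 5),
               class = "phytoflow_validation_error")

  # expansion: a point at radius R ends at R * exp(S/2) after k frames
  sc <- tiny_leaf(rgr = 0.03, size = 128, duration_h = 1)
  k <- 21
  S <- log(sc$truth$frames$area_scale[k])
  ctr <- sc$truth$centroid
  pts <- cbind(x = ctr[1] + c(30, -25), y = ctr[2] + c(0, 10))
  moved <- displacement_between(sc$stack, 1, k,
                                params = flow_params(pyramid_levels = 1),
                                points = pts)
  expected <- cbind(x = ctr[1] + (pts[, 1] - ctr[1]) * exp(S / 2),
                    y = ctr[2] + (pts[, 2] - ctr[2]) * exp(S / 2))
  expect_lt(max(abs(moved - expected)), 0.15)
})
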