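# Internal numeric helpers shared across modules.

# Sampled Gaussian kernel (order 0) or Gaussian first-derivative kernel
# (order 1), normalised so that correlation with a constant gives the
# constant (order 0) or with a unit ramp gives exactly 1 (order 1).
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(sigma > 0)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    k <- x * g
    k / sum(x * k)
  } else {
    stop("order must be 0 or 1")
  }
}

# Correlation of a matrix with separable kernels (kx along columns/x,
# ky along rows/y); replicate borders.
sepconv2 <- function(img, kx, ky) {
  cpp_sepconv2(img, as.numeric(kx), as.numeric(ky))
}

gauss_smooth2 <- function(img, sigma) {
  k <- gauss_kernel(sigma, 0L)
  cpp_sepconv2(img, k, k)
}

# 2x downsampling with Gaussian pre-filter (pyramid reduction).
pyr_down <- function(img, sigma = 1.0) {
  sm <- gauss_smooth2(img, sigma)
  sm[seq(1, nrow(img), by = 2L), seq(1, ncol(img), by = 2L), drop = FALSE]
}

# Bilinear resize of a matrix to given dimensions.
resize_bilinear <- function(img, nrow_out, ncol_out) {
  ys <- seq(0, nrow(img) - 1, length.out = nrow_out)
  xs <- seq(0, ncol(img) - 1, length.out = ncol_out)
  grid_x <- rep(xs, each = nrow_out)
  grid_y <- rep(ys, times = ncol_out)
  matrix(cpp_bilinear(img, grid_x, grid_y), nrow = nrow_out, ncol = ncol_out)
}

# Clamp helper.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic local RNG scope: runs expr with the given seed without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

abort_pf <- function(msg, class) {
  stop(structure(class = c(class, "phytoflow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
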