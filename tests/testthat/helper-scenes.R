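# Small scene builders shared across test files. Everything is generated
# in code at test time; sizes are kept small so the default run stays fast.

tiny_translation <- function(v, size = 96, n = 9, noise = 0, seed = 42) {
  make_translation_stack(velocity = v, image_size = size, n_frames = n,
                         noise_sigma = noise, seed = seed)
}

tiny_leaf <- function(rgr = 0.015, size = 128, duration_h = 1.5, seed = 42,
                      noise = 0.006) {
  make_leaf_stack(leaf_scene_config(image_size = size, rgr_profile = rgr,
                                    duration_h = duration_h,
                                    noise_sigma = noise, seed = seed))
}

tiny_root <- function(v = 0.6, duration_h = 0.5, seed = 42, curvature = 0.002,
                      noise = 0.02, ...) {
  make_root_stack(root_scene_config(velocity_profile = v,
                                    duration_h = duration_h,
                                    curvature = curvature,
                                    noise_sigma = noise, seed = seed, ...))
}

# analytic velocity_field for tests that need exact fields
analytic_field <- function(fu, fv, dim = c(64, 64), interval_s = 90) {
  px <- matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2])
  py <- matrix(rep(seq_len(dim[1]) - 1, times = dim[2]), dim[1], dim[2])
  u <- fu(px, py); v <- fv(px, py)
  structure(list(u = u, v = v,
                 confidence = matrix(1, dim[1], dim[2]),
                 valid = matrix(TRUE, dim[1], dim[2]),
                 u_fill = u, v_fill = v,
                 centre_index = 1L, centre_time = 0,
                 interval_s = interval_s, pixel_size = 0.02),
            class = "velocity_field")
}

octagon <- function(cx, cy, r) {
  ang <- (seq_len(8) - 1) * pi / 4 + pi / 8
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}
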