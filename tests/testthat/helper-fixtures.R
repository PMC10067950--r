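# Shared fixtures: small configurations and phantom settings used across
# test files. All fixtures are built in code at test time.

# non-degenerate tiny stream: 32x32 input -> 4x4x3 feature map
tiny_stream_config <- function() {
  stream_config(block_strides = c(1L, 2L, 2L, 2L, 1L, 1L),
                block_widths = c(2L, 3L, 4L, 4L, 4L, 4L),
                input_shape = c(32L, 32L))
}

# small, noise-free phantom for geometry checks
quiet_phantom_params <- function(...) {
  defaults <- list(n_subjects = 2L, image_height_px = 250L,
                   image_width_px = 200L, pixel_spacing_mm = 2,
                   asymmetry_jitter_mm = 0, noise_sd = 0)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

tiny_pair <- function(seed = 5, pair = c(0L, 0L), target = c(32L, 32L)) {
  s <- generate_subject(quiet_phantom_params(), "s1", seed = seed,
                        force_pair = pair)
  prepare_pair(s$ap_view, target = target)
}

random_probs <- function(n = 1) {
  p <- matrix(stats::rexp(3 * n), ncol = 3)
  p / rowSums(p)
}
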