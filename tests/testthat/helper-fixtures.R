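# Shared fixtures, built in code at test time.

# Small noise-free lawn ground truth with a centred producer colony.
tiny_lawn_gt <- function(decay_length = 100, noise_sd = 0, gain = 10,
                         baseline = 0, seed = 1L, pixel_size = 5,
                         image_shape = c(200L, 200L), radius = 100) {
  scene_ground_truth(
    pixel_size = pixel_size, image_shape = image_shape,
    producer_colonies = data.frame(x = image_shape[2] * pixel_size / 2,
                                   y = image_shape[1] * pixel_size / 2,
                                   r = radius),
    toxin_amplitude = 1000, decay_length = decay_length,
    yfp_baseline = baseline, yfp_gain = gain,
    cfp_level = 3000, mcherry_level = 20000,
    noise_sd = noise_sd, seed = seed)
}

# Independent dense-grid oracle for the half-maximal crossing distance of a
# closed-form curve y(d): first d (resolution `res`) with y(d) <= level.
dense_crossing_oracle <- function(f, level, upper = 1000, res = 0.001) {
  d <- seq(0, upper, by = res)
  d[which(f(d) <= level)[1L]]
}

# Two-pass mean/SD oracle (n-1 denominator), independent of stats::sd.
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Closed-form Welch test oracle.
welch_oracle <- function(a, b) {
  va <- two_pass_sd(a)^2 / length(a)
  vb <- two_pass_sd(b)^2 / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
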