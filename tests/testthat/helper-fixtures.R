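# Shared fixtures, all generated in code.

# uniform calibrated image of one color
uniform_image <- function(color = c(0.5, 0.5, 0.5), h = 48, w = 48) {
  px <- array(rep(color, each = h * w), dim = c(h, w, 3))
  as_calibrated_image(px)
}

# random-pixel calibrated image (deterministic given seed)
random_image <- function(h = 48, w = 48, seed = 1) {
  px <- pattsig:::with_seed(seed, array(runif(h * w * 3), dim = c(h, w, 3)))
  as_calibrated_image(px)
}

# small Gabor bank usable on ~48 px maps (4 scales -> 2 bands)
small_bank <- function() {
  gabor_bank(n_scales = 4L, filter_sizes = c(7L, 9L, 11L, 13L),
             effective_widths = c(2.8, 3.6, 4.5, 5.4),
             wavelengths = c(3.5, 4.6, 5.6, 6.8),
             pool_sizes = c(4L, 6L))
}

# random signature dataset with labels unrelated to the matrix
null_signature_dataset <- function(n = 20, T = 10, seed = 1) {
  pattsig:::with_seed(seed, {
    m <- matrix(runif(n * T), n, T)
    signature_dataset(m, rep(c("a", "b"), length.out = n))
  })
}

# perfectly separated two-class dataset: all-0 rows vs all-1 rows
separated_dataset <- function(n_per = 5, T = 10) {
  m <- rbind(matrix(0, n_per, T), matrix(1, n_per, T))
  signature_dataset(m, rep(c("lo", "hi"), each = n_per))
}

# two specs differing only in base hue at matched BT.601 luminance
matched_luminance_specs <- function(pixel_sd = 0) {
  noise <- list(hue_sd = 0, placement_sd = 0.015, pixel_sd = pixel_sd)
  green <- c(0.30, 0.55, 0.25)
  brown <- matched_luminance_color(green, red = 0.62, blue = 0.18)
  stripe_a <- c(0.70, 0.70, 0.70)
  stripe_b <- matched_luminance_color(stripe_a, red = 0.85, blue = 0.55)
  list(
    g = pattern_spec("g", green,
                     stripe = list(count = 2L, orientation = "vertical",
                                   width_frac = 0.12, color = stripe_a),
                     noise = noise),
    r = pattern_spec("r", brown,
                     stripe = list(count = 2L, orientation = "vertical",
                                   width_frac = 0.12, color = stripe_b),
                     noise = noise))
}
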