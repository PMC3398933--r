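# Small, fast rendering parameters for unit tests (96-px frames, fewer spots).
# Population-level calibration is exercised elsewhere with the real defaults.
small_params <- function(...) {
  args <- utils::modifyList(
    list(image_size = 96L, spot_count_rate = 45, spot_diameter_mean = 4,
         spot_diameter_sd = 1.2, spot_darkness = 0.1, noise_sd = 0.003),
    list(...))
  do.call(speckle_params, args)
}

# measure an egg with a small working window for speed
measure_small <- function(image) {
  egg_pattern_metrics(image, window = 128L)
}
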