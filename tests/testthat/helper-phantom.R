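# Small phantom specs for fast tests.

tiny_means_12bit <- c(ventricles = 3481, thalamus = 1638,
                      grey_matter = 2048, white_matter = 2662)

tiny_spec <- function(seed = 1, noise_sigma = 0, blur_sigma = 0,
                      stored_bits = 12, matrix_size = 64,
                      padding_mode = "zero_msb",
                      region_means = tiny_means_12bit, ...) {
  phantom_spec(matrix_size = matrix_size, stored_bits = stored_bits,
               padding_mode = padding_mode, region_means = region_means,
               noise_sigma = noise_sigma, blur_sigma = blur_sigma,
               seed = seed, ...)
}

# full-dynamic-range spec: brightest region at the stored-bit ceiling,
# background at zero
full_range_spec <- function(stored_bits = 12, seed = 1, ...) {
  full <- 2^stored_bits - 1
  tiny_spec(seed = seed, stored_bits = stored_bits,
            region_means = c(ventricles = full, thalamus = round(0.4 * full),
                             grey_matter = round(0.5 * full),
                             white_matter = round(0.65 * full)), ...)
}
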