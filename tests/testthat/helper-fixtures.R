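# shared in-code fixtures; nothing is read from disk

fp_axis <- seq(800, 1800, by = 2)

# single pseudo-Voigt peak spectrum on the fingerprint axis
peak_spectrum <- function(center, height = 1, fwhm = 25,
                          axis = fp_axis, baseline = 0) {
  u <- (axis - center) / (fwhm / 2)
  y <- height * (0.5 / (1 + u^2) + 0.5 * exp(-log(2) * u^2)) + baseline
  raman_spectrum(axis, y)
}

# replicate set of a shared smooth spectrum plus seeded iid noise
noisy_set <- function(base, n = 25, sd = 0.01, seed = 1) {
  set.seed(seed)
  m <- vapply(seq_len(n), function(j)
    base$intensity + rnorm(length(base$shift), 0, sd),
    numeric(length(base$shift)))
  spectrum_set(base$shift, m)
}

# noiseless single-spectrum fixture drawn from a tier library
clean_config <- function(seed, ...) {
  synthetic_config(seed = seed, background_fraction = 0,
                   cosmic_ray_rate = 0, include_atmospheric = FALSE,
                   n_replicates = 1L, axis_offset_cm1 = 0,
                   axis = fp_axis, ...)
}

single_target <- function(g) raman_spectrum(g$set$shift, g$set$intensity[, 1])
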