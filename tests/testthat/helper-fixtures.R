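# Shared fixtures, built in code at test time.

# a small raw voltage map with hand-set values
tiny_map <- function(n = 5L, seed = 42L) {
  eamreg:::with_seed(seed, {
    voltage_map(
      patient_id = "tiny",
      points = matrix(runif(3 * n, -20, 20), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z"))),
      unipolar = runif(n, 0.5, 6),
      bipolar = runif(n, 0.1, 3),
      af_type = 1L, recurrence_1y = 0L
    )
  })
}

# normalised, resampled shell cloud for registration tests
unit_shell <- function(i, n_raw = 1300L, n = 406L) {
  s <- generate_shell(n_raw, 1000L + i)
  m <- suppressWarnings(minmax_normalize(
    voltage_map(paste0("shell", i), s, seq_len(n_raw), seq_len(n_raw))))
  resample_points(m, n, seed = 5000L + i)$points
}

# small preprocessed synthetic cohort
small_cohort <- function(seed = 7L, n = 8L, effect_size = 2, noise_sd = 0.4) {
  spec <- cohort_spec(n_patients = n, points_per_map_range = c(450L, 900L),
                      effect_size = effect_size, noise_sd = noise_sd,
                      seed = seed)
  preprocess_maps(generate_cohort(spec), seed = seed)
}
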