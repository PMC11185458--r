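# Shared fixtures: small, fast parameter sets used across test files.
# 100 Hz keeps the 250 ms syllable and 80 ms boundary silence on exact
# sample boundaries (the default timing needs srate divisible by 100).

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(srate = 100, n_channels = 4L, noise_sd = 0, seed = 1L),
    list(...))
  do.call(synth_params, args)
}

default_timing <- timing_spec()

# acceptance-scale cohort: the study's subject and trial counts with the
# stated amplitude/noise defaults, at reduced spatial/temporal sampling
acceptance_config <- function(seed) {
  pipeline_config(
    n_subjects = 31L,
    synth = synth_params(srate = 100, n_channels = 16L),
    n_perm = 500L,
    seed = seed)
}

# spectral_coefficients stub for formula-level tests
fake_coeffs <- function(X, freqs = seq_len(dim(X)[3L]), srate = 100) {
  structure(list(X = X, freqs = freqs, N = dim(X)[1L], srate = srate),
            class = "spectral_coefficients")
}
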