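## Shared fixtures. The default EEG calibration is computed once here and
## reused through the package-level cache by every params construction
## with the same spectral configuration.

default_params <- participant_params(seed = 1L)

## Noise-free MEP side (same EEG configuration -> cache hit).
exact_params <- participant_params(mep_noise_cv = 0, excit_jitter_sd = 0,
                                   seed = 2L)

quiet <- function(expr) suppressWarnings(expr)

## Small trained feature cohort used by several classifier tests.
trained_features <- function(n_subjects = 4, n_per_state = 60, seed = 99,
                             ...) {
  simulate_eeg_cohort(n_subjects = n_subjects, n_per_state = n_per_state,
                      seed = seed, ...)
}
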