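# Shared small fixtures, built in code at test time.

# 30-trial design (5 levels x 3 trials x 2 repetitions), ~11 min session.
small_design <- function(seed = 7L) {
  generate_design(n_levels = 5, trials_per_level = 3, repetitions = 2,
                  seed = seed)
}

# Compact high-SNR recording for decoder tests: full montage, low noise.
small_recording <- function(seed = 7L, design = small_design(seed), ...) {
  cfg <- forward_model_config(seed = seed, ...)
  generate_fnirs(design, cfg)
}

quiet_decode <- function(...) suppressWarnings(nested_cv_decode(...))
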