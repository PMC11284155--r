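# Shared fixtures. Everything is generated in code; the heavier synthetic
# patients are cached in a session-local environment so several test files
# can share one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

sine_window <- function(freq, fs = 256, seconds = 5, amplitude = 1) {
  amplitude * sin(2 * pi * freq * (0:(fs * seconds - 1)) / fs)
}

# A small continuous synthetic patient: 4 seizures, strong alpha signature
# spanning the full preictal period (10-min SPH + 30-min SOP).
strong_patient_config <- function(seed = 1, n_channels = 1) {
  simulation_config(
    n_channels = n_channels, fs = 256, duration = 385 * 60,
    seizure_onsets = c(90, 185, 280, 375) * 60, min_seizure_gap = 90 * 60,
    preictal_duration = 40 * 60, effect_band = "alpha", effect_size = 4,
    seed = seed
  )
}

# Feature matrix + split for the strong patient, shared across test files.
strong_patient_split <- function(seed = 1) {
  cached(paste0("strong_split_", seed), {
    rec <- apply_filters(generate_recording(strong_patient_config(seed)),
                         0.5, 60)
    fm <- extract_features(make_windows(rec))
    chronological_split(fm, rec$seizure_onsets, 3)
  })
}

# Small segmented patient built from a continuous recording.
segmented_patient <- function(seed = 1, effect_size = 4) {
  cfg <- simulation_config(
    n_channels = 1, fs = 256, duration = 200 * 60,
    seizure_onsets = c(40, 80, 120, 160, 195) * 60, min_seizure_gap = 35 * 60,
    preictal_duration = 600, effect_band = "alpha",
    effect_size = effect_size, seed = seed
  )
  rec <- generate_recording(cfg)
  segment_recording(rec, segment_duration = 300, preictal_duration = 600,
                    shuffle_seed = seed)
}
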