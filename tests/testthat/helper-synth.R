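# Shared fixtures, built lazily and memoised for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Short three-phase recording: 30 s pre / 150 s stress / 60 s recovery,
# long enough for 2-6-2 construction.
tiny_recording <- function(st_stress = -150, st_rec = -60, noise0 = TRUE,
                           seed = 42) {
  assemble_recording(
    phase_durations = c(30, 150, 60), hr_ramp = c(70, 140),
    st_params = list(pre = 0, stress = st_stress, rec = st_rec),
    noise = if (noise0) list(wander = 0, broadband = 0, burst = 0)
            else list(wander = 50, broadband = 10, burst = 0),
    fs = 500, seed = seed)
}

fixture_noiseless_recording <- function() {
  memo("rec0", function() tiny_recording())
}

# Constant-rate recording assembled beat by beat (for tie-break and
# delineation oracles); fiducials exact by construction.
flat_recording <- function(rr = 0.8, n_beats = 12, st_offset = 0, fs = 500) {
  waves <- lapply(seq_len(n_beats), function(i) generate_beat(rr, st_offset, fs))
  x <- unlist(lapply(waves, `[[`, "waveform"))
  fid <- waves[[1]]$fiducials
  r_times <- (seq_len(n_beats) - 1) * rr + fid$r_peak
  list(x = x, fs = fs, r_times = r_times,
       q_times = (seq_len(n_beats) - 1) * rr + fid$q_onset,
       j_times = (seq_len(n_beats) - 1) * rr + fid$j_point)
}

make_seq <- function(values, patient_id = "T") {
  structure(list(values = values, boundaries = c(1000L, 4000L),
                 source_windows = c(pre = 0, stress = 10, rec = 20),
                 lead_id = "L1", patient_id = patient_id),
            class = "carpe_seq262")
}

# Small tabular-only cohort for model/eval tests.
fixture_patients <- function() {
  memo("patients300", function() {
    generate_cohort(300, prevalence = 0.329, seed = 7)$patients
  })
}

# Tiny signal cohort + trained scaled-down network shared by the mtl and
# explanation tests.
fixture_signal_cohort <- function() {
  memo("sigcohort", function() {
    generate_cohort(36, prevalence = 1 / 3, seed = 21,
                    config = cohort_config(phase_durations = c(30, 150, 60)),
                    signals = TRUE)
  })
}

fixture_mtl_model <- function() {
  memo("mtlmodel", function() {
    cohort <- fixture_signal_cohort()
    dat <- mtl_dataset(cohort, max_sequences = 3, seed = 5)
    cfg <- mtl_config(n_residual_blocks = 2, channel_width = 8, epochs = 2,
                      seed = 5)
    list(model = train_mtl(dat, cfg), data = dat, cohort = cohort)
  })
}
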