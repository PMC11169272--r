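#' Phase annotation for a stress-test recording
#'
#' The three phases of an exercise stress test — pre-stress (warm-up /
#' resting), stress (ergometry up to peak heart rate) and recovery — are
#' encoded by their two internal boundaries on a common time axis.
#'
#' @param pre_end End of the pre-stress phase, seconds.
#' @param stress_end End of the stress phase, seconds.
#' @param total Total recording duration, seconds.
#' @return A `carpe_phases` object.
#' @export
phase_annotation <- function(pre_end, stress_end, total) {
  if (!(0 < pre_end && pre_end < stress_end && stress_end < total)) {
    stopf("phase boundaries must satisfy 0 < pre_end < stress_end < total")
  }
  structure(list(pre_end = pre_end, stress_end = stress_end, total = total),
            class = "carpe_phases")
}

#' @export
print.carpe_phases <- function(x, ...) {
  cat(sprintf("<phases> pre [0, %.1f) stress [%.1f, %.1f) recovery [%.1f, %.1f)\n",
              x$pre_end, x$pre_end, x$stress_end, x$stress_end, x$total))
  invisible(x)
}

# Which phase does time t fall in? Returns "pre"/"stress"/"rec".
phase_of <- function(t, phases) {
  ifelse(t < phases$pre_end, "pre",
         ifelse(t < phases$stress_end, "stress", "rec"))
}

new_stress_recording <- function(signals, fs, lead_names, phases, truth = NULL,
                                 patient_id = NA_character_) {
  stopifnot(is.matrix(signals), fs %in% c(500, 1000))
  structure(list(signals = signals, fs = fs, lead_names = lead_names,
                 phases = phases, truth = truth, patient_id = patient_id),
            class = "carpe_recording")
}

#' @export
print.carpe_recording <- function(x, ...) {
  cat(sprintf("<stress recording> %d lead(s), %.1f s @ %d Hz, patient %s\n",
              ncol(x$signals), nrow(x$signals) / x$fs, x$fs, x$patient_id))
  print(x$phases)
  invisible(x)
}

#' Assemble a synthetic three-phase stress-test recording
#'
#' Concatenates beat templates along a heart-rate ramp that rises through the
#' stress phase and decays during recovery. For ischaemic patients the
#' stress-phase ST offset is negative (ST-segment depression); the recovery
#' offset is a configurable fraction of it. Baseline wander (slow sinusoids),
#' broadband noise and movement-noise bursts emulate the disturbances of
#' treadmill/bicycle ergometry. All programmed quantities (fiducial times,
#' per-phase ST offsets, per-minute heart-rate profile) are stored in
#' `$truth` so downstream measurements can be checked against ground truth.
#'
#' @param phase_durations Numeric triple `c(pre, stress, recovery)` seconds.
#' @param hr_ramp Numeric pair `c(rest, peak)` in beats/min, `peak > rest`.
#' @param st_params List with per-phase ST offsets in microvolts:
#'   `pre`, `stress`, `rec` (negative values = depression).
#' @param noise List with `wander`, `broadband`, `burst` amplitudes in
#'   microvolts (0 disables each component).
#' @param fs Sampling rate, 500 or 1000 Hz.
#' @param n_leads Number of leads (1-12); synthetic leads are amplitude-scaled
#'   variants of one underlying source with independent noise.
#' @param lead_scales Optional per-lead amplitude scales.
#' @param seed Integer seed; the recording is deterministic given the seed.
#' @param patient_id Identifier stamped on the recording.
#' @param morphology Beat morphology, see [beat_morphology()].
#' @return A `carpe_recording` object.
#' @export
assemble_recording <- function(phase_durations = c(60, 300, 180),
                               hr_ramp = c(70, 150),
                               st_params = list(pre = 0, stress = 0, rec = 0),
                               noise = list(wander = 50, broadband = 10, burst = 0),
                               fs = 500, n_leads = 1, lead_scales = NULL,
                               seed = NULL, patient_id = "synthetic",
                               morphology = beat_morphology()) {
  if (any(phase_durations <= 0)) stopf("phase durations must be positive")
  if (hr_ramp[2] <= hr_ramp[1]) stopf("peak HR must exceed rest HR")
  if (!fs %in% c(500, 1000)) stopf("`fs` must be 500 or 1000 Hz")
  if (min(phase_durations) < 60 / hr_ramp[1]) {
    stopf("a phase is too short to hold one beat")
  }
  total <- sum(phase_durations)
  phases <- phase_annotation(phase_durations[1],
                             phase_durations[1] + phase_durations[2], total)
  if (is.null(lead_scales)) {
    lead_scales <- c(1, 0.85, 1.15, 0.75, 1.05, 0.9, 1.1, 0.8, 0.95, 1.2,
                     0.7, 1.25)[seq_len(n_leads)]
  }

  with_seed(seed, {
    hr_fun <- make_hr_fun(phases, hr_ramp)
    n <- round(total * fs)
    clean <- numeric(n + fs)  # slack for the last beat's tail
    r_times <- q_onsets <- j_points <- t_offsets <- numeric(0)
    cache <- new.env(parent = emptyenv())
    t_cur <- 0
    while (t_cur < total - 0.35) {
      rr <- max(0.3, min(2, 60 / hr_fun(t_cur)))
      ph <- phase_of(t_cur, phases)
      st <- st_params[[ph]]
      key <- sprintf("%d|%.0f", round(rr * 1000), st)
      tpl <- cache[[key]]
      if (is.null(tpl)) {
        tpl <- beat_template(round(rr, 3), st, fs, morphology)
        cache[[key]] <- tpl
      }
      i0 <- round(t_cur * fs)
      idx <- i0 + seq_along(tpl$waveform)
      idx <- idx[idx <= length(clean)]
      clean[idx] <- clean[idx] + tpl$waveform[seq_along(idx)]
      fid <- tpl$fiducials
      r_times <- c(r_times, t_cur + fid$r_peak)
      q_onsets <- c(q_onsets, t_cur + fid$q_onset)
      j_points <- c(j_points, t_cur + fid$j_point)
      t_offsets <- c(t_offsets, t_cur + fid$t_offset)
      t_cur <- t_cur + rr
    }
    clean <- clean[seq_len(n)]

    tt <- (seq_len(n) - 1) / fs
    sig <- matrix(0, n, n_leads)
    for (l in seq_len(n_leads)) {
      x <- lead_scales[l] * clean
      if (noise$wander > 0) {
        ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
        x <- x + noise$wander * (sin(2 * pi * 0.23 * tt + ph1) +
                                   0.6 * sin(2 * pi * 0.09 * tt + ph2))
      }
      if (noise$broadband > 0) x <- x + rnorm(n, sd = noise$broadband)
      if (noise$burst > 0) {
        n_burst <- rpois(1, total / 120)  # ~1 movement burst per 2 min
        for (b in seq_len(n_burst)) {
          s0 <- sample.int(n - 2 * fs, 1)
          win <- s0:(s0 + 2 * fs)
          x[win] <- x[win] + rnorm(length(win), sd = noise$burst)
        }
      }
      sig[, l] <- x
    }

    minutes <- seq(0, total - 60, by = 60)
    hr_profile <- vapply(minutes, function(m0) {
      sum(r_times >= m0 & r_times < m0 + 60)
    }, numeric(1))
    truth <- list(
      r_peak_times = r_times, q_onsets = q_onsets, j_points = j_points,
      t_offsets = t_offsets,
      st_offset_profile = lapply(st_params, function(s) s * lead_scales),
      hr_profile = hr_profile, lead_scales = lead_scales
    )
    new_stress_recording(sig, fs, paste0("L", seq_len(n_leads)), phases,
                         truth, patient_id)
  })
}

# Continuous heart-rate profile: flat at rest, linear ramp through stress,
# exponential decay back toward rest during recovery.
make_hr_fun <- function(phases, hr_ramp) {
  rest <- hr_ramp[1]; peak <- hr_ramp[2]
  function(t) {
    if (t < phases$pre_end) return(rest)
    if (t < phases$stress_end) {
      frac <- (t - phases$pre_end) / (phases$stress_end - phases$pre_end)
      return(rest + frac * (peak - rest))
    }
    tau <- (phases$total - phases$stress_end) / 3
    rest + (peak - rest) * exp(-(t - phases$stress_end) / tau)
  }
}
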