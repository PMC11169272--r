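#' Estimate the end of the stress phase from heart rate
#'
#' For recordings without phase annotations, computes the heart rate for each
#' full minute of the signal (from detected R peaks) and takes the end of the
#' minute with maximal heart rate as the end of the stress phase. Ties are
#' broken toward the earliest maximal minute. The pre-stress boundary is not
#' derivable from heart rate alone and defaults to a configured warm-up
#' length.
#'
#' @param recording A `carpe_recording`.
#' @param lead Lead index used for R-peak detection.
#' @param pre_end Warm-up boundary in seconds (default 60).
#' @return A `carpe_phases` annotation.
#' @export
estimate_stress_end <- function(recording, lead = 1, pre_end = 60) {
  fs <- recording$fs
  total <- nrow(recording$signals) / fs
  if (total < 180) stopf("recording must be at least 3 minutes long")
  peaks <- detect_r_peaks(recording$signals[, lead], fs)
  if (length(peaks) < 3) stopf("undetectable rhythm: too few R peaks")
  pt <- (peaks - 1) / fs
  minutes <- seq(0, floor(total / 60) - 1)
  hr <- vapply(minutes, function(m) sum(pt >= 60 * m & pt < 60 * (m + 1)),
               numeric(1))
  stress_end <- 60 * (minutes[which.max(hr)] + 1)
  if (stress_end >= total) stress_end <- total - 1
  if (stress_end <= pre_end) pre_end <- stress_end / 2
  phase_annotation(pre_end, stress_end, total)
}

#' Build 2-6-2 summary sequences from a stress-test recording
#'
#' Each sequence concatenates 2 s from the beginning of the examination,
#' a 6 s window sampled from the last 2 minutes of the stress phase, and a
#' 2 s window sampled from the last 3 minutes of the recovery phase, giving
#' a fixed 10 s (5000 samples at 500 Hz) input whose information content is
#' dominated by the stress phase. Up to `max_sequences` sequences are built
#' per recording by sampling the stress/recovery windows at different start
#' times (uniformly without replacement on a 0.5 s grid); the pre-stress
#' window is fixed. When fewer distinct placements exist, all distinct ones
#' are emitted.
#'
#' @param recording A `carpe_recording` (500 Hz).
#' @param annotation Optional `carpe_phases`; defaults to the recording's own.
#' @param max_sequences Cap on sequences per recording (default 20).
#' @param seed Integer seed for the window sampling.
#' @param lead Lead index to extract.
#' @return A list of `carpe_seq262` objects, each with fields `values`
#'   (5000 samples), `boundaries` (c(2 s, 8 s) boundaries as 0-based sample
#'   indices 1000 and 4000), `source_windows` (start times in seconds of the
#'   three windows), `lead_id`, and `patient_id`.
#' @export
build_sequences <- function(recording, annotation = NULL, max_sequences = 20,
                            seed = 1, lead = 1) {
  if (recording$fs != 500) stopf("build_sequences expects a 500 Hz recording")
  ann <- annotation %||% recording$phases
  fs <- recording$fs
  x <- recording$signals[, lead]

  stress_len <- ann$stress_end - ann$pre_end
  rec_len <- ann$total - ann$stress_end
  if (stress_len < 126) stopf("stress phase too short (need >= 2 min + 6 s)")
  if (rec_len < 2) stopf("recovery phase too short (need >= 2 s)")

  # eligible window-start grids (0.5 s steps)
  stress_lo <- max(ann$pre_end, ann$stress_end - 120)
  stress_starts <- seq(stress_lo, ann$stress_end - 6, by = 0.5)
  rec_lo <- max(ann$stress_end, ann$total - 180)
  rec_starts <- seq(rec_lo, ann$total - 2, by = 0.5)

  n_seq <- min(max_sequences, length(stress_starts), length(rec_starts))
  with_seed(seed, {
    s_pick <- sample(stress_starts, n_seq)
    r_pick <- sample(rec_starts, n_seq)
    purrr::map2(s_pick, r_pick, function(s0, r0) {
      seg <- function(t0, len) {
        i0 <- round(t0 * fs)
        x[(i0 + 1):(i0 + len * fs)]
      }
      structure(list(
        values = c(seg(0, 2), seg(s0, 6), seg(r0, 2)),
        boundaries = c(1000L, 4000L),
        source_windows = c(pre = 0, stress = s0, rec = r0),
        lead_id = recording$lead_names[lead],
        patient_id = recording$patient_id
      ), class = "carpe_seq262")
    })
  })
}

#' @export
print.carpe_seq262 <- function(x, ...) {
  cat(sprintf("<2-6-2 sequence> patient %s lead %s, windows pre=%.1fs stress=%.1fs rec=%.1fs\n",
              x$patient_id, x$lead_id, x$source_windows[1],
              x$source_windows[2], x$source_windows[3]))
  invisible(x)
}
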