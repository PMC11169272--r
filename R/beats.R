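#' Default beat morphology parameters
#'
#' Amplitudes are in microvolts, durations in seconds. The beat is a
#' sum-of-bump template: Gaussian P and T waves and a piecewise-linear QRS
#' complex. Q-wave onset, R peak and the J point sit at fixed offsets from
#' the beat start; the ST segment and T wave compress with shorter RR
#' intervals (rate-dependent QT shortening) while the PR interval stays
#' fixed so the isoelectric window before the Q wave remains flat at any
#' heart rate.
#'
#' @return Named list of morphology parameters.
#' @export
beat_morphology <- function() {
  list(
    p_center = 0.04, p_sigma = 0.015, p_amp = 100,
    q_onset = 0.16, q_amp = -120, r_amp = 1000, s_amp = -200,
    r_offset = 0.04, j_offset = 0.08,    # relative to q_onset
    st_len = 0.12, t_sigma = 0.04, t_amp = 300,
    rr_ref = 0.8
  )
}

# Rate-compression factor for the ST segment / T wave.
beat_compression <- function(rr) {
  # floor keeps the ST plateau >= 80 ms so the J+60 ms sample stays on it
  pmin(1, pmax(2 / 3, (rr - 0.29) / 0.32))
}

#' Generate one synthetic heartbeat with exact fiducials
#'
#' Builds a single-beat waveform containing a P wave, QRS complex and T wave.
#' The segment between the J point and T-wave onset is shifted by `st_offset`
#' relative to the PR-segment level (the isoelectric line), so programmed
#' ST-segment depression is exact by construction and can serve as ground
#' truth for the measurement chain.
#'
#' @param rr_interval RR interval in seconds, in `[0.3, 2]`.
#' @param st_offset ST-segment offset in microvolts (negative = depression).
#' @param fs Sampling rate in Hz, 500 or 1000.
#' @param morphology Morphology parameters, see [beat_morphology()].
#' @return A list with `waveform` (numeric vector of `round(rr_interval * fs)`
#'   samples, microvolts) and `fiducials` (named list of `q_onset`, `r_peak`,
#'   `j_point`, `t_onset`, `t_offset` times in seconds from beat start).
#' @examples
#' b <- generate_beat(0.8, st_offset = -100, fs = 500)
#' length(b$waveform)
#' @export
generate_beat <- function(rr_interval, st_offset = 0, fs = 500,
                          morphology = beat_morphology()) {
  if (!is.numeric(rr_interval) || length(rr_interval) != 1L ||
      rr_interval < 0.3 || rr_interval > 2.0) {
    stopf("`rr_interval` must be a single value in [0.3, 2] s (got %s)",
          format(rr_interval))
  }
  if (!fs %in% c(500, 1000)) stopf("`fs` must be 500 or 1000 Hz")
  m <- morphology
  tpl <- beat_template(rr_interval, st_offset, fs, m)
  n <- round(rr_interval * fs)
  w <- tpl$waveform
  if (length(w) < n) w <- c(w, rep(0, n - length(w))) else w <- w[seq_len(n)]
  list(waveform = w, fiducials = tpl$fiducials)
}

# Full-support template (may extend slightly past rr for fast beats);
# assemble_recording() overlap-adds these onto the global time axis.
beat_template <- function(rr, st_offset, fs, m) {
  cc <- beat_compression(rr)
  q_on <- m$q_onset
  r_pk <- q_on + m$r_offset
  j_pt <- q_on + m$j_offset
  st_len <- m$st_len * cc
  t_sig <- m$t_sigma * cc
  t_on <- j_pt + st_len
  t_c <- t_on + 2.5 * t_sig
  t_off <- t_c + 2.5 * t_sig

  n <- ceiling((max(rr, t_off) + 0.01) * fs)
  t <- (seq_len(n) - 1) / fs
  w <- m$p_amp * exp(-0.5 * ((t - m$p_center) / m$p_sigma)^2)

  # piecewise-linear QRS: 0 at q_onset -> Q dip -> R peak -> S dip -> st_offset at J
  qrs_t <- c(q_on, q_on + 0.01, r_pk, q_on + 0.06, j_pt)
  qrs_v <- c(0, m$q_amp, m$r_amp, m$s_amp, st_offset)
  in_qrs <- t >= q_on & t <= j_pt
  w[in_qrs] <- w[in_qrs] + approx(qrs_t, qrs_v, xout = t[in_qrs])$y

  # ST plateau at st_offset from J to T onset, linear return to 0 by T offset
  in_st <- t > j_pt & t <= t_on
  w[in_st] <- w[in_st] + st_offset
  in_fall <- t > t_on & t <= t_off
  w[in_fall] <- w[in_fall] + st_offset * (t_off - t[in_fall]) / (t_off - t_on)

  w <- w + m$t_amp * cc * exp(-0.5 * ((t - t_c) / t_sig)^2)

  list(waveform = w,
       fiducials = list(q_onset = q_on, r_peak = r_pk, j_point = j_pt,
                        t_onset = t_on, t_offset = t_off))
}
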