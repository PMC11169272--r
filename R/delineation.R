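#' Detect R peaks with a derivative-threshold detector
#'
#' Squares the smoothed derivative of the signal, thresholds it adaptively,
#' and enforces a 200 ms refractory window; the R peak is refined as the
#' absolute-amplitude maximum around each threshold crossing. Designed for
#' the package's own delineation chain; an external delineator can be
#' substituted anywhere a delineation map is consumed.
#'
#' @param x Numeric vector, one ECG lead in microvolts.
#' @param fs Sampling rate (Hz), 500 expected.
#' @return Integer vector of R-peak sample indices (1-based); empty if no
#'   peaks are found.
#' @export
detect_r_peaks <- function(x, fs = 500) {
  n <- length(x)
  if (n < 2 * fs) stopf("signal must be at least 2 s long")
  if (all(x == 0)) return(integer(0))
  d <- c(0, diff(x))
  e <- moving_average(d^2, odd_window(0.02 * fs))
  thr <- 0.3 * quantile(e, 0.99)
  if (thr <= 0) return(integer(0))
  above <- e > thr
  refractory <- round(0.2 * fs)
  half <- round(0.05 * fs)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j0 <- max(1L, i - half); j1 <- min(n, i + half)
      centred <- x[j0:j1] - median(x[j0:j1])
      p <- j0 + which.max(abs(centred)) - 1L
      peaks <- c(peaks, p)
      i <- max(i, p) + refractory
    } else i <- i + 1L
  }
  peaks
}

#' Delineate QRS landmarks around detected R peaks
#'
#' For each R peak, the Q-wave onset is located by a backward slope search
#' (first sample, scanning back from the peak, where the local derivative
#' magnitude falls below a fraction of the peak slope and stays small), and
#' the J point by the symmetric forward slope-flattening search. Beats whose
#' search windows cross the signal edge fail delineation and are flagged
#' invalid rather than erroring.
#'
#' @param x Numeric vector, one ECG lead (microvolts).
#' @param fs Sampling rate in Hz.
#' @param r_peaks Integer vector of R-peak sample indices.
#' @return A tibble (`DelineationMap`) with one row per beat: `r_peak`,
#'   `q_onset`, `j_point`, `t_offset` (sample indices) and `valid`.
#' @export
delineate <- function(x, fs = 500, r_peaks = detect_r_peaks(x, fs)) {
  if (length(r_peaks) == 0) stopf("`r_peaks` must be non-empty")
  win_q <- round(0.10 * fs)   # max Q-onset search distance
  win_j <- round(0.10 * fs)   # max J-point search distance
  # slope on a lightly smoothed copy so broadband noise does not defeat the
  # flatness test; landmark indices still refer to the raw signal
  xs <- moving_average(x, odd_window(0.012 * fs))
  d <- c(0, diff(xs)) * fs    # uV/s
  rows <- purrr::map_dfr(r_peaks, function(r) {
    bad <- tibble::tibble(r_peak = r, q_onset = NA_integer_,
                          j_point = NA_integer_, t_offset = NA_integer_,
                          valid = FALSE)
    if (r - win_q < 1 || r + win_j + round(0.06 * fs) + 1 > length(x)) return(bad)
    slope_ref <- max(abs(d[(r - win_q):(r + win_j)]))
    flat <- 0.04 * slope_ref
    q <- NA_integer_
    run <- 0L
    for (i in seq(r - round(0.01 * fs), r - win_q)) {
      if (abs(d[i]) < flat) { run <- run + 1L } else run <- 0L
      if (run >= 3L) { q <- i + 2L; break }
    }
    j <- NA_integer_
    run <- 0L
    for (i in seq(r + round(0.01 * fs), r + win_j)) {
      if (abs(d[i]) < flat) { run <- run + 1L } else run <- 0L
      if (run >= 3L) { j <- i - 2L; break }
    }
    if (is.na(q) || is.na(j) || !(q < r && r < j)) return(bad)
    t_off <- min(length(x), j + round(0.35 * fs))
    tibble::tibble(r_peak = r, q_onset = q, j_point = j,
                   t_offset = t_off, valid = TRUE)
  })
  rows
}
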