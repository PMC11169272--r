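#' Downsample an ECG signal to 500 Hz
#'
#' 500 Hz input is returned unchanged; 1000 Hz input is anti-alias filtered
#' (zero-phase 8th-order Butterworth low-pass at 200 Hz) and decimated by 2.
#'
#' @param x Numeric vector (one lead, microvolts) or matrix (samples x leads).
#' @param fs Sampling rate, 500 or 1000 Hz.
#' @return Signal at 500 Hz (same type as input).
#' @export
downsample_to_500 <- function(x, fs) {
  if (!fs %in% c(500, 1000)) stopf("`fs` must be 500 or 1000 Hz")
  if (fs == 500) return(x)
  dec1 <- function(v) {
    bf <- signal::butter(8, 200 / (fs / 2), type = "low")
    signal::filtfilt(bf, v)[seq(1, length(v), by = 2)]
  }
  if (is.matrix(x)) apply(x, 2, dec1) else dec1(x)
}

#' Apply one of the three preprocessing schemes
#'
#' Three schemes are supported, mirroring the grid evaluated during model
#' selection:
#' * `"none"` — identity.
#' * `"minimal"` — order-5 high-pass Butterworth at 0.5 Hz, then
#'   moving-average smoothing.
#' * `"thorough"` — 0.05-150 Hz band-pass (order 5), moving-median baseline
#'   subtraction, Savitzky-Golay smoothing, and winsorizing of spurious
#'   outliers.
#'
#' All filters are applied forward-backward (zero phase) so fiducial times
#' remain valid after preprocessing. Output length equals input length.
#'
#' @param x Numeric vector (microvolts) or samples-x-leads matrix.
#' @param fs Sampling rate in Hz.
#' @param scheme `"none"`, `"minimal"` or `"thorough"`.
#' @param params Optional overrides: `ma_window` (s, default 0.015),
#'   `median_window` (s, default 0.6), `sg_window` (s, default 0.025),
#'   `sg_order` (default 3), `winsor` (two percentiles, default
#'   `c(0.001, 0.999)`).
#' @return Preprocessed signal, same dimensions as the input.
#' @export
apply_scheme <- function(x, fs, scheme = c("none", "minimal", "thorough"),
                         params = list()) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(x)
  p <- modifyList(list(ma_window = 0.015, median_window = 0.6,
                       sg_window = 0.025, sg_order = 3,
                       winsor = c(0.001, 0.999)), params)
  f1 <- function(v) {
    if (length(v) < round(0.5 * fs)) stopf("signal too short to preprocess")
    if (scheme == "minimal") {
      bf <- signal::butter(5, 0.5 / (fs / 2), type = "high")
      # demean before high-passing: the DC step otherwise rings at the edges
      v <- signal::filtfilt(bf, v - mean(v))
      moving_average(v, odd_window(p$ma_window * fs))
    } else {
      # 0.05-150 Hz band as a cascade: a single transfer-function band-pass
      # with a 1e-4 normalised lower edge is numerically unstable, so the
      # band edges are applied as order-3 high-pass + order-5 low-pass
      hp <- signal::butter(3, 0.05 / (fs / 2), type = "high")
      lp <- signal::butter(5, min(150 / (fs / 2), 0.99), type = "low")
      v <- signal::filtfilt(lp, signal::filtfilt(hp, v - mean(v)))
      v <- v - running_median(v, odd_window(p$median_window * fs))
      v <- signal::sgolayfilt(v, p = p$sg_order, n = odd_window(p$sg_window * fs))
      lo <- quantile(v, p$winsor[1]); hi <- quantile(v, p$winsor[2])
      pmin(pmax(v, lo), hi)
    }
  }
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

odd_window <- function(w) {
  w <- max(3L, round(w))
  if (w %% 2 == 0) w + 1L else w
}

# centred moving average, edges padded by replication
moving_average <- function(v, w) {
  h <- (w - 1) %/% 2
  padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(h + 1):(h + length(v))]
}

# centred running median via stats::runmed (Tukey endrule keeps length)
running_median <- function(v, w) {
  stats::runmed(v, w, endrule = "median")
}
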