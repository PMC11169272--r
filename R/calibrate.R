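#' Calibrate raw risk scores on a held-aside calibration split
#'
#' Fits a monotone mapping from raw score to probability on the calibration
#' split only. Platt scaling (logistic regression on the logit of the score)
#' is the default; isotonic regression is available as an alternative. Both
#' mappings are monotone non-decreasing, so the rank order of scores — and
#' hence AUROC — is unchanged.
#'
#' @param scores Raw scores in `[0, 1]` to be calibrated.
#' @param cal_scores,cal_labels Scores and labels of the calibration split
#'   (both classes required).
#' @param method `"platt"` or `"isotonic"`.
#' @return Calibrated probabilities, same length as `scores`.
#' @export
calibrate_scores <- function(scores, cal_scores, cal_labels,
                             method = c("platt", "isotonic")) {
  method <- match.arg(method)
  cal_labels <- as.logical(cal_labels)
  if (length(unique(cal_labels)) < 2) {
    stopf("calibration split must contain both classes")
  }
  if (method == "platt") {
    z <- qlogis(pmin(pmax(cal_scores, 1e-6), 1 - 1e-6))
    fit <- suppressWarnings(glm(cal_labels ~ z, family = binomial()))
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope <= 0) {
      # degenerate fit: keep the identity rather than flip ranks
      return(scores)
    }
    zz <- qlogis(pmin(pmax(scores, 1e-6), 1 - 1e-6))
    unname(plogis(coef(fit)[1] + slope * zz))
  } else {
    o <- order(cal_scores)
    iso <- isoreg(cal_scores[o], as.numeric(cal_labels[o]))
    xk <- iso$x; yk <- iso$yf
    approx(xk, yk, xout = scores, rule = 2, ties = "ordered")$y
  }
}
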