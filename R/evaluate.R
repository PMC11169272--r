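#' Paired bootstrap comparison of prediction methods
#'
#' Pools per-patient predictions and resamples the same patient subset for
#' every method in each draw (80% of patients, 25 draws by default), so the
#' per-draw metric distributions are directly comparable across methods —
#' including the cardiologist, who scores each patient only once. Draws
#' that land on a single class are redrawn (and counted).
#'
#' @param predsets Tibble with one row per patient: a logical `label` column
#'   plus one numeric score column per method.
#' @param methods Character vector of score column names (default: all
#'   numeric columns except `label`).
#' @param draws Number of bootstrap draws.
#' @param frac Fraction of patients sampled per draw (without replacement).
#' @param seed Integer seed.
#' @return A `carpe_bootstrap`: tibble with columns `draw`, `method`,
#'   `auroc`, `auprc`, `brier`, plus attributes `draw_indices` and
#'   `redrawn`.
#' @export
paired_bootstrap <- function(predsets, methods = NULL, draws = 25, frac = 0.8,
                             seed = 1) {
  lab <- as.logical(predsets$label)
  if (length(unique(lab)) < 2) stopf("pooled predictions contain one class")
  if (is.null(methods)) {
    methods <- setdiff(names(predsets)[vapply(predsets, is.numeric, TRUE)],
                       c("label", "enrolment_order"))
  }
  n <- nrow(predsets)
  m <- max(2, round(frac * n))
  redrawn <- 0L
  with_seed(seed, {
    idx_list <- vector("list", draws)
    for (d in seq_len(draws)) {
      repeat {
        idx <- sample.int(n, m)
        if (length(unique(lab[idx])) == 2) break
        redrawn <- redrawn + 1L
      }
      idx_list[[d]] <- idx
    }
    res <- purrr::map_dfr(seq_len(draws), function(d) {
      idx <- idx_list[[d]]
      purrr::map_dfr(methods, function(mt) {
        s <- predsets[[mt]][idx]
        tibble::tibble(draw = d, method = mt,
                       auroc = metric_auroc(s, lab[idx]),
                       auprc = metric_auprc(s, lab[idx]),
                       brier = metric_brier(s, lab[idx]))
      })
    })
    structure(res, draw_indices = idx_list, redrawn = redrawn,
              class = c("carpe_bootstrap", class(res)))
  })
}

#' @export
tidy.carpe_bootstrap <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method),
    dplyr::across(c("auroc", "auprc", "brier"),
                  list(mean = mean, sd = sd), .names = "{.col}_{.fn}"),
    .groups = "drop")
}

#' Net benefit of a classification strategy at a threshold probability
#'
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)`, where patients with
#' `score >= pt` are classified positive. Net benefit puts the benefit of a
#' true positive and the harm of an unnecessary intervention on one scale:
#' a strategy with higher net benefit finds more true positives without a
#' higher false-positive rate at that threshold.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Logical labels.
#' @param pt Threshold probability in (0, 1) (vectorised).
#' @return Net benefit per `pt`.
#' @export
net_benefit <- function(scores, labels, pt) {
  if (any(pt <= 0 | pt >= 1)) stopf("`pt` must lie strictly inside (0, 1)")
  labels <- as.logical(labels)
  n <- length(labels)
  vapply(pt, function(p) {
    pos <- scores >= p
    sum(pos & labels) / n - sum(pos & !labels) / n * p / (1 - p)
  }, numeric(1))
}

#' Decision-curve analysis
#'
#' Computes the net-benefit curve of a model over a threshold grid, together
#' with the treat-all and treat-none reference strategies and (optionally)
#' a comparator strategy such as the cardiologist.
#'
#' @param scores,labels Model scores and labels.
#' @param pt_grid Threshold probabilities.
#' @param reference Optional comparator score vector.
#' @return A `carpe_decision_curve` tibble with columns `pt`, `nb_model`,
#'   `nb_all`, `nb_none`, and `nb_reference`/`avoided_per_100` when a
#'   comparator is given.
#' @export
decision_curve <- function(scores, labels, pt_grid = seq(0.01, 0.5, by = 0.01),
                           reference = NULL) {
  labels <- as.logical(labels)
  prev <- mean(labels)
  out <- tibble::tibble(
    pt = pt_grid,
    nb_model = net_benefit(scores, labels, pt_grid),
    nb_all = prev - (1 - prev) * pt_grid / (1 - pt_grid),
    nb_none = 0
  )
  if (!is.null(reference)) {
    out$nb_reference <- net_benefit(reference, labels, pt_grid)
    out$avoided_per_100 <- avoided_tests_per_100(out$nb_model,
                                                 out$nb_reference, pt_grid)
  }
  structure(out, class = c("carpe_decision_curve", class(out)))
}

#' Interventions avoided per 100 patients relative to a comparator
#'
#' The standard net-reduction-in-interventions transform of a net-benefit
#' difference: `(nb_model - nb_reference) * (1 - pt) / pt * 100`. Here the
#' intervention is a myocardial perfusion scan and the comparator is
#' typically the cardiologist's strategy.
#'
#' @param nb_model,nb_reference Net benefits at `pt`.
#' @param pt Threshold probability in (0, 1).
#' @return Avoided interventions per 100 patients (vectorised).
#' @export
avoided_tests_per_100 <- function(nb_model, nb_reference, pt) {
  if (any(pt <= 0 | pt >= 1)) stopf("`pt` must lie strictly inside (0, 1)")
  (nb_model - nb_reference) * (1 - pt) / pt * 100
}

#' Rule-out table row at a probability cutoff
#'
#' Patients with `score < cutoff` are ruled out (no imaging); `score >=
#' cutoff` counts as test-positive for sensitivity/NPV. Reports the
#' percentage below the cutoff, sensitivity, NPV (NA with zero patients
#' below the cutoff), and — given a comparator — imaging avoided per 100
#' patients with a bootstrap 95% CI.
#'
#' @param scores,labels Scores and labels.
#' @param cutoff Rule-out threshold (guideline values: 0.05, 0.10, 0.15).
#' @param reference Optional comparator scores (e.g. cardiologist).
#' @param boot_draws,boot_frac,seed Bootstrap settings for the CI.
#' @return One-row tibble (`RuleOutRow`).
#' @export
rule_out_metrics <- function(scores, labels, cutoff, reference = NULL,
                             boot_draws = 25, boot_frac = 0.8, seed = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stopf("labels are degenerate")
  below <- scores < cutoff
  sens <- if (any(labels)) sum(!below & labels) / sum(labels) else NA_real_
  npv <- if (any(below)) sum(below & !labels) / sum(below) else NA_real_
  row <- tibble::tibble(
    cutoff = cutoff, pct_below = 100 * mean(below), sensitivity = sens,
    npv = npv, avoided_pct = NA_real_, avoided_lo = NA_real_,
    avoided_hi = NA_real_
  )
  if (!is.null(reference) && cutoff > 0 && cutoff < 1) {
    av <- function(idx) {
      avoided_tests_per_100(net_benefit(scores[idx], labels[idx], cutoff),
                            net_benefit(reference[idx], labels[idx], cutoff),
                            cutoff)
    }
    row$avoided_pct <- av(seq_along(scores))
    n <- length(scores); m <- max(2, round(boot_frac * n))
    draws <- with_seed(seed, {
      vapply(seq_len(boot_draws), function(d) {
        repeat {
          idx <- sample.int(n, m)
          if (length(unique(labels[idx])) == 2) return(av(idx))
        }
      }, numeric(1))
    })
    row$avoided_lo <- quantile(draws, 0.025)
    row$avoided_hi <- quantile(draws, 0.975)
  }
  row
}

#' Calibration report: reliability bins and Brier score
#'
#' @param scores Probabilities in `[0, 1]`.
#' @param labels Logical labels.
#' @param n_bins Number of equal-width bins (default 10).
#' @return A `carpe_calibration` list with `bins` (tibble: `bin_mid`,
#'   `mean_pred`, `obs_freq`, `n`) and `brier`.
#' @export
calibration_report <- function(scores, labels, n_bins = 10) {
  labels <- as.numeric(as.logical(labels))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(scores, edges, rightmost.closed = TRUE), 1),
              n_bins)
  bins <- purrr::map_dfr(seq_len(n_bins), function(b) {
    sel <- bin == b
    tibble::tibble(bin_mid = (edges[b] + edges[b + 1]) / 2,
                   mean_pred = if (any(sel)) mean(scores[sel]) else NA_real_,
                   obs_freq = if (any(sel)) mean(labels[sel]) else NA_real_,
                   n = sum(sel))
  })
  structure(list(bins = bins, brier = metric_brier(scores, labels)),
            class = "carpe_calibration")
}

#' @export
print.carpe_calibration <- function(x, ...) {
  cat(sprintf("<calibration> Brier %.4f over %d bins\n", x$brier,
              nrow(x$bins)))
  invisible(x)
}
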