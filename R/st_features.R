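#' ST-segment depression features for one 2-6-2 sequence
#'
#' For each of the three sub-segments (pre-stress, stress, recovery) the
#' isoelectric line is the mean, over valid beats, of the mean of the last
#' `l_pr` milliseconds preceding the Q-wave onset; the ST amplitude is the
#' mean over valid beats of the single sample 60 ms after the J point.
#' Depression is isoelectric minus ST amplitude, so deeper ST below the
#' isoelectric line gives a larger positive depression. Deltas are computed
#' against the pre-stress phase. Beats spanning a concatenation boundary are
#' flagged invalid (the joins are artefacts, not physiology).
#'
#' @param seq A `carpe_seq262`.
#' @param dmap Optional `DelineationMap` for the sequence (computed if
#'   missing).
#' @param l_pr Isoelectric window length in milliseconds (default 80).
#' @param fs Sampling rate (500 Hz).
#' @return A one-row tibble with `st_pre`, `st_stress`, `st_rec` (microvolts),
#'   `delta_stress`, `delta_rec`, `l_pr`, `n_beats`, and `valid` (FALSE when
#'   any phase lacks a valid beat).
#' @export
st_depression_sequence <- function(seq, dmap = NULL, l_pr = 80, fs = 500) {
  x <- seq$values
  if (is.null(dmap)) dmap <- delineate(x, fs)
  b0 <- seq$boundaries  # 0-based: 1000, 4000
  seg_of <- function(i) {
    ifelse(i <= b0[1], "pre", ifelse(i <= b0[2], "stress", "rec"))
  }
  st_sample <- round(0.060 * fs)
  w <- round(l_pr / 1000 * fs)
  d <- dplyr::mutate(dmap,
    seg_q = seg_of(.data$q_onset), seg_j = seg_of(.data$j_point + st_sample),
    valid = .data$valid & !is.na(.data$q_onset) &
      .data$q_onset - w >= 1 & .data$j_point + st_sample <= length(x) &
      .data$seg_q == .data$seg_j
  )
  phase_stat <- function(ph) {
    dd <- d[d$valid & d$seg_q == ph, ]
    if (nrow(dd) == 0) return(c(NA_real_, 0))
    iso <- mean(vapply(dd$q_onset, function(q) mean(x[(q - w):(q - 1)]),
                       numeric(1)))
    st <- mean(x[dd$j_point + st_sample])
    c(iso - st, nrow(dd))
  }
  pre <- phase_stat("pre"); strs <- phase_stat("stress"); rec <- phase_stat("rec")
  tibble::tibble(
    patient_id = seq$patient_id, lead_id = seq$lead_id,
    st_pre = pre[1], st_stress = strs[1], st_rec = rec[1],
    delta_stress = strs[1] - pre[1], delta_rec = rec[1] - pre[1],
    l_pr = l_pr, n_beats = pre[2] + strs[2] + rec[2],
    valid = !anyNA(c(pre[1], strs[1], rec[1]))
  )
}

#' Aggregate per-sequence ST deltas to one patient-level value
#'
#' @param deltas Numeric vector of per-sequence deltas (microvolts).
#' @param method One of `"mean"`, `"median"`, `"min"`, `"max"`.
#' @return Scalar aggregate in microvolts.
#' @export
aggregate_patient <- function(deltas, method = c("mean", "median", "min", "max")) {
  method <- match.arg(method)
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) == 0) stopf("no valid sequences to aggregate")
  switch(method, mean = mean(deltas), median = median(deltas),
         min = min(deltas), max = max(deltas))
}

#' Per-patient ST-depression features for a cohort
#'
#' Runs the full measurement chain — 2-6-2 construction, delineation,
#' per-sequence depression, patient-level aggregation — over a cohort with
#' recordings.
#'
#' @param cohort A `carpe_cohort` with recordings.
#' @param l_pr Isoelectric window (ms).
#' @param method Aggregation method, see [aggregate_patient()].
#' @param which Which delta to aggregate: `"delta_stress"` or `"delta_rec"`.
#' @param max_sequences,seed,lead Passed to [build_sequences()].
#' @param scheme Preprocessing scheme applied to each recording.
#' @return Tibble with one row per patient: `patient_id`, `st_score`
#'   (microvolts, the aggregated delta), `n_sequences`, and `fcad`.
#' @export
st_features_cohort <- function(cohort, l_pr = 80, method = "mean",
                               which = c("delta_stress", "delta_rec"),
                               max_sequences = 20, seed = 1, lead = 1,
                               scheme = "none") {
  which <- match.arg(which)
  if (is.null(cohort$recordings)) stopf("cohort has no recordings")
  purrr::imap_dfr(cohort$recordings, function(rec, id) {
    if (scheme != "none") {
      rec$signals <- apply_scheme(rec$signals, rec$fs, scheme)
    }
    seqs <- build_sequences(rec, max_sequences = max_sequences,
                            seed = seed, lead = lead)
    feats <- purrr::map_dfr(seqs, st_depression_sequence, l_pr = l_pr)
    ok <- feats$valid
    score <- if (any(ok)) aggregate_patient(feats[[which]][ok], method) else NA_real_
    tibble::tibble(patient_id = id, st_score = score, n_sequences = sum(ok),
                   fcad = cohort$patients$fcad[cohort$patients$patient_id == id])
  })
}

#' Grid-select ST-baseline parameters by validation AUPRC
#'
#' Evaluates every combination of isoelectric window length, aggregation
#' method, delta type and lead on a labelled cohort, using the aggregated
#' delta as a monotone risk score, separately per stress-type stratum.
#' Ties are broken by first-in-grid order.
#'
#' @param cohort A `carpe_cohort` with recordings.
#' @param l_pr_grid Isoelectric window lengths (ms).
#' @param methods Aggregation methods.
#' @param which_grid Delta types.
#' @param leads Lead indices.
#' @param stratum Optional stress-type value to restrict to.
#' @param max_sequences,seed Passed through.
#' @return List with `best` (one-row tibble of the winning parameters) and
#'   `grid` (full score table, one row per configuration).
#' @export
select_st_params <- function(cohort, l_pr_grid = c(40, 60, 80),
                             methods = c("mean", "median", "min", "max"),
                             which_grid = c("delta_stress", "delta_rec"),
                             leads = 1, stratum = NULL,
                             max_sequences = 10, seed = 1) {
  patients <- cohort$patients
  if (!is.null(stratum)) {
    keep <- patients$stress_type == stratum
    if (length(unique(patients$fcad[keep])) < 2) {
      stopf("stratum '%s' does not contain both classes", stratum)
    }
  } else keep <- rep(TRUE, nrow(patients))
  # delineation is shared across (method, which) and across l_pr values,
  # so compute the per-sequence table once per (lead, l_pr)
  per_seq <- purrr::map_dfr(leads, function(ld) {
    purrr::imap_dfr(cohort$recordings, function(rec, id) {
      seqs <- build_sequences(rec, max_sequences = max_sequences,
                              seed = seed, lead = ld)
      purrr::map_dfr(seqs, function(s) {
        dmap <- delineate(s$values, rec$fs)
        purrr::map_dfr(l_pr_grid, function(lp) {
          dplyr::mutate(st_depression_sequence(s, dmap, l_pr = lp), lead = ld)
        })
      })
    })
  })
  grid <- tidyr::expand_grid(l_pr = l_pr_grid, method = methods,
                             which = which_grid, lead = leads)
  lab <- patients$fcad[keep]
  ids <- patients$patient_id[keep]
  grid$auprc <- purrr::pmap_dbl(grid, function(l_pr, method, which, lead) {
    tab <- per_seq[per_seq$l_pr == l_pr & per_seq$lead == lead & per_seq$valid, ]
    score <- vapply(ids, function(id) {
      v <- tab[[which]][tab$patient_id == id]
      if (length(v) == 0) NA_real_ else aggregate_patient(v, method)
    }, numeric(1))
    ok <- !is.na(score)
    metric_auprc(score[ok], lab[ok])
  })
  list(best = grid[which.max(grid$auprc), ], grid = grid)
}
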