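#' Additive feature attributions by permutation Shapley sampling
#'
#' Background-referenced additive attributions: for each sampled permutation
#' and background row, features are switched one by one from the background
#' value to the instance value and the marginal prediction changes are
#' accumulated. The telescoping sum makes the attribution exactly additive:
#' `baseline + sum(attributions) = f(instance)` up to float error, where
#' `baseline` is the mean prediction over the background sample. With
#' `groups`, columns are switched jointly as one player and the player's
#' attribution is shared equally among its columns, preserving additivity.
#' The estimator is backend-agnostic: any vectorised prediction function
#' works, so a kernel or model-specific explainer can be swapped in behind
#' the same contract.
#'
#' @param f Prediction function taking a numeric matrix (rows = instances)
#'   and returning a numeric vector.
#' @param x Numeric vector, the instance to explain.
#' @param background Numeric matrix of background rows (columns as `x`).
#' @param groups Optional integer vector (length = `length(x)`) assigning
#'   each column to a player.
#' @param n_perm Number of sampled permutations.
#' @param seed Integer seed.
#' @return List with `attributions` (per column of `x`), `baseline`, and
#'   `prediction`.
#' @export
attribute <- function(f, x, background, groups = NULL, n_perm = 10, seed = 1) {
  p <- length(x)
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  if (ncol(background) != p) stopf("background and instance widths differ")
  if (is.null(groups)) groups <- seq_len(p)
  players <- unique(groups)
  np <- length(players)
  phi <- numeric(np)
  nb <- nrow(background)
  with_seed(seed, {
    for (perm in seq_len(n_perm)) {
      ord <- sample(players)
      for (b in seq_len(nb)) {
        # rows: background with progressively more players set to x
        mat <- matrix(rep(background[b, ], np + 1), nrow = np + 1, byrow = TRUE)
        cur <- background[b, ]
        for (j in seq_len(np)) {
          cur[groups == ord[j]] <- x[groups == ord[j]]
          mat[j + 1, ] <- cur
        }
        preds <- f(mat)
        contrib <- diff(preds)
        phi[match(ord, players)] <- phi[match(ord, players)] + contrib
      }
    }
  })
  phi <- phi / (n_perm * nb)
  attributions <- numeric(p)
  for (j in seq_len(np)) {
    cols <- which(groups == players[j])
    attributions[cols] <- phi[j] / length(cols)
  }
  names(attributions) <- names(x)
  baseline <- mean(f(background))
  list(attributions = attributions, baseline = baseline,
       prediction = unname(f(matrix(x, nrow = 1))))
}

#' Explain one patient's multi-task network prediction
#'
#' Attributes the main-head probability over the 2-6-2 ECG sequence and the
#' eight clinical variables. ECG timepoints are grouped into fixed-width
#' windows (players); a window's attribution is spread uniformly over its
#' samples, so per-timepoint values still sum to the window's contribution
#' and totals are conserved.
#'
#' @param model A `carpe_mtl`.
#' @param seq A `carpe_seq262`.
#' @param clinical One-row patient tibble.
#' @param background An `mtl_data` background sample (a handful of training
#'   sequences).
#' @param window ECG window width in samples (default 250).
#' @param n_perm,seed Passed to [attribute()].
#' @return List with `ecg` (per-timepoint attributions, length 5000),
#'   `clinical` (named length-8 vector), `baseline`, `prediction`.
#' @export
attribute_mtl <- function(model, seq, clinical, background, window = 250,
                          n_perm = 5, seed = 1) {
  n_ecg <- 5000
  x <- c(seq$values, clinical_vector(clinical))
  nb <- dim(background$x)[3]
  bg <- t(vapply(seq_len(nb), function(i) {
    c(background$x[, 1, i], background$clin[, i])
  }, numeric(n_ecg + 8)))
  spec <- model$spec
  f <- function(mat) {
    m <- nrow(mat)
    xa <- array(t(mat[, seq_len(n_ecg), drop = FALSE]), dim = c(n_ecg, 1, m))
    cl <- (t(mat[, (n_ecg + 1):(n_ecg + 8), drop = FALSE]) - model$clin_center) /
      model$clin_scale
    mtl_forward(model$params, spec, xa * model$input_scale, cl,
                feat_mu = model$feat_mu)$outputs$fcad
  }
  groups <- c(rep(seq_len(ceiling(n_ecg / window)), each = window)[seq_len(n_ecg)],
              ceiling(n_ecg / window) + seq_len(8))
  res <- attribute(f, x, bg, groups = groups, n_perm = n_perm, seed = seed)
  list(ecg = unname(res$attributions[seq_len(n_ecg)]),
       clinical = stats::setNames(res$attributions[(n_ecg + 1):(n_ecg + 8)],
                                  names(clinical_vector(clinical))),
       baseline = res$baseline, prediction = res$prediction)
}

#' Sum per-timepoint attributions over ECG segments
#'
#' For each delineated beat, sums the per-timepoint attribution over the P
#' wave, PR segment, QRS complex, ST segment and T wave, and tags the beat
#' with its stress phase (pre / stress / recovery from the 2-6-2
#' boundaries). Timepoints not assigned to any beat segment accumulate in
#' an `other` bucket so segment sums conserve the total.
#'
#' @param per_timepoint Numeric vector of attributions (length 5000).
#' @param dmap Delineation map of the sequence (see [delineate()]).
#' @param boundaries 0-based sub-segment boundaries, default `c(1000, 4000)`.
#' @param fs Sampling rate.
#' @return A `carpe_segment_attr` list: `table` (tibble `beat`, `phase`,
#'   `segment`, `value`, `start`, `end`), `other`, `total`.
#' @export
aggregate_segments <- function(per_timepoint, dmap, boundaries = c(1000L, 4000L),
                               fs = 500) {
  if (is.null(dmap) || nrow(dmap) == 0) stopf("delineation map is required")
  n <- length(per_timepoint)
  assigned <- logical(n)
  phase_of_idx <- function(i) {
    ifelse(i <= boundaries[1], "pre", ifelse(i <= boundaries[2], "stress", "rec"))
  }
  rows <- list()
  valid <- dmap[dmap$valid, ]
  for (bi in seq_len(nrow(valid))) {
    q <- valid$q_onset[bi]; j <- valid$j_point[bi]
    segs <- list(
      p_wave = c(q - round(0.14 * fs), q - round(0.08 * fs) - 1),
      pr_segment = c(q - round(0.08 * fs), q - 1),
      qrs = c(q, j - 1),
      st_segment = c(j, j + round(0.12 * fs) - 1),
      t_wave = c(j + round(0.12 * fs), valid$t_offset[bi])
    )
    for (sn in names(segs)) {
      lo <- max(1L, segs[[sn]][1]); hi <- min(n, segs[[sn]][2])
      if (lo > hi) next
      idx <- lo:hi
      idx <- idx[!assigned[idx]]
      if (length(idx) == 0) next
      assigned[idx] <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        beat = bi, phase = phase_of_idx(valid$r_peak[bi]), segment = sn,
        value = sum(per_timepoint[idx]), start = min(idx), end = max(idx))
    }
  }
  table <- dplyr::bind_rows(rows)
  other <- sum(per_timepoint[!assigned])
  structure(list(table = table, other = other,
                 total = sum(per_timepoint)),
            class = "carpe_segment_attr")
}

#' Extract salient ECG waves by attribution-threshold rules
#'
#' Returns full waves (P onset to T offset) for beats whose QRS attribution
#' is at most `qrs_max` (patterns that push toward absence of disease, in
#' low-probability patients) or whose ST-segment attribution is at least
#' `st_min` (patterns pushing toward presence, in high-probability
#' patients). The analysis is restricted by the predicted-probability band:
#' the QRS rule applies below `band[1]`, the ST rule above `band[2]`.
#'
#' @param seq A `carpe_seq262`.
#' @param seg_attr A `carpe_segment_attr` for the sequence.
#' @param dmap The sequence's delineation map.
#' @param score The patient's predicted probability.
#' @param rules List with `qrs_max` (default -0.25), `st_min` (default
#'   0.25), `band` (default `c(0.15, 0.85)`).
#' @param fs Sampling rate.
#' @return Tibble of extracted waves: `beat`, `rule`, `phase`, `start`,
#'   `end` (sample indices) and `wave` (list column of values); empty when
#'   nothing passes.
#' @export
extract_salient_waves <- function(seq, seg_attr, dmap, score,
                                  rules = list(qrs_max = -0.25, st_min = 0.25,
                                               band = c(0.15, 0.85)),
                                  fs = 500) {
  tab <- seg_attr$table
  empty <- tibble::tibble(beat = integer(0), rule = character(0),
                          phase = character(0), start = integer(0),
                          end = integer(0), wave = list())
  picks <- NULL
  if (score < rules$band[1]) {
    picks <- tab[tab$segment == "qrs" & tab$value <= rules$qrs_max, ]
    picks$rule <- "qrs_low"
  } else if (score > rules$band[2]) {
    picks <- tab[tab$segment == "st_segment" & tab$value >= rules$st_min, ]
    picks$rule <- "st_high"
  }
  if (is.null(picks) || nrow(picks) == 0) return(empty)
  valid <- dmap[dmap$valid, ]
  seg_edges <- c(0L, seq$boundaries, length(seq$values))
  purrr::map_dfr(seq_len(nrow(picks)), function(i) {
    bi <- picks$beat[i]
    q <- valid$q_onset[bi]
    start <- max(1L, q - round(0.14 * fs))
    end <- min(length(seq$values), valid$t_offset[bi])
    # keep the wave inside one 2-6-2 sub-segment
    seg_id <- findInterval(valid$r_peak[bi] - 1L, seg_edges,
                           rightmost.closed = TRUE)
    start <- max(start, seg_edges[seg_id] + 1L)
    end <- min(end, seg_edges[seg_id + 1])
    tibble::tibble(beat = bi, rule = picks$rule[i], phase = picks$phase[i],
                   start = start, end = end,
                   wave = list(seq$values[start:end]))
  })
}
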