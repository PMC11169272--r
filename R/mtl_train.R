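#' Build a training dataset of 2-6-2 sequences from a cohort
#'
#' Extracts up to `max_sequences` 2-6-2 sequences per patient, stacks them
#' into an array, and attaches per-sequence targets (the patient's fCAD
#' label, perfusion scores and pharmacological-support indicator) together
#' with the eight clinical variables.
#'
#' @param cohort A `carpe_cohort` with recordings.
#' @param max_sequences Sequences per patient.
#' @param seed Window-sampling seed.
#' @param lead Lead index (or vector of indices for a multi-channel input).
#' @param scheme Preprocessing scheme applied to each recording.
#' @param patient_ids Optional subset of patients.
#' @return An `mtl_data` list: `x` (5000 x leads x N array, microvolts),
#'   `clin` (8 x N matrix), `targets` (list of per-sequence vectors),
#'   `patient_id` (length N).
#' @export
mtl_dataset <- function(cohort, max_sequences = 10, seed = 1, lead = 1,
                        scheme = "none", patient_ids = NULL) {
  if (is.null(cohort$recordings)) stopf("cohort has no recordings")
  pts <- cohort$patients
  ids <- patient_ids %||% pts$patient_id
  xs <- list(); clin <- list(); tg <- list(); pid <- character(0)
  for (id in ids) {
    rec <- cohort$recordings[[id]]
    if (scheme != "none") rec$signals <- apply_scheme(rec$signals, rec$fs, scheme)
    seqs <- build_sequences(rec, max_sequences = max_sequences,
                            seed = seed, lead = lead[1])
    p <- pts[pts$patient_id == id, ]
    for (s in seqs) {
      mat <- matrix(s$values, ncol = 1)
      if (length(lead) > 1) {
        # same source windows, other leads
        fs <- rec$fs
        extra <- lapply(lead[-1], function(ld) {
          v <- rec$signals[, ld]
          seg <- function(t0, len) v[(round(t0 * fs) + 1):(round(t0 * fs) + len * fs)]
          c(seg(0, 2), seg(s$source_windows[["stress"]], 6),
            seg(s$source_windows[["rec"]], 2))
        })
        mat <- cbind(mat, do.call(cbind, extra))
      }
      xs[[length(xs) + 1]] <- mat
      clin[[length(clin) + 1]] <- clinical_vector(p)
      tg[[length(tg) + 1]] <- c(fcad = as.numeric(p$fcad), sss = p$sss,
                                srs = p$srs,
                                pharm = as.numeric(p$stress_type != "exercise_only"))
      pid <- c(pid, id)
    }
  }
  n <- length(xs)
  x <- array(0, dim = c(5000, length(lead), n))
  for (i in seq_len(n)) x[, , i] <- xs[[i]]
  targets <- do.call(rbind, tg)
  structure(list(
    x = x, clin = do.call(cbind, clin),
    targets = list(fcad = targets[, "fcad"], sss = targets[, "sss"],
                   srs = targets[, "srs"], pharm = targets[, "pharm"]),
    patient_id = pid
  ), class = "mtl_data")
}

# The eight clinical variables, in fixed order.
clinical_vector <- function(p) {
  c(age = p$age, weight = p$weight, sex = as.numeric(p$sex == "male"),
    height = p$height, hr_rest = p$hr_rest, sbp = p$sbp, dbp = p$dbp,
    cad_history = as.numeric(p$cad_history))
}

#' Train the multi-task ECG network
#'
#' Mini-batch Adam on the weighted multi-task loss. Initialisation and data
#' order are fixed by `config$seed`, so training is deterministic. ECG input
#' is scaled to millivolts; clinical variables and the two perfusion-score
#' targets are standardised with training-set statistics stored in the
#' model.
#'
#' @param data An [mtl_dataset()].
#' @param config An [mtl_config()].
#' @param quiet Suppress the per-epoch log line.
#' @return A fitted `carpe_mtl` model.
#' @export
train_mtl <- function(data, config = mtl_config(), quiet = TRUE) {
  validate_mtl_config(config)
  if (length(unique(data$targets$fcad)) < 2) stopf("training data has one class")
  spec <- build_mtl(config, n_leads = dim(data$x)[2])
  clin_center <- rowMeans(data$clin)
  clin_scale <- apply(data$clin, 1, sd)
  clin_scale[clin_scale < 1e-8] <- 1
  reg_stats <- lapply(c(sss = "sss", srs = "srs"), function(k) {
    c(mean = mean(data$targets[[k]]), sd = max(sd(data$targets[[k]]), 1e-8))
  })
  clin <- (data$clin - clin_center) / clin_scale
  x <- data$x / 1000
  tg <- list(
    fcad = data$targets$fcad,
    sss = (data$targets$sss - reg_stats$sss["mean"]) / reg_stats$sss["sd"],
    srs = (data$targets$srs - reg_stats$srs["mean"]) / reg_stats$srs["sd"],
    pharm = data$targets$pharm
  )
  n <- dim(x)[3]
  params <- mtl_init(spec, config$seed)
  opt <- adam_new(params)
  w <- config$task_weights
  history <- numeric(0)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batch <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        xb <- x[, , idx, drop = FALSE]
        cb <- clin[, idx, drop = FALSE]
        tb <- lapply(tg, `[`, idx)
        fwd <- mtl_forward(params, spec, xb, cb, keep_cache = TRUE)
        loss <- mtl_loss(fwd$outputs, tb, w)
        if (!is.finite(loss)) {
          stopf("training diverged (non-finite loss) at lr=%g weights=%s",
                config$lr, paste(w, collapse = ","))
        }
        grads <- mtl_backward(params, spec, fwd, head_grads(fwd, tb, w))
        params <- adam_step(opt, params, grads, config$lr)
        ep_loss <- ep_loss + loss; n_batch <- n_batch + 1
      }
      history <- c(history, ep_loss / n_batch)
      if (!quiet) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / n_batch))
    }
  })
  # training-set means of the layer-normalised features with final weights;
  # used to centre the representation at inference
  feat_sum <- 0
  for (b0 in seq(1, n, by = 256)) {
    idx <- b0:min(b0 + 255, n)
    fwd <- mtl_forward(params, spec, x[, , idx, drop = FALSE],
                       clin[, idx, drop = FALSE], keep_cache = TRUE,
                       feat_mu = rep(0, spec$feat_dim))
    feat_sum <- feat_sum + rowSums(fwd$cache$feat_ln)
  }
  structure(list(params = params, spec = spec, config = config,
                 clin_center = clin_center, clin_scale = clin_scale,
                 reg_stats = reg_stats, input_scale = 1 / 1000,
                 feat_mu = feat_sum / n, history = history),
            class = "carpe_mtl")
}

#' @export
print.carpe_mtl <- function(x, ...) {
  cat(sprintf("<multi-task ECG network> %d blocks x %d channels, %d epochs, final loss %.4f\n",
              x$spec$n_blocks, x$spec$channels, length(x$history),
              tail(x$history, 1)))
  invisible(x)
}

adam_new <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e$t <- 0
  e
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

#' Predict per-sequence scores with a fitted multi-task network
#'
#' @param model A `carpe_mtl`.
#' @param data An `mtl_data`.
#' @return Tibble with one row per sequence: `patient_id`, `p_fcad`, `sss`,
#'   `srs`, `p_pharm` (regression heads are de-standardised).
#' @export
mtl_predict <- function(model, data) {
  n <- dim(data$x)[3]
  clin <- (data$clin - model$clin_center) / model$clin_scale
  out <- list(fcad = numeric(n), sss = numeric(n), srs = numeric(n),
              pharm = numeric(n))
  for (b0 in seq(1, n, by = 256)) {
    idx <- b0:min(b0 + 255, n)
    fwd <- mtl_forward(model$params, model$spec,
                       data$x[, , idx, drop = FALSE] * model$input_scale,
                       clin[, idx, drop = FALSE], feat_mu = model$feat_mu)
    out$fcad[idx] <- fwd$outputs$fcad
    out$sss[idx] <- fwd$outputs$sss
    out$srs[idx] <- fwd$outputs$srs
    out$pharm[idx] <- fwd$outputs$pharm
  }
  tibble::tibble(
    patient_id = data$patient_id,
    p_fcad = out$fcad,
    sss = out$sss * model$reg_stats$sss["sd"] + model$reg_stats$sss["mean"],
    srs = out$srs * model$reg_stats$srs["sd"] + model$reg_stats$srs["mean"],
    p_pharm = out$pharm
  )
}

#' Per-patient fCAD probability: mean over 2-6-2 sequences
#'
#' Predictions of the main task are averaged over all of a patient's 2-6-2
#' sequences; the result is invariant to sequence order.
#'
#' @param model A `carpe_mtl`.
#' @param sequences List of `carpe_seq262` for one patient (non-empty).
#' @param clinical One-row patient tibble carrying the eight clinical
#'   variables.
#' @return Scalar probability.
#' @export
predict_patient <- function(model, sequences, clinical) {
  if (length(sequences) == 0) stopf("at least one sequence is required")
  n <- length(sequences)
  x <- array(0, dim = c(5000, model$spec$n_leads, n))
  for (i in seq_len(n)) x[, 1, i] <- sequences[[i]]$values
  data <- structure(list(
    x = x, clin = matrix(rep(clinical_vector(clinical), n), ncol = n),
    targets = NULL, patient_id = rep(clinical$patient_id, n)
  ), class = "mtl_data")
  mean(mtl_predict(model, data)$p_fcad)
}

#' Per-patient scores for a whole dataset
#'
#' @param model A `carpe_mtl`.
#' @param data An `mtl_data`.
#' @return Tibble `patient_id`, `score_ecg` (mean main-head probability).
#' @export
mtl_predict_patients <- function(model, data) {
  per_seq <- mtl_predict(model, data)
  dplyr::summarise(dplyr::group_by(per_seq, .data$patient_id),
                   score_ecg = mean(.data$p_fcad), .groups = "drop")
}

#' Enumerate the lead x preprocessing x learning-rate selection grid
#'
#' The default axes — 12 single leads plus one all-lead combination, three
#' preprocessing schemes, three learning rates — enumerate the 117
#' configurations examined during lead selection.
#'
#' @param lead_configs Character vector of lead configurations.
#' @param schemes Preprocessing schemes.
#' @param lrs Learning rates.
#' @return Tibble of configurations ordered by (lead, scheme, lr).
#' @export
enumerate_lead_grid <- function(lead_configs = c(paste0("lead_", 1:12), "all_leads"),
                                schemes = c("none", "minimal", "thorough"),
                                lrs = c(0.01, 0.001, 0.0001)) {
  tidyr::expand_grid(lead = lead_configs, scheme = schemes, lr = lrs)
}

#' Grid search over auxiliary-task weights and learning rate
#'
#' Trains one model per configuration on each development split and ranks
#' configurations by mean validation AUPRC of the main task.
#'
#' @param datasets List of `list(train = mtl_data, val = mtl_data)` splits.
#' @param weight_grid Named list with numeric axes `sss`, `srs`, `pharm`
#'   (the main-task weight is fixed at 1).
#' @param lr_grid Learning rates.
#' @param base_config Template [mtl_config()].
#' @return List with `best` (config row) and `table` (per-config mean scores).
#' @export
grid_search_mtl <- function(datasets,
                            weight_grid = list(sss = c(0, 0.25, 0.5, 0.75, 1),
                                               srs = c(0, 0.25, 0.5, 0.75, 1),
                                               pharm = c(0, 0.25, 0.5, 0.75, 1)),
                            lr_grid = c(0.01, 0.001, 0.0001),
                            base_config = mtl_config()) {
  grid <- tidyr::expand_grid(w_sss = weight_grid$sss, w_srs = weight_grid$srs,
                             w_pharm = weight_grid$pharm, lr = lr_grid)
  grid$auprc <- purrr::pmap_dbl(grid, function(w_sss, w_srs, w_pharm, lr) {
    cfg <- base_config
    cfg$task_weights <- c(fcad = 1, sss = w_sss, srs = w_srs, pharm = w_pharm)
    cfg$lr <- lr
    mean(purrr::map_dbl(datasets, function(d) {
      m <- train_mtl(d$train, cfg)
      sc <- mtl_predict_patients(m, d$val)
      lab <- patient_labels(d$val)
      metric_auprc(sc$score_ecg, lab[sc$patient_id])
    }))
  })
  list(best = grid[which.max(grid$auprc), ], table = grid)
}

# patient-level labels of an mtl_data (first sequence of each patient)
patient_labels <- function(data) {
  first <- !duplicated(data$patient_id)
  stats::setNames(as.logical(data$targets$fcad[first]), data$patient_id[first])
}

#' Permute all training targets jointly at the patient level
#'
#' Null-control transform: reassigns each patient's full target tuple
#' (label, perfusion scores, pharmacological support) to a randomly chosen
#' other patient, breaking every input-target association while preserving
#' the marginal target distributions. Auxiliary targets are permuted
#' together with the label — permuting the label alone would leave the
#' shared trunk trainable from the auxiliary tasks.
#'
#' @param data An `mtl_data`.
#' @param seed Integer seed.
#' @return The `mtl_data` with permuted targets.
#' @export
permute_targets <- function(data, seed = 1) {
  ids <- unique(data$patient_id)
  with_seed(seed, {
    new_of <- stats::setNames(sample(ids), ids)
    first_row <- match(ids, data$patient_id)
    names(first_row) <- ids
    src <- first_row[new_of[data$patient_id]]
    data$targets <- lapply(data$targets, function(v) unname(v[src]))
    data
  })
}
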