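#' Default end-to-end experiment configuration
#'
#' Desk-scale settings: a 200-patient cohort, the scaled-down network and a
#' reduced sequence cap keep a full run in the minutes range on one CPU
#' core while exercising every pipeline stage.
#'
#' @param ... Named overrides.
#' @return An experiment configuration list.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n = 200, prevalence = 0.329, seed = 1,
    cohort = cohort_config(),
    max_sequences = 8, scheme = "none", lead = 1,
    heldout_frac = 0.25, k = 5, calib_frac = 0.1,
    mtl = mtl_config(),
    st_l_pr = 80, st_method = "mean", st_which = "delta_stress",
    draws = 25, boot_frac = 0.8,
    cutoffs = c(0.05, 0.10, 0.15),
    calibrate = TRUE
  )
  modifyList(cfg, list(...))
}

validate_experiment_config <- function(cfg) {
  req <- c("n", "prevalence", "seed", "cohort", "max_sequences", "mtl",
           "draws", "cutoffs")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stopf("experiment config is missing required field(s): %s",
          paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

#' Run the full synthetic experiment
#'
#' Executes simulate -> sequences -> ST features -> model training ->
#' prediction -> decision-analytic evaluation on one development split, and
#' returns every artifact. All randomness flows from `config$seed`, so a
#' rerun with the same configuration reproduces the report exactly; the
#' configuration hash is stamped on the result.
#'
#' @param config See [experiment_config()].
#' @param quiet Suppress stage messages.
#' @return A `carpe_experiment` list: `config`, `config_hash`, `cohort`,
#'   `splits`, `models`, `predictions` (per-patient score tibble for all
#'   five predictors), and `report` (bootstrap table, decision curves,
#'   rule-out rows, calibration).
#' @export
run_experiment <- function(config = experiment_config(), quiet = TRUE) {
  validate_experiment_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- rlang::hash(config)

  say("stage simulate: %d patients", config$n)
  cohort <- generate_cohort(config$n, config$prevalence, seed = config$seed,
                            config = config$cohort, signals = TRUE)
  pts <- cohort$patients

  say("stage splits")
  splits <- make_splits(pts, heldout_frac = config$heldout_frac, k = config$k,
                        calib_frac = config$calib_frac, seed = config$seed)
  sp <- splits$splits[[1]]
  held <- splits$heldout

  say("stage features: ST baseline")
  st <- st_features_cohort(cohort, l_pr = config$st_l_pr,
                           method = config$st_method, which = config$st_which,
                           max_sequences = config$max_sequences,
                           seed = config$seed, lead = config$lead,
                           scheme = config$scheme)

  say("stage train: clinical ensemble")
  train_ids <- c(sp$train, sp$calib)
  tab_model <- train_tabular(pts[pts$patient_id %in% sp$train, ],
                             seed = config$seed)

  say("stage train: multi-task network")
  dat_train <- mtl_dataset(cohort, max_sequences = config$max_sequences,
                           seed = config$seed, lead = config$lead,
                           scheme = config$scheme, patient_ids = sp$train)
  mtl_model <- train_mtl(dat_train, config$mtl)

  say("stage predict")
  dat_held <- mtl_dataset(cohort, max_sequences = config$max_sequences,
                          seed = config$seed, lead = config$lead,
                          scheme = config$scheme, patient_ids = held)
  held_pts <- pts[match(held, pts$patient_id), ]
  score_ecg <- mtl_predict_patients(mtl_model, dat_held)
  score_ecg <- score_ecg$score_ecg[match(held, score_ecg$patient_id)]
  score_clin <- predict(tab_model, held_pts)
  if (isTRUE(config$calibrate)) {
    calib_pts <- pts[pts$patient_id %in% sp$calib, ]
    dat_cal <- mtl_dataset(cohort, max_sequences = config$max_sequences,
                           seed = config$seed, lead = config$lead,
                           scheme = config$scheme, patient_ids = sp$calib)
    cal_ecg <- mtl_predict_patients(mtl_model, dat_cal)
    cal_ecg <- cal_ecg$score_ecg[match(calib_pts$patient_id, cal_ecg$patient_id)]
    score_ecg <- calibrate_scores(score_ecg, cal_ecg, calib_pts$fcad)
    score_clin <- calibrate_scores(score_clin, predict(tab_model, calib_pts),
                                   calib_pts$fcad)
  }

  say("stage train: collaborative combiner")
  comb_pts <- pts[pts$patient_id %in% train_ids, ]
  comb_ecg <- mtl_predict_patients(mtl_model, mtl_dataset(
    cohort, max_sequences = config$max_sequences, seed = config$seed,
    lead = config$lead, scheme = config$scheme, patient_ids = comb_pts$patient_id))
  comb_ecg <- comb_ecg$score_ecg[match(comb_pts$patient_id, comb_ecg$patient_id)]
  combiner <- train_collaborative(predict(tab_model, comb_pts), comb_ecg,
                                  comb_pts$vas_post, comb_pts$fcad)
  score_coll <- predict_collaborative(combiner, score_clin, score_ecg,
                                      held_pts$vas_post)

  st_held <- st$st_score[match(held, st$patient_id)]
  predictions <- tibble::tibble(
    patient_id = held, label = held_pts$fcad,
    score_clin = score_clin, score_ecg = score_ecg, score_coll = score_coll,
    score_cardiologist = held_pts$vas_post,
    score_st_baseline = st_held,
    sex = held_pts$sex, age = held_pts$age,
    cad_history = held_pts$cad_history, stress_type = held_pts$stress_type
  )

  say("stage evaluate")
  methods <- c("score_clin", "score_ecg", "score_coll", "score_cardiologist",
               "score_st_baseline")
  boot <- paired_bootstrap(predictions, methods = methods,
                           draws = config$draws, frac = config$boot_frac,
                           seed = config$seed)
  dc <- decision_curve(predictions$score_ecg, predictions$label,
                       reference = predictions$score_cardiologist)
  rule_out <- purrr::map_dfr(config$cutoffs, function(ct) {
    purrr::map_dfr(c("score_ecg", "score_coll"), function(mt) {
      dplyr::mutate(rule_out_metrics(predictions[[mt]], predictions$label, ct,
                                     reference = predictions$score_cardiologist,
                                     boot_draws = config$draws,
                                     seed = config$seed),
                    method = mt, .before = 1)
    })
  })
  calib <- calibration_report(predictions$score_ecg, predictions$label)

  structure(list(
    config = config, config_hash = hash, cohort = cohort, splits = splits,
    models = list(tabular = tab_model, mtl = mtl_model, combiner = combiner),
    predictions = predictions,
    report = list(bootstrap = tibble::as_tibble(boot),
                  summary = tidy(boot), decision_curve = dc,
                  rule_out = rule_out, calibration = calib)
  ), class = "carpe_experiment")
}

#' @export
print.carpe_experiment <- function(x, ...) {
  cat(sprintf("<experiment %s> n=%d, held-out %d patients\n",
              substr(x$config_hash, 1, 8), x$config$n,
              nrow(x$predictions)))
  print(x$report$summary)
  invisible(x)
}
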