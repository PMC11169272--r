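#' Adjudicate functionally relevant CAD from perfusion-scan scores
#'
#' A patient is adjudicated fCAD-positive when the summed difference score
#' (summed stress score minus summed rest score) is at least 2, or the
#' transient ischaemic dilation ratio exceeds the protocol-specific
#' threshold: 1.22 for the dual-isotope protocol, 1.12 for the
#' single-isotope protocol.
#'
#' @param sss Summed stress score (non-negative integer).
#' @param srs Summed rest score (non-negative integer).
#' @param tid Transient ischaemic dilation ratio (positive).
#' @param isotope_protocol `"dual"` or `"single"`.
#' @return Logical, `TRUE` if fCAD is adjudicated. Vectorised over all
#'   arguments.
#' @examples
#' adjudicate_fcad(4, 1, 1.0, "dual")   # SDS = 3 -> TRUE
#' adjudicate_fcad(1, 0, 1.22, "dual")  # TID at threshold -> TRUE
#' @export
adjudicate_fcad <- function(sss, srs, tid, isotope_protocol) {
  if (any(sss < 0) || any(srs < 0)) stopf("`sss` and `srs` must be >= 0")
  if (any(tid <= 0)) stopf("`tid` must be positive")
  if (!all(isotope_protocol %in% c("dual", "single"))) {
    stopf("`isotope_protocol` must be \"dual\" or \"single\"")
  }
  thr <- ifelse(isotope_protocol == "dual", 1.22, 1.12)
  (sss - srs) >= 2 | tid >= thr
}

#' Configuration for the synthetic cohort generator
#'
#' Label-conditional distributions for the eight clinical variables, the
#' perfusion scores, the programmed ST depression, and the simulated
#' cardiologist score. Values are placeholders chosen to be clinically
#' plausible for a referred stress-test population (the generator emulates
#' statistical structure, not any real cohort); every entry can be
#' overridden via `...`.
#'
#' @param ... Named overrides of the default entries.
#' @return A named list of configuration entries.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    # clinical variables: list(neg = c(mean, sd), pos = c(mean, sd))
    age = list(neg = c(64, 11), pos = c(70, 10)),
    hr_rest = list(neg = c(72, 11), pos = c(68, 10)),
    sbp = list(neg = c(133, 17), pos = c(139, 18)),
    dbp = list(neg = c(80, 10), pos = c(81, 10)),
    weight = list(neg = c(78, 15), pos = c(81, 15)),
    height = list(neg = c(170, 9), pos = c(171, 9)),
    p_male = c(neg = 0.60, pos = 0.78),
    # P(history | no fCAD); positive-class odds scaled by cad_history_or
    p_history_neg = 0.32,
    cad_history_or = 2.64,
    # perfusion scores
    p_tid_route = 0.15,          # positives adjudicated via TID alone
    srs_lambda = 1.5,
    sds_pos = 2:10,              # summed difference score for SDS-route positives
    # programmed stress-phase ST depression magnitude (microvolts)
    depression = list(neg = c(0, 50), pos = c(100, 250)),
    rec_fraction = 0.4,          # recovery offset as fraction of stress offset
    # latent-risk model feeding the simulated cardiologist score
    risk_beta = c(intercept = -1.2, label = 1.8, age = 0.02,
                  history = 0.5, depression = 0.004),
    risk_sd = 0.6,
    vas_noise_sd = 1.5,          # logit-scale noise on the VAS transform
    vas_tail_shrink = 0.35,      # shrink toward 0.5: tail miscalibration
    vas_pre_extra_sd = 0.8,
    # signal generation; morphology_cv = inter-patient coefficient of
    # variation of the P/QRS/T amplitudes (real ECGs differ in voltage and
    # wave shape between patients, not only in ST level)
    morphology_cv = 0.15,
    phase_durations = c(60, 300, 180),
    hr_rest_signal = c(65, 80),  # uniform range for the signal HR ramp start
    hr_peak = c(135, 160),
    noise = list(wander = 50, broadband = 10, burst = 0),
    fs = 500,
    n_leads = 1
  )
  modifyList(cfg, list(...))
}

rnorm2 <- function(p) max(1, rnorm(1, p[1], p[2]))

#' Sample one synthetic patient record
#'
#' Draws the eight clinical variables from label-conditional distributions,
#' perfusion scores consistent with the adjudication rule (so
#' [adjudicate_fcad()] always reproduces the label), a programmed
#' ST-depression magnitude, and simulated cardiologist pre/post scores. The
#' cardiologist score is a noisy monotone logistic transform of the latent
#' true risk with shrink-toward-0.5 tail bias, mimicking the systematic
#' over/under-estimation of risk at the extremes.
#'
#' @param label Logical fCAD label.
#' @param seed Optional integer seed.
#' @param config See [cohort_config()].
#' @param patient_id Identifier.
#' @return A one-row tibble (a `PatientRecord`).
#' @export
sample_patient <- function(label, seed = NULL, config = cohort_config(),
                           patient_id = "P0001") {
  with_seed(seed, {
    k <- if (label) "pos" else "neg"
    sex <- if (runif(1) < config$p_male[[k]]) "male" else "female"
    p_hist_neg <- config$p_history_neg
    odds <- p_hist_neg / (1 - p_hist_neg)
    p_hist <- if (label) {
      o <- odds * config$cad_history_or; o / (1 + o)
    } else p_hist_neg
    cad_history <- runif(1) < p_hist

    isotope <- sample(c("dual", "single"), 1)
    tid_thr <- if (isotope == "dual") 1.22 else 1.12
    srs <- rpois(1, config$srs_lambda)
    if (label) {
      if (runif(1) < config$p_tid_route) {
        sss <- srs + sample(0:1, 1)
        tid <- tid_thr + abs(rnorm(1, 0, 0.05))
      } else {
        sss <- srs + sample(config$sds_pos, 1)
        tid <- runif(1, 0.85, tid_thr - 0.01)
      }
    } else {
      sss <- srs + sample(0:1, 1)
      tid <- runif(1, 0.85, tid_thr - 0.01)
    }

    depression <- runif(1, config$depression[[k]][1], config$depression[[k]][2])

    age <- rnorm2(config$age[[k]])
    b <- config$risk_beta
    eta <- b[["intercept"]] + b[["label"]] * label + b[["age"]] * (age - 65) +
      b[["history"]] * cad_history + b[["depression"]] * (depression - 75) +
      rnorm(1, 0, config$risk_sd)
    risk <- plogis(eta)
    vas_post <- vas_transform(risk, config$vas_noise_sd, config$vas_tail_shrink)
    vas_pre <- vas_transform(risk, config$vas_noise_sd + config$vas_pre_extra_sd,
                             config$vas_tail_shrink)

    stress_type <- sample(c("exercise_only", "pharma_from_start", "mixed"), 1,
                          prob = c(0.6, 0.25, 0.15))
    rec <- tibble::tibble(
      patient_id = patient_id,
      age = age, weight = rnorm2(config$weight[[k]]),
      height = rnorm2(config$height[[k]]), sex = sex,
      hr_rest = rnorm2(config$hr_rest[[k]]), sbp = rnorm2(config$sbp[[k]]),
      dbp = rnorm2(config$dbp[[k]]), cad_history = cad_history,
      vas_pre = vas_pre, vas_post = vas_post,
      sss = sss, srs = srs, tid = tid, isotope_protocol = isotope,
      stress_type = stress_type, depression = depression,
      true_risk = risk, fcad = as.logical(label)
    )
    stopifnot(adjudicate_fcad(rec$sss, rec$srs, rec$tid,
                              rec$isotope_protocol) == label)
    rec
  })
}

# Noisy monotone logistic transform of risk with shrink-toward-0.5 tail bias.
vas_transform <- function(risk, noise_sd, shrink) {
  r <- plogis(qlogis(pmin(pmax(risk, 1e-6), 1 - 1e-6)) + rnorm(1, 0, noise_sd))
  pmin(1, pmax(0, 0.5 + (1 - shrink) * (r - 0.5)))
}

#' Generate a synthetic stress-test cohort
#'
#' Draws exactly `round(n * prevalence)` fCAD-positive patients (stratified),
#' shuffles enrolment order, and (optionally) synthesises a stress-test
#' recording per patient whose stress-phase ST offset equals minus the
#' patient's programmed depression magnitude.
#'
#' @param n Number of patients.
#' @param prevalence fCAD prevalence in `[0, 1]`.
#' @param seed Integer seed; the cohort is fully reproducible given the seed.
#' @param config See [cohort_config()].
#' @param signals If `TRUE`, also generate ECG recordings (slower).
#' @return A `carpe_cohort`: list with `patients` (tibble, one row per
#'   patient in enrolment order) and `recordings` (named list of
#'   `carpe_recording`, or `NULL` when `signals = FALSE`).
#' @export
generate_cohort <- function(n, prevalence = 0.329, seed = 1,
                            config = cohort_config(), signals = FALSE) {
  stopifnot(n >= 0, prevalence >= 0, prevalence <= 1)
  if (n == 0) {
    return(structure(list(patients = sample_patient(TRUE)[0, ],
                          recordings = NULL, config = config),
                     class = "carpe_cohort"))
  }
  with_seed(seed, {
    n_pos <- round(n * prevalence)
    labels <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    ids <- sprintf("P%04d", seq_len(n))
    patients <- purrr::map2_dfr(labels, ids, function(lb, id) {
      sample_patient(lb, seed = NULL, config = config, patient_id = id)
    })
    patients$enrolment_order <- seq_len(n)
    recordings <- NULL
    if (signals) {
      recordings <- purrr::map2(seq_len(n), ids, function(i, id) {
        p <- patients[i, ]
        st <- -p$depression
        morph <- beat_morphology()
        cv <- config$morphology_cv
        if (cv > 0) {
          for (fld in c("p_amp", "r_amp", "s_amp", "t_amp", "q_amp")) {
            morph[[fld]] <- morph[[fld]] * max(0.4, rnorm(1, 1, cv))
          }
          morph$t_sigma <- morph$t_sigma * max(0.6, rnorm(1, 1, cv / 2))
          morph$p_sigma <- morph$p_sigma * max(0.6, rnorm(1, 1, cv / 2))
        }
        assemble_recording(
          phase_durations = config$phase_durations,
          hr_ramp = c(runif(1, config$hr_rest_signal[1], config$hr_rest_signal[2]),
                      runif(1, config$hr_peak[1], config$hr_peak[2])),
          st_params = list(pre = 0, stress = st, rec = st * config$rec_fraction),
          noise = config$noise, fs = config$fs, n_leads = config$n_leads,
          seed = NULL, patient_id = id, morphology = morph)
      })
      names(recordings) <- ids
    }
    structure(list(patients = patients, recordings = recordings,
                   config = config),
              class = "carpe_cohort")
  })
}

#' @export
print.carpe_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, prevalence %.3f, %s\n",
              nrow(x$patients),
              if (nrow(x$patients)) mean(x$patients$fcad) else NA,
              if (is.null(x$recordings)) "tabular only" else "with recordings"))
  invisible(x)
}
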