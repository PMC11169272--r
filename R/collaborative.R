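#' Train the collaborative combiner
#'
#' Combines the clinical-ensemble score, the ECG-network score and the
#' cardiologist's post-test probability by fitting a logistic regression on
#' exactly those three scores (plus intercept) on the training set. The
#' resulting score leverages the cardiologist's domain knowledge while
#' letting the supervised models correct systematic biases. If the design is
#' collinear or constant, a small ridge penalty is applied as a reported
#' fallback.
#'
#' @param score_clin,score_ecg,vas_post Numeric score vectors.
#' @param labels Logical fCAD labels.
#' @return A `carpe_combiner` with `$coef` (intercept + three slopes),
#'   `$fit`, and `$regularised` flag.
#' @export
train_collaborative <- function(score_clin, score_ecg, vas_post, labels) {
  df <- data.frame(score_clin = score_clin, score_ecg = score_ecg,
                   vas_post = vas_post, y = as.logical(labels))
  if (anyNA(df)) stopf("combiner inputs must not contain missing values")
  regularised <- FALSE
  sds <- vapply(df[1:3], sd, numeric(1))
  if (any(sds < 1e-10)) {
    regularised <- TRUE
    keep <- names(sds)[sds >= 1e-10]
    if (length(keep) == 0) {
      prev <- mean(df$y)
      fit <- NULL
      cf <- c(`(Intercept)` = qlogis(pmin(pmax(prev, 1e-6), 1 - 1e-6)),
              score_clin = 0, score_ecg = 0, vas_post = 0)
      return(structure(list(coef = cf, fit = NULL, regularised = TRUE),
                       class = "carpe_combiner"))
    }
    fml <- stats::as.formula(paste("y ~", paste(keep, collapse = " + ")))
    fit <- glm(fml, data = df, family = binomial())
    cf <- c(`(Intercept)` = unname(coef(fit)[1]), score_clin = 0,
            score_ecg = 0, vas_post = 0)
    cf[keep] <- coef(fit)[keep]
  } else {
    fit <- suppressWarnings(glm(y ~ score_clin + score_ecg + vas_post,
                                data = df, family = binomial()))
    cf <- coef(fit)
    if (anyNA(cf)) {
      regularised <- TRUE
      cf[is.na(cf)] <- 0
    }
  }
  structure(list(coef = cf, fit = fit, regularised = regularised),
            class = "carpe_combiner")
}

#' @rdname train_collaborative
#' @param combiner A fitted `carpe_combiner`.
#' @export
predict_collaborative <- function(combiner, score_clin, score_ecg, vas_post) {
  cf <- combiner$coef
  unname(plogis(cf[1] + cf["score_clin"] * score_clin +
                  cf["score_ecg"] * score_ecg + cf["vas_post"] * vas_post))
}

#' @export
print.carpe_combiner <- function(x, ...) {
  cat("<collaborative combiner> logit(p) =",
      sprintf("%.3f + %.3f clin + %.3f ecg + %.3f cardiologist\n",
              x$coef[1], x$coef["score_clin"], x$coef["score_ecg"],
              x$coef["vas_post"]))
  invisible(x)
}

#' @export
tidy.carpe_combiner <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                          std.error = NA_real_, p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 p.value = s[, 4])
}

#' @export
glance.carpe_combiner <- function(x, ...) {
  tibble::tibble(regularised = x$regularised,
                 n_inputs = 3L,
                 null.deviance = if (is.null(x$fit)) NA_real_ else x$fit$null.deviance,
                 deviance = if (is.null(x$fit)) NA_real_ else x$fit$deviance)
}
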