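#' Train the clinical-variables ensemble predictor
#'
#' Cross-validates four conventional model families — decision tree, random
#' forest, logistic regression, support vector machine — on exactly the
#' eight clinical variables (age, weight, biological sex, height, resting
#' heart rate, systolic and diastolic blood pressure, CAD history), selects
#' the family with the best mean validation AUPRC over stratified k-fold
#' cross-validation, and refits the winner on the full training data.
#'
#' @param patients Patient tibble (rows = patients) carrying the eight
#'   variables and an `fcad` label column.
#' @param k_folds Number of stratified CV folds (default 5).
#' @param seed Integer seed for fold assignment and the forest.
#' @return A `carpe_tabular` model with `$fit`, `$family`, and a
#'   `$selection` tibble of per-family CV scores.
#' @export
train_tabular <- function(patients, k_folds = 5, seed = 1) {
  y <- as.logical(patients$fcad)
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  X <- tabular_frame(patients)
  df <- cbind(X, fcad = factor(y, levels = c(FALSE, TRUE)))
  families <- c("decision_tree", "random_forest", "logistic_regression", "svm")
  with_seed(seed, {
    folds <- stratified_folds(y, k_folds)
    selection <- purrr::map_dfr(families, function(fam) {
      scores <- vapply(seq_len(k_folds), function(k) {
        tr <- df[folds != k, ]; te <- df[folds == k, ]
        if (length(unique(tr$fcad)) < 2) return(NA_real_)
        fit <- fit_family(fam, tr)
        metric_auprc(predict_family(fam, fit, te), te$fcad == "TRUE")
      }, numeric(1))
      tibble::tibble(family = fam, cv_auprc = mean(scores, na.rm = TRUE))
    })
    winner <- selection$family[which.max(selection$cv_auprc)]
    fit <- fit_family(winner, df)
    structure(list(fit = fit, family = winner, selection = selection,
                   feature_names = names(X)),
              class = "carpe_tabular")
  })
}

tabular_frame <- function(patients) {
  data.frame(
    age = patients$age, weight = patients$weight,
    sex = as.numeric(patients$sex == "male"), height = patients$height,
    hr_rest = patients$hr_rest, sbp = patients$sbp, dbp = patients$dbp,
    cad_history = as.numeric(patients$cad_history)
  )
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

fit_family <- function(family, df) {
  switch(family,
    decision_tree = rpart::rpart(fcad ~ ., data = df, method = "class"),
    random_forest = randomForest::randomForest(fcad ~ ., data = df, ntree = 300),
    logistic_regression = suppressWarnings(glm(fcad ~ ., data = df,
                                               family = binomial())),
    svm = e1071::svm(fcad ~ ., data = df, probability = TRUE, kernel = "radial"),
    stopf("unknown model family '%s'", family)
  )
}

predict_family <- function(family, fit, newdata) {
  switch(family,
    decision_tree = predict(fit, newdata, type = "prob")[, "TRUE"],
    random_forest = predict(fit, newdata, type = "prob")[, "TRUE"],
    logistic_regression = predict(fit, newdata, type = "response"),
    svm = attr(predict(fit, newdata, probability = TRUE),
               "probabilities")[, "TRUE"]
  )
}

#' @export
predict.carpe_tabular <- function(object, newdata, ...) {
  X <- tabular_frame(newdata)
  unname(predict_family(object$family, object$fit, X))
}

#' @export
print.carpe_tabular <- function(x, ...) {
  cat(sprintf("<clinical ensemble> winner: %s (CV AUPRC %.3f)\n", x$family,
              max(x$selection$cv_auprc)))
  invisible(x)
}

#' @export
tidy.carpe_tabular <- function(x, ...) x$selection

#' @export
glance.carpe_tabular <- function(x, ...) {
  tibble::tibble(family = x$family, cv_auprc = max(x$selection$cv_auprc),
                 n_candidates = nrow(x$selection))
}
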