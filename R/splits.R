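#' Build the temporal held-out split and stratified development splits
#'
#' The held-out test set is the last `heldout_frac` of patients by enrolment
#' order (a temporal split: performance on it reflects robustness to
#' temporal shift). The remaining development set is divided into `k`
#' stratified splits of training, validation and calibration sets with a
#' 4:1 train:validation ratio, the calibration set taking 10% of the
#' training portion; fCAD prevalence is preserved across splits within
#' rounding.
#'
#' @param patients Patient tibble with `patient_id`, `fcad`, and
#'   `enrolment_order` columns.
#' @param heldout_frac Fraction held out by enrolment order (default 0.25).
#' @param k Number of stratified development splits (default 5).
#' @param calib_frac Calibration fraction of the training set (default 0.1).
#' @param seed Integer seed for the stratified assignment.
#' @return A `carpe_splits` list: `heldout` (patient ids) and `splits`
#'   (list of `k` lists with `train`, `val`, `calib` id vectors).
#' @export
make_splits <- function(patients, heldout_frac = 0.25, k = 5,
                        calib_frac = 0.1, seed = 1) {
  if (!"enrolment_order" %in% names(patients)) {
    stopf("patients must carry an `enrolment_order` column")
  }
  ord <- order(patients$enrolment_order)
  n <- nrow(patients)
  n_held <- round(n * heldout_frac)
  if (n - n_held < 2 * k) stopf("cohort too small to stratify into %d splits", k)
  held_idx <- ord[(n - n_held + 1):n]
  dev_idx <- setdiff(ord, held_idx)
  y <- as.logical(patients$fcad[dev_idx])
  if (length(unique(y)) < 2) stopf("development set contains a single class")
  with_seed(seed, {
    val_fold <- stratified_folds(y, k)
    splits <- lapply(seq_len(k), function(fold) {
      val <- dev_idx[val_fold == fold]
      train_all <- dev_idx[val_fold != fold]
      ya <- as.logical(patients$fcad[train_all])
      calib_sel <- logical(length(train_all))
      for (cls in unique(ya)) {
        idx <- which(ya == cls)
        n_cal <- round(calib_frac * length(idx))
        calib_sel[sample(idx, n_cal)] <- TRUE
      }
      list(train = patients$patient_id[train_all[!calib_sel]],
           val = patients$patient_id[val],
           calib = patients$patient_id[train_all[calib_sel]])
    })
    structure(list(heldout = patients$patient_id[held_idx], splits = splits,
                   k = k),
              class = "carpe_splits")
  })
}

#' @export
print.carpe_splits <- function(x, ...) {
  s1 <- x$splits[[1]]
  cat(sprintf("<splits> held-out %d; %d dev splits of ~%d train / %d val / %d calib\n",
              length(x$heldout), x$k, length(s1$train), length(s1$val),
              length(s1$calib)))
  invisible(x)
}
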