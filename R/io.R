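#' Write / read a stress recording as a plain-text record
#'
#' Records are stored as a human-readable header (`<name>.hea`: sampling
#' rate, lead names, phase boundaries), a TSV signal file (`<name>.sig.tsv`,
#' one column per lead, microvolts) and, when ground truth is present, a
#' JSON sidecar (`<name>.truth.json`). The layout mirrors the
#' header-plus-signal convention of waveform databases while staying fully
#' text-based.
#'
#' @param rec A `carpe_recording`.
#' @param dir Output directory (created if needed).
#' @param name Record name (defaults to the patient id).
#' @return The record name, invisibly.
#' @export
write_recording <- function(rec, dir, name = rec$patient_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hea <- c(
    sprintf("record %s %d %d %d", name, ncol(rec$signals), rec$fs,
            nrow(rec$signals)),
    sprintf("leads %s", paste(rec$lead_names, collapse = " ")),
    sprintf("phases %g %g %g", rec$phases$pre_end, rec$phases$stress_end,
            rec$phases$total))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  utils::write.table(round(rec$signals, 3), file.path(dir, paste0(name, ".sig.tsv")),
                     sep = "\t", row.names = FALSE,
                     col.names = rec$lead_names)
  if (!is.null(rec$truth)) {
    jsonlite::write_json(rec$truth, file.path(dir, paste0(name, ".truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(name)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir, name) {
  hea <- readLines(file.path(dir, paste0(name, ".hea")))
  head1 <- strsplit(hea[1], " ")[[1]]
  fs <- as.integer(head1[4])
  leads <- strsplit(hea[2], " ")[[1]][-1]
  ph <- as.numeric(strsplit(hea[3], " ")[[1]][-1])
  sig <- as.matrix(utils::read.table(file.path(dir, paste0(name, ".sig.tsv")),
                                     header = TRUE, sep = "\t"))
  colnames(sig) <- leads
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  new_stress_recording(sig, fs, leads, phase_annotation(ph[1], ph[2], ph[3]),
                       truth, name)
}

#' Write / read a patient table as CSV
#'
#' Column names are the documented field names of the patient record
#' (the eight clinical variables, VAS scores, perfusion scores, stress type
#' and label).
#'
#' @param patients Patient tibble.
#' @param path CSV path.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
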