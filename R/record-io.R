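#' Write a waveform record as plain-text files
#'
#' Persists an `ecg_record` as three files: `<name>.csv` (columns `t`,
#' `ecg`, optional `event`, `gap`), `<name>.hea.yaml` (sampling rate,
#' length, channel names) and — when the record carries ground truth —
#' `<name>.truth.csv` with the per-beat fiducials (`beat_sample` = R
#' peak, wave onsets/offsets in samples, `true_qt_ms`, `is_ectopic`).
#'
#' @param record An `ecg_record` (see [simulate_ecg()]).
#' @param path Output path prefix (without extension).
#' @param overwrite Overwrite existing files.
#' @return The signal file path, invisibly.
#' @export
write_record <- function(record, path, overwrite = FALSE) {
  sig <- paste0(path, ".csv")
  hea <- paste0(path, ".hea.yaml")
  tru <- paste0(path, ".truth.csv")
  hit <- c(sig, hea, tru)[file.exists(c(sig, hea, tru))]
  if (length(hit) > 0 && !overwrite) {
    abort(paste0("Refusing to overwrite: ", paste(hit, collapse = ", ")))
  }
  dir.create(dirname(sig), showWarnings = FALSE, recursive = TRUE)
  fs <- record_fs(record)
  readr::write_csv(as_tibble(record), sig)
  yaml::write_yaml(
    list(fs_hz = fs, n_samples = nrow(record),
         channels = setdiff(names(record), "t"),
         t0_s = record$t[1]),
    hea)
  truth <- attr(record, "truth", exact = TRUE)
  if (!is.null(truth)) {
    out <- truth
    out$beat_sample <- out$r_peak
    readr::write_csv(out, tru)
  }
  invisible(sig)
}

#' Read a waveform record written by [write_record()]
#'
#' @param path Path prefix used at writing time.
#' @return An `ecg_record` with its `fs` and (if present) `truth`
#'   attributes restored.
#' @export
read_record <- function(path) {
  sig <- paste0(path, ".csv")
  hea <- paste0(path, ".hea.yaml")
  if (!file.exists(sig) || !file.exists(hea)) {
    abort(sprintf("No record at prefix '%s'.", path))
  }
  header <- yaml::read_yaml(hea)
  data <- readr::read_csv(sig, show_col_types = FALSE)
  tru <- paste0(path, ".truth.csv")
  truth <- if (file.exists(tru)) {
    readr::read_csv(tru, show_col_types = FALSE)
  }
  new_ecg_record(data, fs = header$fs_hz, truth = truth)
}
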