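#' Filter a raw ECG record
#'
#' Applies a fifth-order 0.5 Hz high-pass Butterworth filter and a 60 Hz
#' powerline notch, both run forward–backward (zero phase) so fiducial
#' positions are not biased by filter delay. The gap mask is dilated by
#' one second on each side of every gap, because filter ringing bleeds
#' into the neighbourhood of a zero-filled span.
#'
#' @param record An `ecg_record` (or tibble with columns `t`, `ecg` and
#'   optionally `gap`).
#' @param fs Sampling rate in Hz; defaults to the record's `fs`
#'   attribute. Must be at least 125 Hz so the 60 Hz notch is below
#'   Nyquist.
#' @param highpass_hz,highpass_order High-pass corner and order.
#' @param notch_hz Powerline frequency to suppress.
#'
#' @return The filtered record (same shape, `fs`/`truth` attributes
#'   preserved).
#' @export
ecg_preprocess <- function(record, fs = record_fs(record),
                           highpass_hz = 0.5, highpass_order = 5,
                           notch_hz = 60) {
  if (fs < 125) abort("`fs` must be at least 125 Hz (60 Hz notch needs headroom).")
  if (notch_hz >= fs / 2) abort("Powerline frequency is at or above Nyquist.")
  if (nrow(record) < 10 * fs) abort("Record must be at least 10 s long.")
  x <- record$ecg - mean(record$ecg)
  hp <- signal::butter(highpass_order, highpass_hz / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, x)
  bw <- 2  # Hz half-width of the notch stop band
  notch <- signal::butter(2, c(notch_hz - bw, notch_hz + bw) / (fs / 2),
                          type = "stop")
  x <- signal::filtfilt(notch, x)
  out <- record
  out$ecg <- x
  if ("gap" %in% names(out) && any(out$gap)) {
    out$gap <- dilate_mask(out$gap, as.integer(fs))
    out$ecg[out$gap] <- 0
  }
  out
}

dilate_mask <- function(mask, by) {
  if (!any(mask) || by <= 0) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- logical(length(mask))
  for (i in which(r$values)) {
    out[max(1L, starts[i] - by):min(length(mask), ends[i] + by)] <- TRUE
  }
  out
}
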