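# Dyadic a-trous wavelet transform with the quadratic-spline filter pair
# (lowpass 1/8*[1,3,3,1], highpass 2*[1,-1]). W at scale 2^j approximates
# the derivative of the signal smoothed at that scale, so wave limbs
# appear as modulus-maxima pairs with a zero crossing at the wave peak.

upsample_filter <- function(f, by) {
  if (by == 1) return(f)
  out <- numeric((length(f) - 1) * by + 1)
  out[seq(1, length(out), by = by)] <- f
  out
}

conv_aligned <- function(x, f, delay) {
  full <- convolve(x, rev(f), type = "open")
  idx <- seq_along(x) + as.integer(round(delay))
  idx[idx < 1 | idx > length(full)] <- NA
  out <- full[idx]
  out[is.na(out)] <- 0
  out
}

#' Dyadic wavelet transform of an ECG trace
#'
#' @param x Numeric signal.
#' @param scales Integer vector of dyadic scales (j for scale 2^j).
#' @return A matrix with one column per requested scale, time-aligned to
#'   the input.
#' @keywords internal
ecg_wavelet <- function(x, scales = 1:5) {
  h <- c(1, 3, 3, 1) / 8
  g <- c(2, -2)
  n_max <- max(scales)
  out <- matrix(0, length(x), length(scales))
  colnames(out) <- paste0("w", scales)
  s <- x
  acc <- 0  # accumulated smoothing delay in samples
  for (j in seq_len(n_max)) {
    up <- 2^(j - 1)
    g_up <- upsample_filter(g, up)
    d_g <- 0.5 * up
    if (j %in% scales) {
      out[, match(j, scales)] <- conv_aligned(s, g_up, acc + d_g)
    }
    if (j < n_max) {
      h_up <- upsample_filter(h, up)
      s <- conv_aligned(s, h_up, 1.5 * up)
    }
  }
  out
}
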