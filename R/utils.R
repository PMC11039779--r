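#' @importFrom rlang abort warn inform %||%
#' @importFrom stats fft sd var pt pnorm rnorm rlnorm qnorm predict
NULL

# metadata columns that every feature tibble carries alongside the features
ID_COLS <- c("subject_id", "segment_index", "label")

#' Names of the feature columns of a feature matrix
#'
#' @param features A feature tibble as produced by [build_feature_matrix()].
#' @return Character vector of feature column names (everything except
#'   `subject_id`, `segment_index`, `label`).
#' @export
feature_names <- function(features) {
  setdiff(names(features), ID_COLS)
}

abort_config <- function(msg, ...) abort(msg, class = "gaboreeg_config_error", ...)
abort_data   <- function(msg, ...) abort(msg, class = "gaboreeg_data_error", ...)
abort_io     <- function(msg, ...) abort(msg, class = "gaboreeg_io_error", ...)

# Deterministic 32-bit seed derived from a sequence of integer keys.
# All intermediate products stay below 2^53 so the arithmetic is exact.
derive_seed <- function(...) {
  key <- c(...)
  h <- 0
  for (k in key) h <- (h * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Welch power spectral density estimate
#'
#' Averaged Hann-windowed periodograms with 50% overlap; one-sided density
#' in units of power per Hz.  Used by the synthetic-cohort spectral checks.
#'
#' @param x Numeric vector, a single-channel signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Samples per window (clamped to `length(x)`).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A tibble with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = 512, overlap = 0.5) {
  n <- length(x)
  if (n < 8) abort_data("welch_psd() needs at least 8 samples.")
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1)))
  scale <- fs * sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    X <- fft(w * (seg - mean(seg)))
    acc <- acc + (Mod(X)^2 / scale)[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # fold negative frequencies into the interior one-sided bins
  if (nperseg %% 2 == 0) {
    psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  tibble::tibble(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Band power from a Welch periodogram
#'
#' @inheritParams welch_psd
#' @param lo,hi Band edges in Hz (power integrated over `[lo, hi)`).
#' @return Scalar band power.
#' @export
band_power <- function(x, fs, lo, hi, nperseg = 512) {
  p <- welch_psd(x, fs, nperseg = nperseg)
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[p$freq >= lo & p$freq < hi]) * df
}
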