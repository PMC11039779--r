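# deterministic fixtures built in code

# record with gaussian noise channels
make_noise_record <- function(n_channels = 2, n_samples = 512, fs = 128,
                              seed = 7, label = 1L, subject_id = "noise") {
  withr::with_seed(seed, {
    eeg_record(matrix(rnorm(n_channels * n_samples), nrow = n_channels),
               fs = fs, subject_id = subject_id, label = label)
  })
}

# single-channel pure tone record
make_tone_record <- function(freq, n_samples = 3840, fs = 128, amp = 1) {
  t <- (0:(n_samples - 1)) / fs
  eeg_record(matrix(amp * sin(2 * pi * freq * t), nrow = 1),
             fs = fs, subject_id = "tone", label = 0L)
}

# small labelled feature tibble: `gap` shifts the case-class mean of the
# first `n_informative` features
make_feature_tibble <- function(n_per_class = 10, n_features = 5, gap = 0,
                                n_informative = 1, seed = 1,
                                segments_per_subject = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c(0L, 1L), each = n_per_class)
    X <- matrix(rnorm(n * n_features), nrow = n)
    if (n_informative > 0) {
      X[, seq_len(n_informative)] <-
        X[, seq_len(n_informative), drop = FALSE] + gap * y
    }
    colnames(X) <- paste0("ch1_f1_", seq_len(n_features))
    subj <- paste0("s", rep(seq_len(n / segments_per_subject),
                            each = segments_per_subject))
    dplyr::bind_cols(
      tibble::tibble(subject_id = subj,
                     segment_index = rep(seq_len(segments_per_subject) - 1L,
                                         n / segments_per_subject),
                     label = y),
      tibble::as_tibble(X)
    )
  })
}

# full-length FFT convolution oracle (independent of the package's
# time-domain path): linear convolution via zero-padding, "same" cut
fft_conv_same <- function(x, taps) {
  n <- length(x)
  k <- length(taps)
  T <- (k - 1) / 2
  N <- n + k - 1
  X <- stats::fft(c(x, rep(0, N - n)))
  H <- stats::fft(c(taps, rep(0, N - k)))
  full <- stats::fft(X * H, inverse = TRUE) / N
  full[(T + 1):(T + n)]
}
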