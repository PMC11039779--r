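#' Construct a Gabor filter bank
#'
#' A bank is an ordered set of complex Gabor filters, each a Gaussian
#' envelope modulated by a complex sinusoid at central frequency `fc`:
#' `g(t) = (2*pi*sigma_t^2)^(-1/2) exp(-t^2 / (2*sigma_t^2)) exp(i*2*pi*fc*t)`.
#' The width parameter `sigma` can be interpreted in the frequency domain
#' (`"freq_hz"`, the default: `sigma` is the standard deviation of the
#' filter's Gaussian frequency profile in Hz, so the time-domain width is
#' `sigma_t = fs / (2*pi*sigma)` samples) or directly in the time domain
#' (`"time_samples"`).
#'
#' @param fc Numeric vector of central frequencies in Hz, strictly increasing.
#' @param sigma Numeric vector of width parameters, same length as `fc`.
#' @param sigma_domain `"freq_hz"` or `"time_samples"`.
#' @param truncation_sigmas Kernel half-width in multiples of the
#'   time-domain standard deviation (>= 3; default 4).
#' @param name Bank name carried into outputs.
#' @return A `gabor_bank`: a tibble with columns `filter`, `fc`, `sigma`
#'   and attributes `sigma_domain`, `truncation_sigmas`, `bank_name`.
#' @export
gabor_bank <- function(fc, sigma, sigma_domain = c("freq_hz", "time_samples"),
                       truncation_sigmas = 4, name = "custom") {
  sigma_domain <- match.arg(sigma_domain)
  if (length(fc) < 1 || length(fc) != length(sigma)) {
    abort_config("`fc` and `sigma` must be non-empty vectors of equal length.")
  }
  if (any(fc <= 0) || any(diff(fc) <= 0)) {
    abort_config("Central frequencies must be positive and strictly increasing.")
  }
  if (any(sigma <= 0)) abort_config("`sigma` must be positive.")
  if (truncation_sigmas < 3) abort_config("`truncation_sigmas` must be >= 3.")
  bank <- tibble::tibble(filter = seq_along(fc), fc = as.numeric(fc),
                         sigma = as.numeric(sigma))
  structure(bank,
            sigma_domain = sigma_domain,
            truncation_sigmas = truncation_sigmas,
            bank_name = name,
            class = c("gabor_bank", class(bank)))
}

# (fc, sigma) presets for the 3-, 4- and 5-filter banks, tiling 1-64 Hz
GABOR_PRESETS <- list(
  `3` = list(fc = c(12.8, 25.6, 38.4), sigma = c(10, 10, 5)),
  `4` = list(fc = c(12.8, 25.6, 38.4, 51.2), sigma = c(10, 10, 10, 10)),
  `5` = list(fc = c(10.24, 20.48, 30.72, 40.96, 51.2),
             sigma = c(12, 12, 12, 12, 10))
)

#' Preset Gabor banks with 3, 4 or 5 filters
#'
#' Returns the standard parameter sets whose central frequencies tile the
#' 1-64 Hz EEG range (64 Hz = Nyquist at the nominal 128 Hz rate).
#'
#' @param n_filters 3, 4 or 5.
#' @inheritParams gabor_bank
#' @return A [gabor_bank()] named `"preset3"`, `"preset4"` or `"preset5"`.
#' @export
gabor_preset <- function(n_filters, sigma_domain = c("freq_hz", "time_samples"),
                         truncation_sigmas = 4) {
  key <- as.character(n_filters)
  if (length(n_filters) != 1 || !key %in% names(GABOR_PRESETS)) {
    abort_config(
      "Presets exist for 3, 4 or 5 filters only; build other banks with gabor_bank(fc, sigma)."
    )
  }
  p <- GABOR_PRESETS[[key]]
  gabor_bank(p$fc, p$sigma, sigma_domain = match.arg(sigma_domain),
             truncation_sigmas = truncation_sigmas,
             name = paste0("preset", key))
}

# time-domain standard deviation in samples for one filter
sigma_time_samples <- function(sigma, sigma_domain, fs) {
  if (sigma_domain == "freq_hz") fs / (2 * pi * sigma) else sigma
}

#' Build a discrete complex Gabor kernel
#'
#' Taps are `g(t) = (2*pi*sigma_t^2)^(-1/2) exp(-t^2/(2*sigma_t^2))
#' exp(i*2*pi*(fc/fs)*t)` for integer `t` in `[-T, T]`,
#' `T = ceiling(truncation_sigmas * sigma_t)` (at least 4, so the kernel has
#' at least 9 taps).
#'
#' @param fc Central frequency in Hz (must be below `fs/2`).
#' @param sigma Width parameter (see [gabor_bank()]).
#' @param fs Sampling rate in Hz.
#' @inheritParams gabor_bank
#' @return A `gabor_kernel`: list with complex `taps` (odd length), `fs`,
#'   `fc`, `sigma`, `sigma_domain`, `sigma_t`.
#' @export
gabor_kernel <- function(fc, sigma, fs, sigma_domain = c("freq_hz", "time_samples"),
                         truncation_sigmas = 4) {
  sigma_domain <- match.arg(sigma_domain)
  if (fc >= fs / 2) {
    abort_config(sprintf(
      "Central frequency %g Hz is at or above Nyquist (%g Hz): aliasing.",
      fc, fs / 2
    ))
  }
  st <- sigma_time_samples(sigma, sigma_domain, fs)
  if (st < 1) {
    abort_config(sprintf(
      "Time-domain width %.3f samples (< 1): kernel numerically degenerate.", st
    ))
  }
  T <- max(4L, as.integer(ceiling(truncation_sigmas * st)))
  t <- seq.int(-T, T)
  taps <- exp(-t^2 / (2 * st^2)) / sqrt(2 * pi * st^2) *
    exp(1i * 2 * pi * (fc / fs) * t)
  structure(
    list(taps = taps, fs = fs, fc = fc, sigma = sigma,
         sigma_domain = sigma_domain, sigma_t = st),
    class = "gabor_kernel"
  )
}

#' @export
print.gabor_kernel <- function(x, ...) {
  cat(sprintf(
    "<gabor_kernel> fc = %g Hz, sigma = %g (%s), %d taps @ %g Hz\n",
    x$fc, x$sigma, x$sigma_domain, length(x$taps), x$fs
  ))
  invisible(x)
}

bank_kernels <- function(bank, fs) {
  sd <- attr(bank, "sigma_domain")
  ts <- attr(bank, "truncation_sigmas")
  purrr::map2(bank$fc, bank$sigma, gabor_kernel, fs = fs,
              sigma_domain = sd, truncation_sigmas = ts)
}

#' Frequency response of a Gabor kernel
#'
#' Evaluates `G(f) = sum_t g(t) exp(-i*2*pi*(f/fs)*t)` at the requested
#' frequencies.
#'
#' @param kernel A [gabor_kernel()].
#' @param freq Frequencies in Hz.
#' @return Complex vector of responses, one per frequency.
#' @export
kernel_freq_response <- function(kernel, freq) {
  T <- (length(kernel$taps) - 1L) / 2L
  t <- seq.int(-T, T)
  vapply(freq, function(f) sum(kernel$taps * exp(-1i * 2 * pi * (f / kernel$fs) * t)),
         complex(1))
}

# zero-padded "same"-length complex convolution z[n] = sum_s g[s] y[n - s],
# with the kernel's centre tap aligned on the current sample
convolve_same <- function(x, taps) {
  n <- length(x)
  T <- (length(taps) - 1L) / 2L
  xp <- c(rep(0, T), x, rep(0, T))
  z <- complex(n)
  base <- T + seq_len(n)
  for (m in seq_along(taps)) {
    s <- m - T - 1L
    z <- z + taps[m] * xp[base - s]
  }
  z
}

#' Apply a Gabor filter bank to a multichannel segment
#'
#' Each channel is convolved with each complex kernel ("same"-length,
#' zero-padded boundaries) and the modulus of the response is taken,
#' yielding a narrow-band amplitude envelope per (filter, channel).
#'
#' @param data Channels x samples numeric matrix (e.g. the `data` element of
#'   a [segment_record()] row), or an [eeg_record()].
#' @param bank A [gabor_bank()].
#' @param fs Sampling rate in Hz (taken from the record if `data` is one).
#' @param trim_edges If `TRUE`, one kernel half-length is trimmed from each
#'   end of every envelope before it is returned (default `FALSE`: edge
#'   transients are kept).
#' @return A `bank_response`: numeric array of magnitudes with dimensions
#'   (filter, channel, sample) and attributes `fs` and `bank`.
#' @export
apply_filter_bank <- function(data, bank, fs = NULL, trim_edges = FALSE) {
  if (inherits(data, "eeg_record")) {
    fs <- data$fs
    m <- data$data
    rownames(m) <- data$channels
    data <- m
  }
  if (is.null(fs)) abort_config("Supply `fs` when `data` is a bare matrix.")
  stopifnot(is.matrix(data), inherits(bank, "gabor_bank"))
  kernels <- bank_kernels(bank, fs)
  L <- ncol(data)
  max_trim <- 0L
  for (k in seq_along(kernels)) {
    kl <- length(kernels[[k]]$taps)
    if (kl > L) {
      abort_data(sprintf(
        "Segment (%d samples) shorter than kernel of filter %d (%d taps).",
        L, k, kl
      ))
    }
    max_trim <- max(max_trim, (kl - 1L) %/% 2L)
  }
  keep <- if (trim_edges) (max_trim + 1L):(L - max_trim) else seq_len(L)
  out <- array(0, dim = c(length(kernels), nrow(data), length(keep)))
  for (k in seq_along(kernels)) {
    for (c in seq_len(nrow(data))) {
      out[k, c, ] <- Mod(convolve_same(data[c, ], kernels[[k]]$taps))[keep]
    }
  }
  dimnames(out) <- list(
    filter = paste0("f", seq_along(kernels)),
    channel = rownames(data) %||% paste0("ch", seq_len(nrow(data))),
    NULL
  )
  structure(out, fs = fs, bank = bank, trim_edges = trim_edges,
            class = c("bank_response", "array"))
}

#' Frequency coverage of a bank
#'
#' Total width (Hz) of the union of the per-filter `fc +/- 2*sigma_f`
#' intervals intersected with `(0, fs/2]`, where `sigma_f` is each filter's
#' frequency-domain standard deviation.
#'
#' @param bank A [gabor_bank()].
#' @param fs Sampling rate in Hz.
#' @return Scalar coverage width in Hz.
#' @export
bank_coverage <- function(bank, fs) {
  sdom <- attr(bank, "sigma_domain")
  sf <- if (sdom == "freq_hz") bank$sigma else fs / (2 * pi * bank$sigma)
  lo <- pmax(bank$fc - 2 * sf, 0)
  hi <- pmin(bank$fc + 2 * sf, fs / 2)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  total + (cur_hi - cur_lo)
}

#' Gaussian frequency-profile mass of each filter within a band
#'
#' Useful for asking which filter of a bank best overlaps a canonical EEG
#' band (e.g. theta, 4-8 Hz).
#'
#' @param bank A [gabor_bank()].
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz.
#' @return Numeric vector, one mass in `[0, 1]` per filter.
#' @export
filter_band_mass <- function(bank, fs, lo, hi) {
  sdom <- attr(bank, "sigma_domain")
  sf <- if (sdom == "freq_hz") bank$sigma else fs / (2 * pi * bank$sigma)
  pnorm((hi - bank$fc) / sf) - pnorm((lo - bank$fc) / sf)
}

#' Read or write a bank configuration as YAML
#'
#' The file holds `filters` (list of `{fc, sigma}`), `sigma_domain`,
#' `truncation_sigmas` and `name`; alternatively `preset: 3|4|5`.
#'
#' @param path YAML file path.
#' @return [read_bank_yaml()] returns a [gabor_bank()].
#' @export
read_bank_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  bank_from_config(cfg)
}

#' @rdname read_bank_yaml
#' @param bank A [gabor_bank()].
#' @export
write_bank_yaml <- function(bank, path) {
  yaml::write_yaml(list(
    name = attr(bank, "bank_name"),
    sigma_domain = attr(bank, "sigma_domain"),
    truncation_sigmas = attr(bank, "truncation_sigmas"),
    filters = purrr::map2(bank$fc, bank$sigma, ~list(fc = .x, sigma = .y))
  ), path)
  invisible(path)
}

bank_from_config <- function(cfg) {
  if (inherits(cfg, "gabor_bank")) return(cfg)
  sdom <- cfg$sigma_domain %||% "freq_hz"
  ts <- cfg$truncation_sigmas %||% 4
  if (!is.null(cfg$preset)) {
    return(gabor_preset(cfg$preset, sigma_domain = sdom, truncation_sigmas = ts))
  }
  if (is.null(cfg$filters)) {
    abort_config("Bank config needs either `preset` or a `filters` list.")
  }
  gabor_bank(
    fc = purrr::map_dbl(cfg$filters, "fc"),
    sigma = purrr::map_dbl(cfg$filters, "sigma"),
    sigma_domain = sdom, truncation_sigmas = ts,
    name = cfg$name %||% "custom"
  )
}
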