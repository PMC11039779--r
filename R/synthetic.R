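CANONICAL_BANDS <- list(
  delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
  beta = c(13, 30), gamma = c(30, 60)
)

# 10-20 electrode labels used when a cohort has the standard 19 channels
TEN_TWENTY_19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                   "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Configuration for a synthetic two-class EEG cohort
#'
#' Each channel of a synthetic subject is a sum of band-limited Gaussian
#' noise processes (one per canonical band: delta 1-4, theta 4-8, alpha
#' 8-13, beta 13-30, gamma 30-60 Hz), each scaled by a subject-specific
#' gain drawn lognormally around its class mean, plus a pink (1/f)
#' background and a white-noise floor.  The class difference lives in the
#' band gains; by default the case class has `theta_ratio` times the
#' control theta amplitude (so theta *power* differs by the ratio squared),
#' mirroring the elevated theta activity reported for ADHD.
#'
#' @param n_case,n_control Subjects per class (defaults 61 / 60, the shape
#'   of the reference clinical cohort).
#' @param n_channels Channels per subject (default 19).
#' @param fs Sampling rate in Hz (default 128; must exceed twice the
#'   highest band edge).
#' @param duration_s Recording length per subject in seconds (default 120,
#'   a realistic resting-state take that yields four 30 s windows).
#' @param theta_ratio Case/control mean theta amplitude ratio (default 2).
#' @param band_gains Optional full override: list with named numeric
#'   vectors `case` and `control` (names = bands).  When given,
#'   `theta_ratio` is ignored.
#' @param subject_gain_sd Lognormal sdlog of the between-subject gain
#'   spread (default 0.1, small enough that a configured 2x band effect
#'   stays well above the between-subject spread; real cohorts vary more).
#' @param pink_exponent Spectral slope of the 1/f background (PSD ~
#'   `f^-pink_exponent`; default 1).
#' @param pink_gain Amplitude of the pink background (default 0.5; 0
#'   disables it).
#' @param noise_sd White-noise floor standard deviation (default 0.2).
#' @param seed Integer master seed; every subject's signal is fully
#'   determined by `(seed, subject_seed)`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_case = 61, n_control = 60, n_channels = 19,
                         fs = 128, duration_s = 120, theta_ratio = 2,
                         band_gains = NULL, subject_gain_sd = 0.1,
                         pink_exponent = 1, pink_gain = 0.5, noise_sd = 0.2,
                         seed = 1) {
  if (is.null(band_gains)) {
    control <- c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 0.5)
    case <- control
    case[["theta"]] <- control[["theta"]] * theta_ratio
    band_gains <- list(case = case, control = control)
  }
  bands <- names(CANONICAL_BANDS)
  for (cls in c("case", "control")) {
    if (!all(bands %in% names(band_gains[[cls]]))) {
      abort_config(sprintf("`band_gains$%s` must name all bands: %s.",
                           cls, paste(bands, collapse = ", ")))
    }
    if (any(band_gains[[cls]] < 0)) abort_config("Band gains must be >= 0.")
  }
  top_edge <- max(purrr::map_dbl(CANONICAL_BANDS, 2))
  if (fs <= 2 * top_edge) {
    abort_config(sprintf(
      "fs = %g Hz cannot represent the %g Hz band edge (need fs > %g).",
      fs, top_edge, 2 * top_edge
    ))
  }
  if (n_channels < 1 || duration_s <= 0) {
    abort_config("Need >= 1 channel and a positive duration.")
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         n_channels = as.integer(n_channels), fs = fs,
         duration_s = duration_s, band_gains = band_gains,
         subject_gain_sd = subject_gain_sd, pink_exponent = pink_exponent,
         pink_gain = pink_gain, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# band-limited unit-variance Gaussian noise via spectral shaping:
# FFT of white noise, raised-cosine band mask, inverse FFT
band_limited_noise <- function(n, fs, lo, hi, taper = 0.5) {
  f_abs <- abs(((0:(n - 1) + floor(n / 2)) %% n - floor(n / 2)) * fs / n)
  m <- numeric(n)
  m[f_abs >= lo & f_abs <= hi] <- 1
  ramp_lo <- f_abs >= lo - taper & f_abs < lo
  m[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f_abs[ramp_lo]) / taper))
  ramp_hi <- f_abs > hi & f_abs <= hi + taper
  m[ramp_hi] <- 0.5 * (1 + cos(pi * (f_abs[ramp_hi] - hi) / taper))
  x <- Re(fft(fft(rnorm(n)) * m, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

pink_noise <- function(n, fs, exponent) {
  f_abs <- abs(((0:(n - 1) + floor(n / 2)) %% n - floor(n / 2)) * fs / n)
  a <- pmax(f_abs, 1)^(-exponent / 2)
  a[1] <- 0   # no DC
  x <- Re(fft(fft(rnorm(n)) * a, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic subject
#'
#' @param config A [synth_config()].
#' @param label 1 (case) or 0 (control); selects the class band gains.
#' @param subject_seed Integer distinguishing subjects under one config.
#' @param subject_id Subject identifier.
#' @return An [eeg_record()]; the per-subject realized band gains are
#'   attached as attribute `"band_gains"`.
#' @export
generate_subject <- function(config, label, subject_seed,
                             subject_id = sprintf("subj%03d", subject_seed)) {
  stopifnot(inherits(config, "synth_config"))
  if (!label %in% c(0, 1)) abort_config("`label` must be 0 or 1.")
  n <- round(config$duration_s * config$fs)
  gains_mean <- config$band_gains[[if (label == 1) "case" else "control"]]
  bands <- names(CANONICAL_BANDS)
  rec <- withr::with_seed(derive_seed(config$seed, subject_seed), {
    sdl <- config$subject_gain_sd
    subj_gains <- gains_mean[bands] *
      rlnorm(length(bands), meanlog = -sdl^2 / 2, sdlog = sdl)
    data <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      sig <- numeric(n)
      for (b in bands) {
        if (subj_gains[[b]] > 0) {
          edges <- CANONICAL_BANDS[[b]]
          sig <- sig + subj_gains[[b]] *
            band_limited_noise(n, config$fs, edges[1], edges[2])
        }
      }
      if (config$pink_gain > 0) {
        sig <- sig + config$pink_gain * pink_noise(n, config$fs,
                                                   config$pink_exponent)
      }
      if (config$noise_sd > 0) sig <- sig + config$noise_sd * rnorm(n)
      data[ch, ] <- sig
    }
    list(data = data, gains = subj_gains)
  })
  channels <- if (config$n_channels == 19) TEN_TWENTY_19 else
    paste0("ch", seq_len(config$n_channels))
  out <- eeg_record(rec$data, fs = config$fs, channels = channels,
                    subject_id = subject_id, label = label)
  attr(out, "band_gains") <- rec$gains
  out
}

#' Generate a labelled synthetic cohort
#'
#' @param config A [synth_config()].
#' @return An `eeg_cohort`: list with `records` (list of [eeg_record()]),
#'   `subjects` (tibble `subject_id`, `label`, `subject_seed`) and the
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_case < 1 || config$n_control < 1) {
    abort_config("Need at least one subject per class.")
  }
  subjects <- tibble::tibble(
    subject_id = c(sprintf("case%03d", seq_len(config$n_case)),
                   sprintf("ctrl%03d", seq_len(config$n_control))),
    label = c(rep(1L, config$n_case), rep(0L, config$n_control)),
    subject_seed = seq_len(config$n_case + config$n_control)
  )
  records <- unname(Map(function(subject_id, label, subject_seed) {
    generate_subject(config, label, subject_seed, subject_id = subject_id)
  }, subjects$subject_id, subjects$label, subjects$subject_seed))
  structure(list(records = records, subjects = subjects, config = config),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf(
    "<eeg_cohort> %d case + %d control subjects, %d channels @ %g Hz, %g s each\n",
    x$config$n_case, x$config$n_control, x$config$n_channels, x$config$fs,
    x$config$duration_s
  ))
  invisible(x)
}

#' Write a cohort to disk (per-subject files + manifest + ground truth)
#'
#' Writes one recording file per subject, a `manifest.csv`
#' (`path, subject_id, label`) loadable with [read_cohort()], and a
#' `ground_truth.json` with each subject's realized band gains and seed.
#'
#' @param cohort An `eeg_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"edf"`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(cohort$records, function(rec) {
    fn <- paste0(rec$subject_id, ".", format)
    p <- file.path(dir, fn)
    if (format == "csv") write_eeg_csv(rec, p) else write_eeg_edf(rec, p)
    fn
  })
  manifest <- tibble::tibble(
    path = paths,
    subject_id = cohort$subjects$subject_id,
    label = cohort$subjects$label
  )
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp, progress = FALSE)
  truth <- purrr::map2(cohort$records, cohort$subjects$subject_seed,
                       function(rec, s) {
    list(subject_id = rec$subject_id, label = rec$label, subject_seed = s,
         band_gains = as.list(attr(rec, "band_gains")))
  })
  jsonlite::write_json(
    list(seed = cohort$config$seed, fs = cohort$config$fs, subjects = truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(mp)
}
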