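#' Construct an EEG record
#'
#' A record holds one subject's multichannel signal as a channels x samples
#' matrix together with its sampling rate and a binary class label
#' (case = 1, control = 0).
#'
#' @param data Numeric matrix, channels x samples (amplitudes in microvolts,
#'   nominally).
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of channel names, one per row of `data`.
#' @param subject_id Subject identifier string.
#' @param label Binary class label, 1 = case, 0 = control (NA allowed for
#'   unlabelled data that will not reach classification).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channels = rownames(data),
                       subject_id = "subject", label = NA_integer_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_data("`data` must be a numeric channels x samples matrix.")
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      label = as.integer(label),
      fs = as.numeric(fs),
      channels = as.character(channels),
      data = unname(data)
    ),
    class = "eeg_record"
  )
  validate_eeg_record(rec)
}

validate_eeg_record <- function(rec) {
  if (length(rec$fs) != 1 || !is.finite(rec$fs) || rec$fs <= 0) {
    abort_data("Sampling rate `fs` must be a single positive number.")
  }
  if (nrow(rec$data) < 1 || ncol(rec$data) < 1) {
    abort_data("Record must have at least 1 channel and 1 sample.")
  }
  if (length(rec$channels) != nrow(rec$data)) {
    abort_data(sprintf(
      "Channel name count (%d) does not match data rows (%d).",
      length(rec$channels), nrow(rec$data)
    ))
  }
  if (!is.na(rec$label) && !rec$label %in% c(0L, 1L)) {
    abort_data("`label` must be 0 (control), 1 (case) or NA.")
  }
  bad <- which(!is.finite(rec$data), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_data(sprintf(
      "Non-finite value in channel '%s' at sample %d (and possibly others).",
      rec$channels[bad[1, 1]], bad[1, 2]
    ))
  }
  rec
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %s: %d channels x %d samples @ %g Hz (%.1f s), label = %s\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    ifelse(is.na(x$label), "NA", x$label)
  ))
  invisible(x)
}

#' @export
dim.eeg_record <- function(x) dim(x$data)

#' Cut a record into fixed-duration labelled segments
#'
#' Consecutive non-overlapping windows starting at sample 1; a trailing
#' partial window is dropped, so the number of segments is
#' `floor(n_samples / round(duration_s * fs))`.
#'
#' @param record An [eeg_record()].
#' @param duration_s Window duration in seconds (> 0).
#' @return A tibble with one row per segment and columns `subject_id`,
#'   `label`, `fs`, `duration_s`, `segment_index` (0-based) and `data`
#'   (list column of channels x L matrices).
#' @export
segment_record <- function(record, duration_s) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort_config("`duration_s` must be positive.")
  }
  L <- round(duration_s * record$fs)
  n <- ncol(record$data)
  n_seg <- floor(n / L)
  if (n_seg < 1) {
    abort_data(sprintf(
      "Record '%s' (%d samples) is shorter than one %g s window (%d samples).",
      record$subject_id, n, duration_s, L
    ))
  }
  segs <- purrr::map(seq_len(n_seg), function(i) {
    m <- record$data[, ((i - 1) * L + 1):(i * L), drop = FALSE]
    rownames(m) <- record$channels
    m
  })
  tibble::tibble(
    subject_id = record$subject_id,
    label = record$label,
    fs = record$fs,
    duration_s = duration_s,
    segment_index = seq_len(n_seg) - 1L,
    data = segs
  )
}

#' Segment every record of a cohort
#'
#' @param records A list of [eeg_record()] objects, or an `eeg_cohort`.
#' @param duration_s Window duration in seconds.
#' @return Row-bound segment tibble (see [segment_record()]).
#' @export
segment_cohort <- function(records, duration_s) {
  if (inherits(records, "eeg_cohort")) records <- records$records
  if (length(records) == 0) abort_data("No records to segment.")
  dplyr::bind_rows(lapply(records, segment_record, duration_s = duration_s))
}
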