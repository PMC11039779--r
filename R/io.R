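#' Read an EEG recording from disk
#'
#' CSV files hold one column per channel (header row = channel names) and
#' one row per sample; they carry no sampling rate, so `fs_override` is
#' required.  EDF files carry their own rate and channel labels.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param label Binary class label to attach (1 = case, 0 = control).
#' @param fs_override Sampling rate in Hz; required for CSV, optional
#'   override for EDF.
#' @param subject_id Subject id; defaults to the file name without extension.
#' @return An [eeg_record()].
#' @export
read_eeg_record <- function(path, format = c("auto", "csv", "edf"),
                            label = NA_integer_, fs_override = NULL,
                            subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("File not found: '%s'.", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "csv", edf = "edf",
      abort_config(sprintf("Cannot infer format from extension '.%s'.", ext))
    )
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  switch(format,
    csv = read_eeg_csv(path, fs = fs_override, label = label,
                       subject_id = subject_id),
    edf = read_eeg_edf(path, label = label, fs_override = fs_override,
                       subject_id = subject_id)
  )
}

#' @rdname read_eeg_record
#' @param fs Sampling rate in Hz (CSV files carry none).
#' @export
read_eeg_csv <- function(path, fs, label = NA_integer_,
                         subject_id = tools::file_path_sans_ext(basename(path))) {
  if (missing(fs) || is.null(fs)) {
    abort_config("CSV recordings carry no sampling rate: supply `fs` (fs_override).")
  }
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(tb) < 1 || nrow(tb) < 1) abort_io(sprintf("Empty recording: '%s'.", path))
  m <- t(as.matrix(tb))
  if (!is.numeric(m)) abort_data(sprintf("Non-numeric values in '%s'.", path))
  eeg_record(m, fs = fs, channels = names(tb), subject_id = subject_id,
             label = label)
}

#' Write an EEG record as CSV (samples x channels, header = channel names)
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  tb <- tibble::as_tibble(t(record$data), .name_repair = "minimal")
  names(tb) <- record$channels
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------
# Minimal but format-conformant reader/writer: ASCII header of 256 bytes plus
# 256 per signal, then data records of little-endian int16 samples scaled
# between the per-signal physical and digital ranges.

edf_field <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), width = 1, format = "g")
  if (nchar(s) > width) s <- formatC(x, digits = width - 3, format = "g")
  edf_field(s, width)
}

#' Write an EEG record as a 16-bit EDF file
#'
#' Amplitudes are quantized to the signed 16-bit range between each
#' channel's physical minimum and maximum, as the format prescribes.
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  nch <- nrow(record$data)
  n <- ncol(record$data)
  fs <- record$fs
  if (fs == round(fs) && n %% fs == 0) {
    spr <- as.integer(fs); n_rec <- as.integer(n / fs); rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / fs
  }
  dmin <- -32767L; dmax <- 32767L
  pmin_s <- character(nch); pmax_s <- character(nch)
  for (c in seq_len(nch)) {
    r <- range(record$data[c, ])
    if (r[1] == r[2]) r <- r + c(-1, 1)
    # widen before formatting so the low-precision header range still
    # covers every sample (values are clamped to the digital range below)
    span <- r[2] - r[1]
    pmin_s[c] <- edf_num(r[1] - 0.005 * span, 8)
    pmax_s[c] <- edf_num(r[2] + 0.005 * span, 8)
  }
  phys_lo <- as.numeric(pmin_s); phys_hi <- as.numeric(pmax_s)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(record$subject_id, 80),
    edf_field("gaboreeg export", 80),
    edf_field("01.01.01", 8), edf_field("00.00.00", 8),
    edf_field(256 * (nch + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_num(rec_dur, 8),
    edf_field(nch, 4),
    paste(vapply(record$channels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field("uV", 8), nch), collapse = ""),
    paste(pmin_s, collapse = ""), paste(pmax_s, collapse = ""),
    paste(rep(edf_field(dmin, 8), nch), collapse = ""),
    paste(rep(edf_field(dmax, 8), nch), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field(spr, 8), nch), collapse = ""),
    paste(rep(edf_field("", 32), nch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  dig <- matrix(0L, nrow = nch, ncol = n)
  for (c in seq_len(nch)) {
    dig[c, ] <- as.integer(pmin(pmax(round(
      (record$data[c, ] - phys_lo[c]) / (phys_hi[c] - phys_lo[c]) *
        (dmax - dmin) + dmin
    ), dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' @rdname read_eeg_record
#' @export
read_eeg_edf <- function(path, label = NA_integer_, fs_override = NULL,
                         subject_id = NULL) {
  if (!file.exists(path)) abort_io(sprintf("File not found: '%s'.", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                      # version
  pat <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1 || is.na(n_rec) || n_rec < 1) {
    abort_io(sprintf("Unreadable EDF header in '%s'.", path))
  }
  sig_field <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- sig_field(16); sig_field(80); sig_field(8)
  pmin <- as.numeric(sig_field(8)); pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)
  spr <- as.integer(sig_field(8)); sig_field(32)
  if (length(unique(spr)) != 1) {
    abort_io("Signals with differing sampling rates are not supported.")
  }
  spr <- spr[1]
  n <- n_rec * spr
  data <- matrix(NA_real_, nrow = nch, ncol = n)
  for (r in seq_len(n_rec)) {
    for (c in seq_len(nch)) {
      raw <- readBin(con, "integer", n = spr, size = 2, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr) abort_io(sprintf("Truncated EDF data in '%s'.", path))
      data[c, ((r - 1) * spr + 1):(r * spr)] <-
        (raw - dmin[c]) * (pmax[c] - pmin[c]) / (dmax[c] - dmin[c]) + pmin[c]
    }
  }
  fs <- fs_override %||% (spr / rec_dur)
  eeg_record(data, fs = fs, channels = labels,
             subject_id = subject_id %||% (if (nzchar(pat)) pat else
               tools::file_path_sans_ext(basename(path))),
             label = label)
}

#' Load a cohort from a manifest file
#'
#' The manifest is a CSV with columns `path`, `subject_id`, `label`;
#' relative paths resolve against the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param fs_override Sampling rate for CSV recordings (Hz).
#' @return A list of [eeg_record()] objects.
#' @export
read_cohort <- function(manifest_path, fs_override = NULL) {
  if (!file.exists(manifest_path)) {
    abort_io(sprintf("Manifest not found: '%s'.", manifest_path))
  }
  mf <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  need <- c("path", "subject_id", "label")
  if (!all(need %in% names(mf))) {
    abort_config("Manifest must have columns path, subject_id, label.")
  }
  base <- dirname(manifest_path)
  Map(function(path, subject_id, label) {
    p <- if (file.exists(path)) path else file.path(base, path)
    read_eeg_record(p, label = as.integer(label), fs_override = fs_override,
                    subject_id = as.character(subject_id))
  }, mf$path, mf$subject_id, mf$label) |> unname()
}
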