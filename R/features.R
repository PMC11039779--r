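#' Four summary statistics of a magnitude envelope
#'
#' Computes Shannon entropy, sample standard deviation, skewness and excess
#' kurtosis of a non-negative series.  Entropy is taken over the histogram
#' probability mass of `entropy_bins` equal-width bins spanning the series'
#' own `[min, max]` (natural log; empty bins contribute 0), which makes it
#' invariant to positive rescaling.  Skewness and kurtosis use central
#' moments with an `n` denominator (`skew = m3/m2^1.5`,
#' `kurt = m4/m2^2 - 3`); the standard deviation uses `n - 1`.  A
#' zero-variance series returns `(0, 0, 0, 0)` by convention and is flagged
#' via the `"degenerate"` attribute.
#'
#' @param x Non-negative numeric series of length >= 2.
#' @param entropy_bins Number of histogram bins for the entropy (default 256).
#' @return Named numeric vector `(entropy, std, skew, kurt)` with logical
#'   attribute `degenerate`.
#' @export
compute_statistics <- function(x, entropy_bins = 256) {
  if (length(x) < 2) abort_data("Need at least 2 samples to compute statistics.")
  if (any(!is.finite(x))) abort_data("Non-finite values in series.")
  if (any(x < 0)) abort_data("Magnitude series must be non-negative.")
  if (entropy_bins < 1) abort_config("`entropy_bins` must be >= 1.")
  n <- length(x)
  m <- sum(x) / n
  xc <- x - m
  m2 <- sum(xc^2) / n
  if (m2 == 0) {
    out <- c(entropy = 0, std = 0, skew = 0, kurt = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  std <- sqrt(sum(xc^2) / (n - 1))
  skew <- (sum(xc^3) / n) / m2^1.5
  kurt <- (sum(xc^4) / n) / m2^2 - 3
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = entropy_bins + 1L)
  counts <- tabulate(.bincode(x, breaks, include.lowest = TRUE), entropy_bins)
  p <- counts[counts > 0] / n
  entropy <- -sum(p * log(p))
  out <- c(entropy = entropy, std = std, skew = skew, kurt = kurt)
  attr(out, "degenerate") <- FALSE
  out
}

STAT_NAMES <- c("entropy", "std", "skew", "kurt")

#' Flatten a bank response into a named feature vector
#'
#' One 4-statistic block per (channel, filter) pair, concatenated
#' channel-major: for channel `c`, filter `k`, the names are
#' `ch{c}_f{k}_entropy`, `ch{c}_f{k}_std`, `ch{c}_f{k}_skew`,
#' `ch{c}_f{k}_kurt`.  Length is `n_channels * n_filters * 4`.
#'
#' @param response A `bank_response` from [apply_filter_bank()].
#' @param entropy_bins Histogram bins for the entropy statistic.
#' @return Named numeric vector; attribute `degenerate` lists the names of
#'   any zero-variance blocks.
#' @export
extract_features <- function(response, entropy_bins = 256) {
  stopifnot(inherits(response, "bank_response"))
  d <- dim(response)
  n_filters <- d[1]; n_channels <- d[2]
  vals <- numeric(n_channels * n_filters * 4L)
  nms <- character(length(vals))
  degen <- character(0)
  i <- 0L
  for (c in seq_len(n_channels)) {
    for (k in seq_len(n_filters)) {
      s <- tryCatch(
        compute_statistics(response[k, c, ], entropy_bins = entropy_bins),
        gaboreeg_data_error = function(e) {
          abort_data(sprintf("Channel %d, filter %d: %s", c, k, conditionMessage(e)))
        }
      )
      block <- paste0("ch", c, "_f", k, "_", STAT_NAMES)
      if (isTRUE(attr(s, "degenerate"))) degen <- c(degen, block[1])
      vals[i + 1:4] <- s
      nms[i + 1:4] <- block
      i <- i + 4L
    }
  }
  names(vals) <- nms
  attr(vals, "degenerate") <- degen
  vals
}

#' Build a feature matrix from labelled segments
#'
#' Runs every segment through the bank and stacks the resulting feature
#' vectors into one tibble row per segment.
#'
#' @param segments Segment tibble from [segment_record()]/[segment_cohort()].
#' @param bank A [gabor_bank()].
#' @param entropy_bins Histogram bins for the entropy statistic.
#' @return A tibble with columns `subject_id`, `segment_index`, `label` and
#'   one column per feature (`n_channels * n_filters * 4` of them).
#' @export
build_feature_matrix <- function(segments, bank, entropy_bins = 256) {
  if (!is.data.frame(segments) || nrow(segments) == 0) {
    abort_data("Empty segment list: nothing to extract features from.")
  }
  ncs <- purrr::map_int(segments$data, nrow)
  if (length(unique(ncs)) != 1) {
    bad <- unique(segments$subject_id[ncs != ncs[1]])
    abort_data(paste0(
      "Heterogeneous channel counts across segments; offending subjects: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (length(unique(segments$fs)) != 1) {
    abort_data("Segments mix sampling rates; resample before extraction.")
  }
  rows <- Map(function(m, fs) {
    extract_features(apply_filter_bank(m, bank, fs = fs),
                     entropy_bins = entropy_bins)
  }, segments$data, segments$fs)
  feat <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = segments$subject_id,
      segment_index = segments$segment_index,
      label = segments$label
    ),
    feat
  )
  attr(out, "bank_name") <- attr(bank, "bank_name")
  attr(out, "entropy_bins") <- entropy_bins
  out
}

#' Write / read a feature matrix as CSV
#'
#' Column order is `subject_id`, `segment_index`, `label`, then the feature
#' columns in their canonical order, so files round-trip bit-stably.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param path CSV path.
#' @return The path (write) or the feature tibble (read).
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Feature file not found: '%s'.", path))
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(ID_COLS %in% names(tb))) {
    abort_config("Feature file lacks subject_id/segment_index/label columns.")
  }
  tb$label <- as.integer(tb$label)
  tb
}
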