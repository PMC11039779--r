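#' Plot the frequency responses of a Gabor bank
#'
#' Draws `|G(f)|` for every filter over `(0, fs/2)`, normalized to unit
#' peak, with the canonical EEG band edges marked.
#'
#' @param object A [gabor_bank()].
#' @param fs Sampling rate in Hz (default 128).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gabor_bank
#' @export
autoplot.gabor_bank <- function(object, fs = 128, ...) {
  freq <- seq(0.1, fs / 2 - 0.1, length.out = 400)
  kernels <- bank_kernels(object, fs)
  df <- purrr::imap_dfr(kernels, function(k, i) {
    g <- Mod(kernel_freq_response(k, freq))
    tibble::tibble(filter = factor(paste0("f", i, " (", k$fc, " Hz)")),
                   freq = freq, gain = g / max(g))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$gain,
                                   colour = .data$filter)) +
    ggplot2::geom_vline(xintercept = c(4, 8, 13, 30), linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalized |G(f)|",
                  colour = NULL,
                  title = paste("Gabor bank", attr(object, "bank_name")),
                  subtitle = paste("sigma interpreted as",
                                   attr(object, "sigma_domain"))) +
    ggplot2::theme_minimal()
}

#' Plot magnitude envelopes of a bank response
#'
#' One facet per filter, showing the narrow-band amplitude envelope of a
#' chosen channel over time.
#'
#' @param object A `bank_response` from [apply_filter_bank()].
#' @param channel Channel index or name (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bank_response
#' @export
autoplot.bank_response <- function(object, channel = 1, ...) {
  fs <- attr(object, "fs")
  if (is.character(channel)) {
    channel <- match(channel, dimnames(object)$channel)
  }
  d <- dim(object)
  df <- purrr::map_dfr(seq_len(d[1]), function(k) {
    tibble::tibble(filter = factor(dimnames(object)$filter[k]),
                   time = (seq_len(d[3]) - 1) / fs,
                   magnitude = object[k, channel, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$magnitude)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2c7fb8") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$filter), scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "|z(t)|") +
    ggplot2::theme_minimal()
}

#' Plot per-fold evaluation metrics
#'
#' Bars for the pooled accuracy / sensitivity / specificity with per-fold
#' points overlaid (cross-validation results only have multiple folds).
#'
#' @param object An `eeg_eval` from [evaluate_cv()] / [evaluate_split()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eeg_eval
#' @export
autoplot.eeg_eval <- function(object, ...) {
  pooled <- tibble::tibble(
    metric = factor(c("Acc", "Sn", "Sp"), levels = c("Acc", "Sn", "Sp")),
    value = c(object$acc, object$sn, object$sp)
  )
  folds <- tidyr::pivot_longer(
    object$per_fold[, c("fold", "acc", "sn", "sp")],
    cols = c("acc", "sn", "sp"), names_to = "metric", values_to = "value"
  )
  folds$metric <- factor(c(acc = "Acc", sn = "Sn", sp = "Sp")[folds$metric],
                         levels = c("Acc", "Sn", "Sp"))
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#a6bddb", width = 0.6) +
    ggplot2::geom_jitter(data = folds, width = 0.08, alpha = 0.6, size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "%",
                  title = sprintf("%s / %s / %s", object$scheme,
                                  toupper(object$config$classifier),
                                  object$config$selection)) +
    ggplot2::theme_minimal()
}

#' Plot feature-selection scores
#'
#' Lollipop chart of the top-scoring features, selected ones highlighted.
#'
#' @param object A `feature_selection`.
#' @param top_n How many features to show (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_selection
#' @export
autoplot.feature_selection <- function(object, top_n = 30, ...) {
  tb <- tidy(object)
  tb <- dplyr::slice_max(tb, abs(.data$score), n = top_n)
  tb$feature <- stats::reorder(tb$feature, abs(tb$score))
  ggplot2::ggplot(tb, ggplot2::aes(x = abs(.data$score), y = .data$feature,
                                   colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature),
                          linewidth = 0.3) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = paste0("|", object$method, " score|"), y = NULL,
                  colour = "selected") +
    ggplot2::theme_minimal()
}
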