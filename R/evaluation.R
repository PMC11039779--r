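#' Evaluation configuration
#'
#' Bundles the classifier, the feature-selection rule, the validation
#' scheme parameters and the split unit for [evaluate_cv()] /
#' [evaluate_split()].
#'
#' @param classifier `"svm"` (RBF kernel, cost 1, gamma
#'   `1/(n_features * mean feature variance)` unless overridden) or `"knn"`
#'   (k = 5, Euclidean).
#' @param classifier_params Named list overriding classifier defaults
#'   (`cost`, `gamma`, `kernel` for SVM; `k` for k-NN).
#' @param selection `"none"`, `"ttest"` or `"chi2"`; always fitted on the
#'   training partition only.
#' @param selection_params Named list passed to [ttest_select()] /
#'   [chi2_select()] (e.g. `alpha`, `top_k`, `mode`).  `chi2` defaults to
#'   keeping half the features.
#' @param split_unit `"segment"` (each window is an independent unit; note
#'   that windows of one subject may then straddle train and test) or
#'   `"subject"` (all windows of a subject stay together).
#' @param folds Number of CV folds (default 10).
#' @param train_frac Training fraction for the holdout split (default 0.8).
#' @param standardize Z-score features using training-partition statistics
#'   (default `TRUE`).
#' @param seed Integer seed controlling fold assignment / the split and any
#'   classifier tie-breaking.
#' @return An `eval_config` list.
#' @export
eval_config <- function(classifier = c("svm", "knn"),
                        classifier_params = list(),
                        selection = c("ttest", "none", "chi2"),
                        selection_params = list(),
                        split_unit = c("segment", "subject"),
                        folds = 10, train_frac = 0.8,
                        standardize = TRUE, seed = 1) {
  cfg <- list(
    classifier = match.arg(classifier),
    classifier_params = classifier_params,
    selection = match.arg(selection),
    selection_params = selection_params,
    split_unit = match.arg(split_unit),
    folds = as.integer(folds),
    train_frac = train_frac,
    standardize = isTRUE(standardize),
    seed = as.integer(seed)
  )
  if (cfg$folds < 2) abort_config("`folds` must be >= 2.")
  if (train_frac <= 0 || train_frac >= 1) {
    abort_config("`train_frac` must be in (0, 1).")
  }
  structure(cfg, class = "eval_config")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Case (label 1) is the positive class.  `acc = 100*(TP+TN)/total`,
#' `sn = 100*TP/(TP+FN)`, `sp = 100*TN/(TN+FP)`; a ratio with a zero
#' denominator is reported as `NA`, never as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Named list with `acc`, `sn`, `sp` (percentages).
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_data("Confusion counts must be non-negative integers.")
  }
  total <- sum(counts)
  if (total == 0) abort_data("Empty confusion: total count is 0.")
  list(
    acc = 100 * (tp + tn) / total,
    sn = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    sp = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  )
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == 1 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0))
}

# stratified fold assignment; returns an integer fold id per row
make_folds <- function(y, groups, split_unit, k, seed) {
  if (split_unit == "subject") {
    gl <- tapply(y, groups, function(v) {
      if (length(unique(v)) != 1) {
        abort_data("A subject carries more than one class label.")
      }
      v[1]
    })
    subj <- names(gl)
    for (cls in c(0, 1)) {
      if (sum(gl == cls) < k) {
        abort_data(sprintf(
          "Only %d class-%d subjects for %d folds; reduce `folds`.",
          sum(gl == cls), cls, k
        ))
      }
    }
    subj_fold <- stats::setNames(integer(length(subj)), subj)
    withr::with_seed(seed, {
      for (cls in c(0, 1)) {
        s <- sample(subj[gl == cls])
        subj_fold[s] <- rep_len(seq_len(k), length(s))
      }
    })
    unname(subj_fold[as.character(groups)])
  } else {
    for (cls in c(0, 1)) {
      if (sum(y == cls) < k) {
        abort_data(sprintf(
          "Only %d class-%d rows for %d folds; reduce `folds`.",
          sum(y == cls), cls, k
        ))
      }
    }
    fold <- integer(length(y))
    withr::with_seed(seed, {
      for (cls in c(0, 1)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    fold
  }
}

fit_selection <- function(train_features, method, params) {
  nms <- feature_names(train_features)
  switch(method,
    none = NULL,
    ttest = do.call(ttest_select, c(list(features = train_features),
                                    params[intersect(names(params),
                                      c("mode", "alpha", "top_k", "var_equal"))])),
    chi2 = chi2_select(train_features,
                       top_k = params$top_k %||% ceiling(length(nms) / 2))
  )
}

fit_predict <- function(Xtr, ytr, Xte, classifier, params, seed) {
  if (ncol(Xtr) == 0) {
    abort_config("No features selected: classifier refuses an empty feature set.")
  }
  ytr_f <- factor(ytr, levels = c(0, 1))
  pred <- withr::with_seed(seed, {
    if (classifier == "svm") {
      v <- mean(apply(Xtr, 2, var))
      gamma <- params$gamma %||% (1 / (ncol(Xtr) * max(v, .Machine$double.eps)))
      m <- e1071::svm(Xtr, ytr_f, kernel = params$kernel %||% "radial",
                      cost = params$cost %||% 1, gamma = gamma, scale = FALSE)
      predict(m, Xte)
    } else {
      class::knn(Xtr, Xte, ytr_f, k = params$k %||% 5)
    }
  })
  as.integer(as.character(pred))
}

# standardize -> select -> classify, all fitted on the training rows only
eval_partition <- function(features, train_idx, test_idx, cfg, fold_seed) {
  nms <- feature_names(features)
  tr <- features[train_idx, , drop = FALSE]
  te <- features[test_idx, , drop = FALSE]
  if (cfg$standardize) {
    mu <- purrr::map_dbl(tr[nms], mean)
    sdv <- purrr::map_dbl(tr[nms], sd)
    sdv[sdv == 0] <- 1
    tr[nms] <- purrr::map2(tr[nms], seq_along(nms),
                           function(col, j) (col - mu[j]) / sdv[j])
    te[nms] <- purrr::map2(te[nms], seq_along(nms),
                           function(col, j) (col - mu[j]) / sdv[j])
  }
  sel <- fit_selection(tr, cfg$selection, cfg$selection_params)
  if (!is.null(sel)) {
    tr <- apply_selection(tr, sel)
    te <- apply_selection(te, sel)
  }
  used <- feature_names(tr)
  pred <- fit_predict(as.matrix(tr[used]), tr$label, as.matrix(te[used]),
                      cfg$classifier, cfg$classifier_params, fold_seed)
  list(confusion = confusion_counts(te$label, pred),
       n_features = length(used),
       selected = used)
}

new_eval_result <- function(scheme, confusion, per_fold, row_assignment,
                            n_features_used, selected, cfg, n_rows) {
  m <- compute_metrics(confusion[["tp"]], confusion[["tn"]],
                       confusion[["fp"]], confusion[["fn"]])
  structure(
    list(scheme = scheme, confusion = confusion,
         acc = m$acc, sn = m$sn, sp = m$sp,
         per_fold = per_fold, row_assignment = row_assignment,
         n_features_used = n_features_used, selected = selected,
         config = cfg, n_rows = n_rows,
         leakage_note = if (cfg$split_unit == "segment")
           paste("split_unit = 'segment': windows of one subject may occur",
                 "in both train and test; use split_unit = 'subject' to rule",
                 "out within-subject leakage.") else NULL),
    class = "eeg_eval"
  )
}

#' Stratified k-fold cross-validation of the classification pipeline
#'
#' Per fold, the standardizer and the feature selection are fitted on the
#' training fold only, the classifier is trained, and the test-fold
#' confusion is accumulated; the pooled confusion plus per-fold detail are
#' returned.  Fold assignment is stratified by class over the chosen split
#' unit and fully determined by `config$seed`.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param config An [eval_config()].
#' @return An `eeg_eval` object (see [compute_metrics()] for the metric
#'   definitions); `row_assignment` records each row's fold.
#' @export
evaluate_cv <- function(features, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  y <- features$label
  check_two_classes(y)
  folds <- make_folds(y, features$subject_id, config$split_unit,
                      config$folds, config$seed)
  per <- vector("list", config$folds)
  pooled <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  selected <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    res <- eval_partition(features, which(folds != f), which(folds == f),
                          config, derive_seed(config$seed, f))
    pooled <- pooled + res$confusion
    m <- compute_metrics(res$confusion[["tp"]], res$confusion[["tn"]],
                         res$confusion[["fp"]], res$confusion[["fn"]])
    per[[f]] <- tibble::tibble(
      fold = f, tp = res$confusion[["tp"]], tn = res$confusion[["tn"]],
      fp = res$confusion[["fp"]], fn = res$confusion[["fn"]],
      acc = m$acc, sn = m$sn, sp = m$sp, n_features = res$n_features
    )
    selected[[f]] <- res$selected
  }
  per_fold <- dplyr::bind_rows(per)
  new_eval_result(
    scheme = paste0("cv", config$folds),
    confusion = pooled, per_fold = per_fold, row_assignment = folds,
    n_features_used = as.integer(round(mean(per_fold$n_features))),
    selected = selected, cfg = config, n_rows = nrow(features)
  )
}

#' Stratified holdout (80:20 by default) evaluation
#'
#' One stratified train/test split over the chosen split unit, the same
#' fit-on-train-only discipline as [evaluate_cv()], and the test confusion.
#'
#' @inheritParams evaluate_cv
#' @return An `eeg_eval`; `row_assignment` is `"train"`/`"test"` per row.
#' @export
evaluate_split <- function(features, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  y <- features$label
  check_two_classes(y)
  units <- if (config$split_unit == "subject") {
    as.character(features$subject_id)
  } else {
    as.character(seq_len(nrow(features)))
  }
  ul <- tapply(y, units, function(v) {
    if (length(unique(v)) != 1) abort_data("A subject carries more than one class label.")
    v[1]
  })
  test_units <- withr::with_seed(config$seed, {
    unlist(lapply(c(0, 1), function(cls) {
      u <- sample(names(ul)[ul == cls])
      n_test <- max(1L, round((1 - config$train_frac) * length(u)))
      if (n_test >= length(u)) {
        abort_data(sprintf(
          "Class %d has too few units (%d) for a %d:%d split.",
          cls, length(u), round(100 * config$train_frac),
          round(100 * (1 - config$train_frac))
        ))
      }
      u[seq_len(n_test)]
    }))
  })
  is_test <- units %in% test_units
  if (length(unique(y[is_test])) < 2 || length(unique(y[!is_test])) < 2) {
    abort_data("A class is absent from the train or test partition; use subject stratification or another seed.")
  }
  res <- eval_partition(features, which(!is_test), which(is_test), config,
                        derive_seed(config$seed, 0L))
  m <- compute_metrics(res$confusion[["tp"]], res$confusion[["tn"]],
                       res$confusion[["fp"]], res$confusion[["fn"]])
  per_fold <- tibble::tibble(
    fold = 1L, tp = res$confusion[["tp"]], tn = res$confusion[["tn"]],
    fp = res$confusion[["fp"]], fn = res$confusion[["fn"]],
    acc = m$acc, sn = m$sn, sp = m$sp, n_features = res$n_features
  )
  new_eval_result(
    scheme = sprintf("split%d%d", round(100 * config$train_frac),
                     round(100 * (1 - config$train_frac))),
    confusion = res$confusion, per_fold = per_fold,
    row_assignment = ifelse(is_test, "test", "train"),
    n_features_used = res$n_features, selected = list(res$selected),
    cfg = config, n_rows = nrow(features)
  )
}

#' @export
print.eeg_eval <- function(x, ...) {
  cfg <- x$config
  fs_lab <- switch(cfg$selection, none = "Without FS", ttest = "t-test",
                   chi2 = "Chi-square")
  cat("<eeg_eval>\n")
  cat(sprintf("  %-12s %-10s %-11s %6s %6s %6s %12s\n",
              "Validation", "Classifier", "FS", "Acc", "Sn", "Sp",
              "No. of feat."))
  cat(sprintf("  %-12s %-10s %-11s %6.1f %6.2f %6.2f %12d\n",
              x$scheme, toupper(cfg$classifier), fs_lab,
              x$acc, x$sn, x$sp, x$n_features_used))
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d (n=%d, split by %s, seed %d)\n",
              x$confusion[["tp"]], x$confusion[["tn"]], x$confusion[["fp"]],
              x$confusion[["fn"]], x$n_rows, cfg$split_unit, cfg$seed))
  if (!is.null(x$leakage_note)) cat("  note:", x$leakage_note, "\n")
  invisible(x)
}

#' Tidy and summarise fitted objects
#'
#' `tidy()` returns per-fold (or per-feature) detail; `glance()` returns a
#' one-row summary.
#'
#' @param x A `feature_selection` or `eeg_eval` object.
#' @param ... Unused.
#' @name generics_methods
NULL

#' @rdname generics_methods
#' @method tidy eeg_eval
#' @export
tidy.eeg_eval <- function(x, ...) x$per_fold

#' @rdname generics_methods
#' @method glance eeg_eval
#' @export
glance.eeg_eval <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    classifier = x$config$classifier,
    selection = x$config$selection,
    acc = x$acc, sn = x$sn, sp = x$sp,
    n_features = x$n_features_used,
    n_rows = x$n_rows,
    seed = x$config$seed
  )
}

#' Serialize an evaluation result to JSON
#'
#' @param result An `eeg_eval`.
#' @param path JSON path.
#' @export
write_eval_json <- function(result, path) {
  stopifnot(inherits(result, "eeg_eval"))
  jsonlite::write_json(
    list(
      scheme = result$scheme,
      confusion = as.list(result$confusion),
      metrics = list(acc = result$acc, sn = result$sn, sp = result$sp),
      per_fold = result$per_fold,
      n_features_used = result$n_features_used,
      config = result$config[c("classifier", "selection", "split_unit",
                               "folds", "train_frac", "standardize", "seed")],
      leakage_note = result$leakage_note
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
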