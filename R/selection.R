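new_selection <- function(method, scores, p_values, selected, params, all_names,
                          flagged = character(0)) {
  structure(
    list(method = method, scores = scores, p_values = p_values,
         selected = selected, params = params, all_names = all_names,
         flagged = flagged),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> method = %s: %d / %d features kept\n",
              x$method, length(x$selected), length(x$all_names)))
  invisible(x)
}

check_two_classes <- function(y, min_per_class = 1) {
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab < min_per_class)) {
    abort_data(sprintf(
      "Both classes must be present with >= %d rows each (have %d control, %d case).",
      min_per_class, tab[["0"]], tab[["1"]]
    ))
  }
}

# Vectorised per-column two-sample t statistics (Welch by default).
# Columns with zero variance in both classes get t = 0, p = 1.
welch_t_stats <- function(X, y, var_equal = FALSE) {
  i1 <- y == 1; i0 <- y == 0
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[i0, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, var)
  v0 <- apply(X[i0, , drop = FALSE], 2, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2, ncol(X))
  } else {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  flat <- se2 == 0
  t <- ifelse(flat, 0, (m1 - m0) / sqrt(ifelse(flat, 1, se2)))
  p <- ifelse(flat, 1, 2 * pt(-abs(t), ifelse(flat | !is.finite(df), 1, df)))
  list(t = t, p = p, flat = flat)
}

#' Rank features by a two-sample t-test
#'
#' Computes a per-feature two-sample t statistic (Welch by default) between
#' case and control rows and keeps either every feature with `p < alpha`
#' (`mode = "alpha"`) or the `top_k` smallest p-values (`mode = "top_k"`).
#' Ties are broken by larger `|t|`, then by lower column index.  Features
#' with zero variance in both classes get `t = 0`, `p = 1`, are never
#' selected, and are flagged.
#'
#' @param features Training feature tibble (both classes present, >= 2 rows
#'   per class).
#' @param mode `"alpha"` or `"top_k"`.
#' @param alpha Two-sided p-value threshold (default 0.05).
#' @param top_k Number of features to keep in `top_k` mode.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `feature_selection` object.
#' @export
ttest_select <- function(features, mode = c("alpha", "top_k"), alpha = 0.05,
                         top_k = NULL, var_equal = FALSE) {
  mode <- match.arg(mode)
  nms <- feature_names(features)
  y <- features$label
  check_two_classes(y, min_per_class = 2)
  X <- as.matrix(features[nms])
  st <- welch_t_stats(X, y, var_equal = var_equal)
  ord <- order(st$p, -abs(st$t), seq_along(nms))
  if (mode == "alpha") {
    if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
      abort_config("`alpha` must be in (0, 1].")
    }
    keep <- ord[st$p[ord] < alpha]
    params <- list(mode = "alpha", alpha = alpha, var_equal = var_equal)
  } else {
    if (is.null(top_k) || top_k < 0) abort_config("Supply `top_k` >= 0.")
    if (top_k > length(nms)) {
      warn(sprintf("top_k = %d exceeds %d features; keeping all.",
                   top_k, length(nms)))
      top_k <- length(nms)
    }
    keep <- ord[seq_len(top_k)]
    keep <- keep[!st$flat[keep]]
    params <- list(mode = "top_k", top_k = top_k, var_equal = var_equal)
  }
  new_selection(
    method = "ttest",
    scores = stats::setNames(st$t, nms),
    p_values = stats::setNames(st$p, nms),
    selected = nms[keep],
    params = params,
    all_names = nms,
    flagged = nms[st$flat]
  )
}

# chi-square class-association score on train-min-max-scaled features
chi2_stats <- function(X, y) {
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  rng <- maxs - mins
  Xs <- sweep(X, 2, mins)
  Xs <- sweep(Xs, 2, ifelse(rng == 0, 1, rng), "/")
  n <- nrow(Xs)
  total <- colSums(Xs)
  score <- numeric(ncol(Xs))
  for (cls in c(0, 1)) {
    obs <- colSums(Xs[y == cls, , drop = FALSE])
    exp_ <- total * sum(y == cls) / n
    term <- ifelse(exp_ == 0, 0, (obs - exp_)^2 / ifelse(exp_ == 0, 1, exp_))
    score <- score + term
  }
  list(score = score, flat = rng == 0)
}

#' Rank features by a chi-square class-association score
#'
#' Each feature is min-max scaled to `[0, 1]` on the training rows (the
#' score requires non-negative values); the score is
#' `sum_c (O_c - E_c)^2 / E_c`, where `O_c` is the scaled-feature sum over
#' class-`c` rows and `E_c` the total scaled sum times the class prior.
#' The `top_k` highest-scoring features are kept (ties to lower index);
#' constant features score 0.
#'
#' @param features Training feature tibble (both classes present).
#' @param top_k Number of features to keep (clamped with a warning if it
#'   exceeds the feature count; 0 yields an empty selection).
#' @return A `feature_selection` object.
#' @export
chi2_select <- function(features, top_k) {
  nms <- feature_names(features)
  y <- features$label
  check_two_classes(y)
  if (missing(top_k) || is.null(top_k) || top_k < 0) {
    abort_config("Supply `top_k` >= 0.")
  }
  if (top_k > length(nms)) {
    warn(sprintf("top_k = %d exceeds %d features; keeping all.",
                 top_k, length(nms)))
    top_k <- length(nms)
  }
  X <- as.matrix(features[nms])
  st <- chi2_stats(X, y)
  ord <- order(-st$score, seq_along(nms))
  keep <- ord[seq_len(top_k)]
  new_selection(
    method = "chi2",
    scores = stats::setNames(st$score, nms),
    p_values = NULL,
    selected = nms[keep],
    params = list(top_k = top_k),
    all_names = nms,
    flagged = nms[st$flat]
  )
}

#' Apply a fitted selection to a feature matrix
#'
#' Guards against schema drift: the matrix must carry exactly the feature
#' names the selection was fitted on.
#'
#' @param features Feature tibble (train or test rows).
#' @param selection A `feature_selection`, or the string `"none"` for the
#'   identity.
#' @return The feature tibble restricted to the selected columns, in
#'   selected order (id columns kept).
#' @export
apply_selection <- function(features, selection) {
  if (identical(selection, "none")) return(features)
  stopifnot(inherits(selection, "feature_selection"))
  if (selection$method == "none") return(features)
  if (!identical(selection$all_names, feature_names(features))) {
    abort_config("Feature names differ from those the selection was fitted on.")
  }
  dplyr::select(features, dplyr::all_of(c(
    intersect(ID_COLS, names(features)), selection$selected
  )))
}

#' Serialize a selection result to JSON (and back)
#'
#' @param selection A `feature_selection`.
#' @param path JSON path.
#' @export
write_selection_json <- function(selection, path) {
  stopifnot(inherits(selection, "feature_selection"))
  jsonlite::write_json(
    list(method = selection$method, params = selection$params,
         scores = as.list(selection$scores),
         p_values = if (is.null(selection$p_values)) NULL else
           as.list(selection$p_values),
         selected = selection$selected, flagged = selection$flagged),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname generics_methods
#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) {
  tb <- tibble::tibble(
    feature = x$all_names,
    score = unname(x$scores[x$all_names]),
    selected = x$all_names %in% x$selected,
    rank = match(x$all_names, c(x$selected,
                                setdiff(x$all_names[order(-abs(x$scores))],
                                        x$selected)))
  )
  if (!is.null(x$p_values)) tb$p_value <- unname(x$p_values[x$all_names])
  tb
}

#' @rdname generics_methods
#' @method glance feature_selection
#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_features = length(x$all_names),
    n_selected = length(x$selected),
    n_flagged = length(x$flagged)
  )
}
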