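test_that("metrics follow their confusion-count definitions", {
  m <- compute_metrics(10, 10, 0, 0)
  expect_equal(c(m$acc, m$sn, m$sp), c(100, 100, 100))
  m2 <- compute_metrics(9, 8, 2, 1)
  expect_equal(m2$acc, 85.0)
  expect_equal(m2$sn, 90.0)
  expect_equal(m2$sp, 80.0)
  # undefined ratios are NA, never 0
  m3 <- compute_metrics(0, 5, 3, 0)
  expect_true(is.na(m3$sn))
  expect_equal(m3$sp, 62.5)
  expect_error(compute_metrics(0, 0, 0, 0), class = "gaboreeg_data_error")
  expect_error(compute_metrics(-1, 2, 3, 4), class = "gaboreeg_data_error")
})

test_that("separable data is classified perfectly under CV and the split", {
  fm <- make_feature_tibble(n_per_class = 30, n_features = 5, gap = 10,
                            n_informative = 5, seed = 2)
  for (clf in c("svm", "knn")) {
    cv <- evaluate_cv(fm, eval_config(classifier = clf, selection = "none",
                                      seed = 4))
    expect_equal(cv$acc, 100)
    sp <- evaluate_split(fm, eval_config(classifier = clf, selection = "none",
                                         seed = 4))
    expect_equal(sp$acc, 100)
  }
})

test_that("emitted metrics always recompute from the emitted confusion", {
  fm <- make_feature_tibble(n_per_class = 20, n_features = 6, gap = 1,
                            seed = 12)
  for (sel in c("none", "ttest", "chi2")) {
    r <- evaluate_cv(fm, eval_config(selection = sel, seed = 3,
                                     selection_params = list(top_k = 3,
                                                             mode = "top_k")))
    m <- compute_metrics(r$confusion[["tp"]], r$confusion[["tn"]],
                         r$confusion[["fp"]], r$confusion[["fn"]])
    expect_equal(r$acc, m$acc)
    expect_equal(r$sn, m$sn)
    expect_equal(r$sp, m$sp)
    expect_equal(sum(r$confusion), nrow(fm))
    # per-fold test sets are disjoint and exhaustive
    expect_equal(sum(r$per_fold$tp + r$per_fold$tn +
                       r$per_fold$fp + r$per_fold$fn), nrow(fm))
  }
})

test_that("cross-validation is deterministic given the seed", {
  fm <- make_feature_tibble(n_per_class = 15, n_features = 4, gap = 0.5,
                            seed = 6)
  a <- evaluate_cv(fm, eval_config(selection = "none", seed = 11))
  b <- evaluate_cv(fm, eval_config(selection = "none", seed = 11))
  expect_identical(a, b)
  s1 <- evaluate_split(fm, eval_config(selection = "none", seed = 11))
  s2 <- evaluate_split(fm, eval_config(selection = "none", seed = 11))
  expect_identical(s1, s2)
})

test_that("the 80:20 split has the right proportions and stratification", {
  fm <- make_feature_tibble(n_per_class = 50, n_features = 3, gap = 0.2,
                            seed = 9)
  r <- evaluate_split(fm, eval_config(selection = "none", seed = 5))
  expect_equal(sum(r$row_assignment == "test"), 20)
  expect_equal(sum(r$row_assignment == "train"), 80)
  # stratified: 10 test rows per class
  expect_equal(sum(fm$label[r$row_assignment == "test"]), 10)
})

test_that("subject-level splitting keeps every subject on one side", {
  fm <- make_feature_tibble(n_per_class = 24, n_features = 4, gap = 1,
                            seed = 14, segments_per_subject = 4)
  cfg <- eval_config(split_unit = "subject", folds = 3, seed = 21,
                     selection = "none")
  r <- evaluate_cv(fm, cfg)
  cross <- table(fm$subject_id, r$row_assignment)
  expect_true(all(rowSums(cross > 0) == 1))

  rs <- evaluate_split(fm, eval_config(split_unit = "subject", seed = 21,
                                       selection = "none"))
  crosss <- table(fm$subject_id, rs$row_assignment)
  expect_true(all(rowSums(crosss > 0) == 1))
})

test_that("selection inside CV is fitted on the training folds only", {
  fm <- make_feature_tibble(n_per_class = 20, n_features = 10, gap = 1.5,
                            n_informative = 4, seed = 18)
  cfg <- eval_config(selection = "ttest", seed = 7,
                     selection_params = list(mode = "top_k", top_k = 3))
  r <- evaluate_cv(fm, cfg)
  nms <- feature_names(fm)
  for (f in seq_len(cfg$folds)) {
    train <- fm[r$row_assignment != f, , drop = FALSE]
    # re-fit on the train fold after train-only standardization
    mu <- purrr::map_dbl(train[nms], mean)
    sdv <- purrr::map_dbl(train[nms], sd); sdv[sdv == 0] <- 1
    train[nms] <- purrr::map2(train[nms], seq_along(nms),
                              function(col, j) (col - mu[j]) / sdv[j])
    refit <- ttest_select(train, mode = "top_k", top_k = 3)
    expect_identical(r$selected[[f]], refit$selected)
  }
})

test_that("permuted labels drop accuracy to chance over repetitions", {
  fm <- make_feature_tibble(n_per_class = 30, n_features = 5, gap = 4,
                            seed = 25)
  accs <- withr::with_seed(77, {
    purrr::map_dbl(1:20, function(i) {
      fm$label <- sample(fm$label)
      fm$subject_id <- paste0("s", seq_len(nrow(fm)))  # relabelled units
      evaluate_cv(fm, eval_config(selection = "none", seed = i))$acc
    })
  })
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("too few rows or subjects for the fold count is an error", {
  fm <- make_feature_tibble(n_per_class = 5, n_features = 3)
  expect_error(evaluate_cv(fm, eval_config(folds = 10)),
               regexp = "folds", class = "gaboreeg_data_error")
  fm2 <- make_feature_tibble(n_per_class = 12, segments_per_subject = 4)
  expect_error(evaluate_cv(fm2, eval_config(folds = 10,
                                            split_unit = "subject")),
               class = "gaboreeg_data_error")
})

test_that("eval results tidy, glance, serialize and print as a table row", {
  fm <- make_feature_tibble(n_per_class = 15, n_features = 4, gap = 2,
                            seed = 33)
  r <- evaluate_cv(fm, eval_config(seed = 2))
  expect_equal(nrow(tidy(r)), 10)
  g <- glance(r)
  expect_equal(g$scheme, "cv10")
  expect_equal(g$acc, r$acc)
  p <- withr::local_tempfile(fileext = ".json")
  write_eval_json(r, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$metrics$acc, r$acc)
  expect_equal(parsed$confusion$tp + parsed$confusion$tn +
                 parsed$confusion$fp + parsed$confusion$fn, nrow(fm))
  out <- capture.output(print(r))
  expect_true(any(grepl("Validation", out)))
  expect_true(any(grepl("note:", out)))  # segment-mode leakage caveat
})
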