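test_that("Welch t statistics match the stats::t.test oracle to 1e-10", {
  fm <- make_feature_tibble(n_per_class = 15, n_features = 8, gap = 1.2,
                            n_informative = 3, seed = 31)
  sel <- ttest_select(fm, mode = "alpha", alpha = 0.05)
  X <- as.matrix(fm[feature_names(fm)])
  for (j in seq_len(ncol(X))) {
    o <- stats::t.test(X[fm$label == 1, j], X[fm$label == 0, j])
    expect_equal(unname(sel$scores[j]), unname(o$statistic), tolerance = 1e-10)
    expect_equal(unname(sel$p_values[j]), o$p.value, tolerance = 1e-10)
  }
  # pooled variant against var.equal oracle
  selp <- ttest_select(fm, mode = "alpha", var_equal = TRUE)
  op <- stats::t.test(X[fm$label == 1, 1], X[fm$label == 0, 1],
                      var.equal = TRUE)
  expect_equal(unname(selp$scores[1]), unname(op$statistic), tolerance = 1e-10)
})

test_that("strongly separated features are selected, flat features never", {
  withr::with_seed(8, {
    n <- 50
    fm <- tibble::tibble(
      subject_id = paste0("s", 1:(2 * n)),
      segment_index = 0L,
      label = rep(c(0L, 1L), each = n),
      sep = c(rnorm(n, 0, 1), rnorm(n, 10, 1)),
      flat = rep(1.5, 2 * n),
      noise = rnorm(2 * n)
    )
  })
  sel <- ttest_select(fm, mode = "alpha", alpha = 0.05)
  expect_lt(sel$p_values[["sep"]], 1e-10)
  expect_true("sep" %in% sel$selected)
  expect_equal(sel$scores[["flat"]], 0)
  expect_equal(sel$p_values[["flat"]], 1)
  expect_false("flat" %in% sel$selected)
  expect_true("flat" %in% sel$flagged)

  # top_k = all returns every informative feature ordered by p
  sel_all <- ttest_select(fm, mode = "top_k", top_k = 3)
  expect_equal(sel_all$selected[1], "sep")
  expect_false("flat" %in% sel_all$selected)  # flat never selected
})

test_that("single-class input is rejected", {
  fm <- make_feature_tibble(n_per_class = 5)
  fm$label <- 1L
  expect_error(ttest_select(fm), class = "gaboreeg_data_error")
  expect_error(chi2_select(fm, top_k = 2), class = "gaboreeg_data_error")
})

test_that("t statistic grows with the between-class mean gap", {
  gaps <- c(0.5, 1, 2, 4)
  ts <- purrr::map_dbl(gaps, function(g) {
    fm <- make_feature_tibble(n_per_class = 30, n_features = 1, gap = g,
                              seed = 99)  # same noise, larger shift
    abs(ttest_select(fm, mode = "alpha")$scores[[1]])
  })
  expect_true(all(diff(ts) > 0))
})

test_that("chi-square scoring matches a brute-force oracle and ranks separation first", {
  fm <- withr::with_seed(17, {
    n <- 100
    tb <- tibble::tibble(
      subject_id = paste0("s", 1:(2 * n)), segment_index = 0L,
      label = rep(c(0L, 1L), each = n),
      sep = c(rnorm(n, 0, 1), rnorm(n, 10, 1))
    )
    for (j in 1:10) tb[[paste0("noise", j)]] <- rnorm(2 * n)
    tb
  })
  sel <- chi2_select(fm, top_k = 11)
  # brute-force score oracle
  X <- as.matrix(fm[feature_names(fm)])
  y <- fm$label
  for (j in seq_len(ncol(X))) {
    x <- (X[, j] - min(X[, j])) / diff(range(X[, j]))
    sc <- 0
    for (cls in c(0, 1)) {
      O <- sum(x[y == cls]); E <- sum(x) * mean(y == cls)
      sc <- sc + (O - E)^2 / E
    }
    expect_equal(unname(sel$scores[j]), sc, tolerance = 1e-10)
  }
  expect_equal(sel$selected[1], "sep")

  # class-independent feature scores near zero and ranks last
  expect_lt(max(sel$scores[paste0("noise", 1:10)]), sel$scores[["sep"]] / 10)
})

test_that("top_k boundaries: zero, clamped, and empty-selection refusal", {
  fm <- make_feature_tibble(n_per_class = 10, n_features = 4, gap = 3)
  empty <- chi2_select(fm, top_k = 0)
  expect_length(empty$selected, 0)
  applied <- apply_selection(fm, empty)
  expect_length(feature_names(applied), 0)
  expect_error(
    evaluate_cv(dplyr::bind_rows(fm), eval_config(selection = "chi2",
                                                  selection_params = list(top_k = 0),
                                                  folds = 2)),
    class = "gaboreeg_config_error"
  )
  expect_warning(chi2_select(fm, top_k = 99), regexp = "exceeds")
  expect_warning(sel <- ttest_select(fm, mode = "top_k", top_k = 99),
                 regexp = "exceeds")
})

test_that("apply_selection subsets by name and guards schema drift", {
  fm <- make_feature_tibble(n_per_class = 10, n_features = 6, gap = 2,
                            n_informative = 2)
  sel <- ttest_select(fm, mode = "top_k", top_k = 3)
  out <- apply_selection(fm, sel)
  expect_equal(feature_names(out), sel$selected)
  expect_equal(nrow(out), nrow(fm))
  # identity for "none"
  expect_identical(apply_selection(fm, "none"), fm)
  # disjoint schema errors
  fm2 <- fm
  names(fm2)[4] <- "renamed"
  expect_error(apply_selection(fm2, sel), class = "gaboreeg_config_error")
})

test_that("selection results serialize to JSON and tidy into tibbles", {
  fm <- make_feature_tibble(n_per_class = 10, n_features = 4, gap = 2)
  sel <- ttest_select(fm)
  p <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$method, "ttest")
  expect_equal(unlist(parsed$selected), sel$selected)
  td <- tidy(sel)
  expect_equal(nrow(td), 4)
  expect_true(all(c("feature", "score", "p_value", "selected") %in% names(td)))
  g <- glance(sel)
  expect_equal(g$n_selected, length(sel$selected))
})
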