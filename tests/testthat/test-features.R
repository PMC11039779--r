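test_that("constant and two-level series have closed-form statistics", {
  s <- compute_statistics(c(5, 5, 5, 5))
  expect_equal(as.numeric(s), c(0, 0, 0, 0))
  expect_true(attr(s, "degenerate"))

  # 500 + 500 samples at two distinct values: entropy = ln 2
  x <- c(rep(1, 500), rep(3, 500))
  s2 <- compute_statistics(x)
  expect_equal(s2[["entropy"]], log(2), tolerance = 1e-12)
  expect_false(attr(s2, "degenerate"))

  expect_error(compute_statistics(c(1)), class = "gaboreeg_data_error")
  expect_error(compute_statistics(c(1, -2, 3)), class = "gaboreeg_data_error")
})

test_that("moments of shifted normal draws are near their population values", {
  x <- withr::with_seed(42, rnorm(10000))
  x <- x - min(x)   # shift non-negative
  s <- compute_statistics(x)
  expect_lt(abs(s[["skew"]]), 0.1)
  expect_lt(abs(s[["kurt"]]), 0.1)
  expect_equal(s[["std"]], sd(x))
})

test_that("statistics agree with independent oracles to 1e-10", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      x <- abs(rnorm(400)) + runif(400)
      s <- compute_statistics(x, entropy_bins = 64)
      # moment oracles from e1071 (n-denominator conventions)
      expect_equal(s[["skew"]], e1071::skewness(x, type = 1), tolerance = 1e-10)
      expect_equal(s[["kurt"]], e1071::kurtosis(x, type = 1), tolerance = 1e-10)
      expect_equal(s[["std"]], sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                   tolerance = 1e-10)
      # histogram-entropy oracle via graphics::hist
      h <- hist(x, breaks = seq(min(x), max(x), length.out = 65), plot = FALSE)
      p <- h$counts[h$counts > 0] / length(x)
      expect_equal(s[["entropy"]], -sum(p * log(p)), tolerance = 1e-10)
    }
  })
})

test_that("skew, kurt and entropy are scale invariant; std scales linearly", {
  x <- withr::with_seed(5, abs(rnorm(500)))
  a <- compute_statistics(x)
  b <- compute_statistics(3.7 * x)
  expect_equal(b[["skew"]], a[["skew"]], tolerance = 1e-10)
  expect_equal(b[["kurt"]], a[["kurt"]], tolerance = 1e-10)
  expect_equal(b[["entropy"]], a[["entropy"]], tolerance = 1e-10)
  expect_equal(b[["std"]], 3.7 * a[["std"]], tolerance = 1e-10)
})

test_that("feature vectors have length n_channels * n_filters * 4 in canonical order", {
  fs <- 128
  cases <- list(
    list(nch = 19, bank = gabor_preset(3), len = 228),
    list(nch = 19, bank = gabor_preset(4), len = 304),
    list(nch = 1, bank = gabor_bank(12.8, 10), len = 4)
  )
  for (cs in cases) {
    rec <- make_noise_record(n_channels = cs$nch, n_samples = 512, seed = cs$nch)
    v <- extract_features(apply_filter_bank(rec$data, cs$bank, fs = fs))
    expect_length(v, cs$len)
    expect_false(any(duplicated(names(v))))
  }
  # canonical naming: channel-major, then filter, then statistic
  rec <- make_noise_record(n_channels = 2, n_samples = 512)
  v <- extract_features(apply_filter_bank(rec$data, gabor_preset(3), fs = fs))
  expect_equal(names(v)[1:8],
               c("ch1_f1_entropy", "ch1_f1_std", "ch1_f1_skew", "ch1_f1_kurt",
                 "ch1_f2_entropy", "ch1_f2_std", "ch1_f2_skew", "ch1_f2_kurt"))
  expect_equal(names(v)[13], "ch2_f1_entropy")
})

test_that("19 channels x 5 filters gives a 380-column feature matrix", {
  rec <- make_noise_record(n_channels = 19, n_samples = 2560, fs = 128)
  segs <- segment_record(rec, 2)   # 10 segments of 256 samples
  fm <- build_feature_matrix(segs, gabor_preset(5))
  expect_equal(nrow(fm), 10)
  expect_length(feature_names(fm), 380)
  expect_true(all(c("subject_id", "segment_index", "label") %in% names(fm)))
})

test_that("feature matrices are row-independent and reject bad input", {
  rec <- make_noise_record(n_channels = 3, n_samples = 1024, fs = 128)
  segs <- segment_record(rec, 2)
  bank <- gabor_preset(3)
  fm <- build_feature_matrix(segs, bank)
  perm <- c(3, 1, 4, 2)
  fm_perm <- build_feature_matrix(segs[perm, ], bank)
  expect_equal(as.matrix(fm_perm[feature_names(fm_perm)]),
               as.matrix(fm[feature_names(fm)])[perm, ])

  expect_error(build_feature_matrix(segs[0, ], bank),
               class = "gaboreeg_data_error")
  mixed <- dplyr::bind_rows(
    segs,
    segment_record(make_noise_record(n_channels = 2, n_samples = 1024,
                                     subject_id = "odd"), 2)
  )
  expect_error(build_feature_matrix(mixed, bank), regexp = "odd",
               class = "gaboreeg_data_error")
})

test_that("feature CSV files round-trip", {
  rec <- make_noise_record(n_channels = 2, n_samples = 1024, fs = 128)
  fm <- build_feature_matrix(segment_record(rec, 2), gabor_preset(3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, p)
  back <- read_feature_matrix(p)
  expect_equal(names(back), names(fm))
  expect_equal(as.matrix(back[feature_names(back)]),
               as.matrix(fm[feature_names(fm)]), tolerance = 1e-12)
})
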