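test_that("magnitude spectrum matches a direct O(N^2) DFT", {
  withr::with_seed(4, {
    x <- rnorm(60)
    sp <- magnitude_spectrum(x, fs = 4)
    expect_equal(sp$magnitude, oracle_spectrum(x, 4), tolerance = 1e-9)
    expect_equal(nrow(sp), 31)            # DC + 30 bins
    expect_equal(sp$freq[1], 0)
  })
})

test_that("spectrum concentrates energy where expected", {
  # constant window: all energy in DC
  sp <- magnitude_spectrum(rep(2, 64), fs = 4)
  expect_gt(sp$magnitude[1], 1)
  expect_true(all(sp$magnitude[-1] < 1e-10))
  # bin-frequency sinusoid: single dominant non-DC bin
  t <- (0:63) / 4
  sp2 <- magnitude_spectrum(sin(2 * pi * 0.5 * t), fs = 4)
  peak_bin <- which.max(sp2$magnitude)
  expect_equal(sp2$freq[peak_bin], 0.5)
  expect_gt(sp2$magnitude[peak_bin], 10 * max(sp2$magnitude[-peak_bin]))
})

test_that("the feature vector has exactly the 23 canonical names", {
  expect_length(feature_catalogue(), 23L)
  withr::with_seed(6, {
    fv <- extract_features(rnorm(60, 2), rnorm(60, 2), rnorm(60, 0, 0.01),
                           fs = 4)
    expect_named(fv, feature_catalogue())
    expect_true(all(is.finite(fv)))
  })
})

test_that("every statistic matches the definition-level oracle", {
  withr::with_seed(16, {
    sc <- rnorm(60, 2, 0.3)
    scl <- rnorm(60, 2, 0.1)
    scr <- rnorm(60, 0, 0.02)
    fv <- extract_features(sc, scl, scr, fs = 4)
    o <- oracle_moments(sc)
    expect_equal(unname(fv["sc_t_mean"]), o$mean, tolerance = 1e-9)
    expect_equal(unname(fv["sc_t_std"]), o$sd, tolerance = 1e-9)
    expect_equal(unname(fv["sc_t_variance"]), o$var, tolerance = 1e-9)
    expect_equal(unname(fv["sc_t_skewness"]), o$skew, tolerance = 1e-9)
    expect_equal(unname(fv["sc_t_kurtosis"]), o$kurt, tolerance = 1e-9)
    expect_equal(unname(fv["sc_t_range"]), max(sc) - min(sc), tolerance = 1e-12)
    expect_equal(unname(fv["sc_t_median"]), median(sc), tolerance = 1e-12)
    om <- oracle_moments(oracle_spectrum(sc, 4))
    expect_equal(unname(fv["sc_f_mean"]), om$mean, tolerance = 1e-9)
    expect_equal(unname(fv["sc_f_kurtosis"]), om$kurt, tolerance = 1e-9)
    ol <- oracle_moments(scl)
    expect_equal(unname(fv["scl_t_std"]), ol$sd, tolerance = 1e-9)
    expect_equal(unname(fv["scl_t_min"]), min(scl), tolerance = 1e-12)
  })
})

test_that("degenerate constant windows take the zero-moment convention", {
  fv <- extract_features(rep(2, 60), rep(2, 60), rep(0, 60), fs = 4)
  expect_equal(unname(fv["sc_t_mean"]), 2)
  expect_equal(unname(fv["sc_t_std"]), 0)
  expect_equal(unname(fv["sc_t_range"]), 0)
  expect_equal(unname(fv["sc_t_skewness"]), 0)
  expect_equal(unname(fv["sc_t_kurtosis"]), 0)
  expect_equal(unname(fv["scr_num_peaks"]), 0)
})

test_that("SCR peak counting honours the relevance threshold", {
  expect_equal(count_scr_peaks(rep(0, 60)), 0L)
  bump <- function(h) c(rep(0, 10), h * sin(seq(0, pi, length.out = 21)),
                        rep(0, 9))
  expect_equal(count_scr_peaks(bump(0.005)), 0L)   # below 0.01 uS
  expect_equal(count_scr_peaks(bump(0.05)), 1L)
  expect_equal(count_scr_peaks(c(bump(0.05), bump(0.08))), 2L)
  # synthetic window with 2 injected kernel SCRs above threshold, mild noise
  withr::with_seed(33, {
    t <- (0:59) / 4
    w <- 0.05 * scr_kernel(t - 2) + 0.05 * scr_kernel(t - 9) +
      rnorm(60, 0, 0.0005)
    expect_equal(count_scr_peaks(w), 2L)
  })
})

test_that("Pearson correlation matches its covariance definition", {
  expect_equal(pearson_correlation(1:10, 1:10), 1)
  expect_equal(pearson_correlation(1:10, -2 * (1:10) + 5), -1)
  withr::with_seed(10, {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_correlation(x, y), oracle_pearson(x, y),
                 tolerance = 1e-12)
  })
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("pruning drops the collinear five and keeps independent features", {
  tab <- make_collinear_fixture()
  pruned <- correlation_prune(tab)
  expect_length(selected_features(pruned), 18L)
  expect_setequal(selected_features(pruned), feature_catalogue()[1:18])
  log <- attr(pruned, "pruning_log")
  expect_setequal(log$feature, feature_catalogue()[19:23])
  expect_true(all(abs(log$rho) > 0.90))
  # duplicated column: exactly one of the pair survives
  dup <- tab
  dup$sc_t_min <- dup$sc_t_std
  pruned2 <- correlation_prune(dup)
  expect_true("sc_t_std" %in% selected_features(pruned2))
  expect_false("sc_t_min" %in% selected_features(pruned2))
})

test_that("independent features are all retained and pruning is idempotent", {
  withr::with_seed(50, {
    tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(500 * 8), ncol = 8)))
    names(tab) <- paste0("f", 1:8)
    tab$class <- rep_len(1:3, 500)
    p1 <- correlation_prune(tab)
    expect_length(selected_features(p1), 8L)
    p2 <- correlation_prune(p1)
    expect_identical(selected_features(p2), selected_features(p1))
  })
})

test_that("all retained pairwise correlations respect the threshold", {
  s <- generate_session(session_spec(seed = 41))
  res <- run_pipeline(s, config = pipeline_config(seed = 2))
  tab <- res$feature_table
  feats <- selected_features(tab)
  cm <- abs(cor(as.data.frame(tab)[, feats]))
  diag(cm) <- 0
  expect_true(all(cm <= 0.90))
})

test_that("constant feature columns are dropped with a warning", {
  tab <- make_collinear_fixture(n = 50)
  tab$sc_f_min <- 1
  expect_warning(pruned <- correlation_prune(tab), "constant")
  expect_false("sc_f_min" %in% selected_features(pruned))
})

test_that("feature extraction is permutation-covariant over windows", {
  s <- generate_session(session_spec(duration_s = 600, drowsiness_profile = 2,
                                     artifact_burst_rate_per_min = 0,
                                     seed = 18))
  d <- decompose_scl_scr(s$sc)
  lab <- assign_labels(window_segments(d), s$kss)
  tab <- extract_feature_table(lab, d$fs)
  perm <- c(5, 1, 7, 3, 2, 40, 39, 12, seq_len(40)[-c(5, 1, 7, 3, 2, 40, 39, 12)])
  tab_perm <- extract_feature_table(lab[perm, ], d$fs)
  expect_equal(as.data.frame(tab_perm), as.data.frame(tab)[perm, ],
               ignore_attr = TRUE)
})

test_that("feature-class ranking reports a correlation per feature", {
  tab <- make_collinear_fixture(n = 100)
  rk <- feature_class_correlation(tab)
  expect_setequal(rk$feature, feature_catalogue())
  expect_true(all(rk$rho_class >= 0 & rk$rho_class <= 1, na.rm = TRUE))
})
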