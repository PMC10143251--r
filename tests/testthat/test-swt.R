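test_that("decomposition level follows the log2 rule", {
  expect_identical(decomposition_level(4), 4L)
  expect_identical(decomposition_level(256), 10L)
  expect_identical(decomposition_level(1), 2L)
  expect_warning(j <- decomposition_level(6), "power of two")
  expect_identical(j, 5L)
  expect_error(decomposition_level(0.5))
})

test_that("SWT coefficients match the brute-force convolution oracle", {
  withr::with_seed(8, {
    for (n in c(64, 256)) {
      x <- rnorm(n)
      j <- if (n == 64) 5 else 7
      w <- swt_haar(x, j)
      o <- oracle_swt(x, j)
      for (l in seq_len(j)) {
        expect_equal(w$details[[l]], o$details[[l]], tolerance = 1e-12)
      }
      expect_equal(w$approx, o$approx, tolerance = 1e-12)
    }
  })
})

test_that("ISWT is a 1e-9 exact inverse of the SWT", {
  withr::with_seed(9, {
    for (n in c(16, 128, 256)) {
      x <- cumsum(rnorm(n))
      j <- log2(n)
      expect_lt(max(abs(iswt_haar(swt_haar(x, j)) - x)), 1e-9)
    }
  })
})

test_that("Laplace thresholds evaluate the closed-form rule", {
  thr <- laplace_thresholds(c(1, 1, 1, 1), 0.10)
  expect_equal(unname(thr["low"]), log(0.10), tolerance = 1e-6)   # -2.302585
  expect_equal(unname(thr["high"]), -log(0.10), tolerance = 1e-6)
  thr <- laplace_thresholds(c(2, -2), 0.01)
  expect_equal(unname(thr["low"]), 2 * log(0.01), tolerance = 1e-5) # -9.21034
  expect_equal(unname(laplace_thresholds(c(0, 0), 0.5)), c(0, 0))
  expect_error(laplace_thresholds(c(1), 1))
  expect_error(laplace_thresholds(c(1), 0))
  expect_error(laplace_thresholds(numeric(0), 0.1))
})

test_that("delta selection gates on the per-axis standard deviation", {
  cfg <- filter_config()
  mk <- function(s) rnorm(500, sd = s) * s / max(sd(rnorm(500)), 1e-9)
  # deterministic slices with exact sds via scaling
  slice <- function(target_sd) {
    v <- seq(-1, 1, length.out = 100)
    v * target_sd / sd(v)
  }
  expect_equal(select_delta(slice(0.01), slice(0.02), slice(0.03), cfg), 0.01)
  expect_equal(select_delta(slice(0.01), slice(0.05), slice(0.01), cfg), 0.10)
  expect_equal(select_delta(rep(1, 10), rep(2, 10), rep(3, 10), cfg), 0.01)
  expect_error(select_delta(numeric(0), 1, 1, cfg))
})

test_that("coefficient thresholding zeroes exactly the out-of-band details", {
  x <- c(rep(0.1, 15), 5)            # one outlier
  w <- swt_haar(rep(x, 8), 4)
  wt <- threshold_coefficients(w, 0.01)
  for (l in seq_len(4)) {
    thr <- laplace_thresholds(w$details[[l]], 0.01)
    expected <- w$details[[l]]
    expected[expected < thr["low"] | expected > thr["high"]] <- 0
    expect_equal(wt$details[[l]], expected)
  }
  expect_identical(wt$approx, w$approx)
  # all-inside case: workspace unchanged
  w2 <- swt_haar(sin(seq_len(64) / 3), 4)
  wt2 <- threshold_coefficients(w2, 0.5)
  keep_all <- vapply(seq_len(4), function(l) {
    thr <- laplace_thresholds(w2$details[[l]], 0.5)
    all(w2$details[[l]] >= thr["low"] & w2$details[[l]] <= thr["high"])
  }, logical(1))
  for (l in which(keep_all)) {
    expect_identical(wt2$details[[l]], w2$details[[l]])
  }
})

test_that("monotone aggressiveness: delta 0.10 zeroes a superset of delta 0.01", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      x <- cumsum(rnorm(128)) + c(rep(0, 60), 5, rep(0, 67))
      w <- swt_haar(x, 7)
      w01 <- threshold_coefficients(w, 0.01)
      w10 <- threshold_coefficients(w, 0.10)
      for (l in 1:7) {
        zero01 <- which(w01$details[[l]] == 0 & w$details[[l]] != 0)
        zero10 <- which(w10$details[[l]] == 0 & w$details[[l]] != 0)
        expect_true(all(zero01 %in% zero10))
      }
    }
  })
})

test_that("both filter variants reproduce their input with thresholding off", {
  s <- generate_session(session_spec(duration_s = 600, drowsiness_profile = 1,
                                     seed = 3))
  for (fun in list(filter_original, filter_improved)) {
    out <- fun(s$sc, s$acc, filter_config(j = 4), thresholding = FALSE)
    expect_lt(max(abs(out$samples - s$sc$samples)), 1e-9)
  }
})

test_that("a constant signal passes through both variants unchanged", {
  sc <- sc_recording(rep(2.5, 512), fs = 4)
  acc <- triaxial_recording(rnorm(4096, 0, 0.01), rnorm(4096, 0, 0.01),
                            rnorm(4096, 0, 0.01), fs = 32)
  expect_equal(filter_original(sc, acc, filter_config(j = 4))$samples,
               rep(2.5, 512))
  expect_equal(filter_improved(sc, acc, filter_config(j = 4))$samples,
               rep(2.5, 512))
})

test_that("filters preserve length and never introduce NaNs, padded tails included", {
  s <- generate_session(session_spec(duration_s = 600, drowsiness_profile = 2,
                                     seed = 13))
  sc_odd <- sc_recording(s$sc$samples[1:2389], fs = 4)   # not a segment multiple
  for (fun in list(filter_original, filter_improved)) {
    out <- fun(sc_odd, s$acc, filter_config(j = 4))
    expect_length(out$samples, 2389)
    expect_true(all(is.finite(out$samples)))
  }
})

test_that("mismatched SC and acceleration spans raise an error", {
  s <- generate_session(session_spec(duration_s = 600, drowsiness_profile = 1,
                                     seed = 2))
  acc_short <- triaxial_recording(s$acc$x[1:6400], s$acc$y[1:6400],
                                  s$acc$z[1:6400], fs = 32)  # 200 s vs 600 s
  expect_error(filter_original(s$sc, acc_short, filter_config(j = 4)), "span")
})

test_that("filtering an artifact-laden session moves it toward the clean truth", {
  s <- generate_session(session_spec(seed = 7))
  cfg <- filter_config(j = 4)
  raw_err <- rmse(s$sc$samples, s$truth$clean$samples)
  expect_lt(rmse(filter_original(s$sc, s$acc, cfg)$samples,
                 s$truth$clean$samples), raw_err)
  expect_lt(rmse(filter_improved(s$sc, s$acc, cfg)$samples,
                 s$truth$clean$samples), raw_err)
})

test_that("compare_filters reports zero deviation for a zero signal", {
  sc <- sc_recording(rep(0, 256), fs = 4)
  acc <- triaxial_recording(rnorm(2048, 0, 0.01), rnorm(2048, 0, 0.01),
                            rnorm(2048, 0, 0.01), fs = 32)
  cmp <- compare_filters(sc, acc, filter_config(j = 4))
  expect_equal(cmp$summary$max_dev_original, 0)
  expect_equal(cmp$summary$max_dev_improved, 0)
  expect_equal(cmp$summary$n_joint_dev_between, 0L)
})

test_that("both variants attenuate an injected spike artifact", {
  withr::with_seed(17, {
    clean <- 2 + 0.001 * rnorm(512)
    dirty <- clean
    dirty[200:207] <- dirty[200:207] + 1.5        # spike burst
    sc <- sc_recording(dirty, fs = 4)
    n_acc <- 4096
    sd_acc <- rep(0.01, n_acc)
    sd_acc[(200 * 8):(208 * 8)] <- 0.5            # time-locked shaking
    acc <- triaxial_recording(rnorm(n_acc, 0, sd_acc), rnorm(n_acc, 0, sd_acc),
                              rnorm(n_acc, 0, sd_acc), fs = 32)
    cfg <- filter_config(j = 4)
    for (fun in list(filter_original, filter_improved)) {
      out <- fun(sc, acc, cfg)
      expect_lt(rmse(out$samples, clean), rmse(dirty, clean))
    }
  })
})
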