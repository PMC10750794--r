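norm_of <- function(x, rate = 50) {
  norm_signal(seq_along(x) / rate, x, rate)
}

test_that("window accounting follows the count formula", {
  cfg <- windowing_config(128L, 0.5)
  expect_identical(window_count(256L, cfg), 3L)
  expect_identical(window_count(127L, cfg), 0L)
  expect_identical(window_count(128L, cfg), 1L)
  for (L in c(130L, 191L, 192L, 500L, 1280L))
    expect_identical(window_count(L, cfg),
                     as.integer(floor((L - 128) / 64) + 1))
})

test_that("band power of a 5 Hz sine matches A^2/2 and the periodogram oracle", {
  rate <- 50
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 5 * t)
  bp46 <- band_power(x, 4, 6, rate = rate)
  expect_equal(bp46, 0.5, tolerance = 0.05)
  expect_equal(bp46, periodogram_band_power(x, rate, 4, 6), tolerance = 0.05)
  # off-band leakage: gait band carries under 1 % of the total
  expect_lt(band_power(x, 1, 3, rate = rate),
            0.01 * band_power(x, 0.1, 24.9, rate = rate))
  # 2 Hz sine: gait band holds A^2/2, tremor band nearly nothing
  y <- 0.8 * sin(2 * pi * 2 * t)
  expect_equal(band_power(y, 1, 3, rate = rate), 0.8^2 / 2, tolerance = 0.05)
  expect_lt(band_power(y, 4, 6, rate = rate),
            0.01 * band_power(y, 0.1, 24.9, rate = rate))
})

test_that("disjoint bands add to the power of their union", {
  set.seed(3)
  rate <- 50
  x <- rnorm(1500) + sin(2 * pi * 5 * seq_len(1500) / rate)
  parts <- band_power(x, 0, 3, rate = rate) +
    band_power(x, 3, 8, rate = rate) + band_power(x, 8, 20, rate = rate)
  whole <- band_power(x, 0, 20, rate = rate)
  expect_equal(parts, whole, tolerance = 0.01)
})

test_that("Parseval: full-band power of a zero-mean signal equals its variance", {
  rate <- 50
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 5 * t)
  expect_equal(band_power(x, 0, rate / 2, rate = rate), var(x),
               tolerance = 0.02)
  set.seed(8)
  w <- rnorm(1500, sd = 1.3)
  # white noise: the 0-20 Hz band holds 20/25 of the variance
  expect_equal(band_power(w, 0, 20, rate = rate), var(w) * 20 / 25,
               tolerance = 0.10)
  expect_equal(band_power(rep(0, 1500), 0, 20, rate = rate), 0)
})

test_that("scaling the signal by k scales std-like features by k, powers by k^2", {
  set.seed(5)
  rate <- 50
  x <- rnorm(1500) + sin(2 * pi * 4 * seq_len(1500) / rate)
  k <- 3.7
  f1 <- segment_features(norm_of(x))
  f2 <- segment_features(norm_of(k * x))
  for (nm in c("std"))
    expect_equal(f2[[nm]], k * f1[[nm]], tolerance = 1e-10)
  for (nm in grep("^bp_", names(f1), value = TRUE))
    expect_equal(f2[[nm]], k^2 * f1[[nm]], tolerance = 1e-8)
})

test_that("segment features: constant and order-statistic contracts", {
  f <- segment_features(norm_of(rep(4.2, 200)))
  expect_equal(unname(f[c("mean", "median", "p25", "p75", "max", "min")]),
               rep(4.2, 6))
  expect_equal(unname(f["std"]), 0)
  expect_true(is.na(f[["skewness"]]))  # undefined on constant input

  set.seed(2)
  for (rep in 1:10) {
    f <- segment_features(norm_of(rexp(300)))
    expect_lte(f[["p25"]], f[["median"]])
    expect_lte(f[["median"]], f[["p75"]])
    expect_lte(f[["min"]], f[["mean"]])
    expect_lte(f[["mean"]], f[["max"]])
  }
  expect_error(segment_features(norm_of(numeric(0))), "empty|length")
  # short segments: time features only, band powers missing
  fshort <- segment_features(norm_of(rnorm(50)))
  expect_true(all(is.na(fshort[grep("^bp_", names(fshort))])))
  expect_false(is.na(fshort[["std"]]))
})

test_that("jerk is the scaled first difference", {
  expect_equal(jerk(c(0, 1, 2, 3), 50), rep(50, 3))
  expect_equal(jerk(rep(2.5, 10), 50), rep(0, 9))
  rate <- 50
  t <- seq(0, 10, by = 1 / rate)
  x <- 2 * sin(2 * pi * 3 * t)
  # discrete-difference gain ~ A * 2*pi*f for f << Nyquist
  expect_equal(max(abs(jerk(x, rate))), 2 * 2 * pi * 3, tolerance = 0.05)
  expect_error(jerk(1, 50), "2 samples")
})

test_that("windowed feature table: window counts, labels and constant channels", {
  rate <- 50
  n1 <- 256; n2 <- 127; n3 <- 300
  labels <- c(rep(1L, n1), rep(0L, n2), rep(6L, n3))
  n <- length(labels)
  set.seed(4)
  sig <- triaxial_signal((0:(n - 1)) / rate,
                         rnorm(n, sd = 0.3), rnorm(n, sd = 0.3),
                         9.81 + rnorm(n, sd = 0.3), rate)
  tr <- trial_record("S09", "supervised", 2L, sig, labels,
                     c("3.17" = 1, "3.6" = 3))
  wf <- windowed_features(tr)
  expect_equal(sum(wf$label_code == 1L), 3L)   # 256 samples -> 3 windows
  expect_equal(sum(wf$label_code == 0L), 0L)   # 127 samples -> none
  expect_equal(sum(wf$label_code == 6L), window_count(n3))
  expect_equal(unique(wf$score[wf$label_code == 6L]), 3)
  expect_equal(unique(wf$score_item[wf$label_code == 6L]), "3.6")
  expect_true(all(is.na(wf$score_item[wf$label_code == 0L])))

  # a constant channel has zero spread and minimal spectral entropy
  x <- rep(1.5, 128)
  f <- wristpd:::.window_channel_features(x, rate, default_bands())
  expect_equal(unname(f[c("std", "mad", "iqr", "zcr")]), rep(0, 4))
  expect_equal(unname(f["spec_entropy"]), 0)
})

test_that("a window larger than every segment yields an empty table", {
  rate <- 50
  labels <- rep(c(0L, 1L), each = 60)
  sig <- triaxial_signal((0:119) / rate, rnorm(120), rnorm(120),
                         9.81 + rnorm(120), rate)
  tr <- trial_record("S01", "control", 1L, sig, labels)
  expect_warning(wf <- windowed_features(tr), "window")
  expect_equal(nrow(wf), 0L)
})
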