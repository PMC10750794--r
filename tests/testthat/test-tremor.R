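test_that("a zero signal yields no tremor intervals at any positive threshold", {
  z <- simulate_rest_segment(30, data.frame(start_s = numeric(0),
                                            end_s = numeric(0)),
                             amp = 1, freq_hz = 5, noise_sd = 0, seed = 1)
  for (th in c(1e-6, 1e-3, 1)) {
    res <- label_tremor(norm_highpass(z$signal),
                        tremor_label_config(threshold = th))
    expect_equal(nrow(res$intervals), 0L)
  }
})

test_that("an injected 5 Hz burst is recovered with IoU >= 0.8", {
  for (s in 1:3) {
    rs <- simulate_rest_segment(30, data.frame(start_s = 10, end_s = 20),
                                amp = 1.0, freq_hz = 5, seed = s)
    res <- label_tremor(norm_highpass(rs$signal),
                        tremor_label_config(threshold = 0.01))
    expect_equal(nrow(res$intervals), 1L)
    expect_gte(interval_iou(c(res$intervals$start_s, res$intervals$end_s),
                            c(10, 20)), 0.8)
  }
})

test_that("a threshold above the burst band power suppresses all intervals", {
  rs <- simulate_rest_segment(30, data.frame(start_s = 10, end_s = 20),
                              amp = 1.0, freq_hz = 5, seed = 1)
  nh <- norm_highpass(rs$signal)
  res <- label_tremor(nh, tremor_label_config(threshold = 100))
  expect_equal(nrow(res$intervals), 0L)
})

test_that("labeling is deterministic and monotone in the threshold", {
  rs <- simulate_rest_segment(30, data.frame(start_s = 10, end_s = 20),
                              amp = 1.0, freq_hz = 5, seed = 2)
  nh <- norm_highpass(rs$signal)
  cfg <- tremor_label_config(threshold = 0.02)
  expect_identical(label_tremor(nh, cfg)$intervals,
                   label_tremor(nh, cfg)$intervals)
  durations <- vapply(c(0.002, 0.01, 0.05, 0.2, 1, 10), function(th) {
    iv <- label_tremor(nh, tremor_label_config(threshold = th))$intervals
    sum(iv$end_s - iv$start_s)
  }, numeric(1))
  expect_true(all(diff(durations) <= 0))
})

test_that("intervals respect min duration and merge across short gaps", {
  # two bursts 0.3 s apart merge; an isolated 0.5 s blip is dropped
  rs <- simulate_rest_segment(
    40, data.frame(start_s = c(5, 10.3, 30), end_s = c(10, 15, 30.5)),
    amp = 1.0, freq_hz = 6, seed = 3)
  res <- label_tremor(norm_highpass(rs$signal),
                      tremor_label_config(threshold = 0.01,
                                          merge_gap_s = 1.5,
                                          min_duration_s = 1.5))
  expect_equal(nrow(res$intervals), 1L)
  expect_gte(interval_iou(c(res$intervals$start_s, res$intervals$end_s),
                          c(5, 15)), 0.75)
  expect_true(all(res$intervals$end_s - res$intervals$start_s >= 1.5))
})

test_that("a segment shorter than one window warns and returns nothing", {
  rs <- simulate_rest_segment(2, data.frame(start_s = numeric(0),
                                            end_s = numeric(0)),
                              amp = 1, freq_hz = 5, seed = 1)
  expect_warning(res <- label_tremor(norm_highpass(rs$signal)),
                 "shorter than one")
  expect_equal(nrow(res$intervals), 0L)
})

test_that("threshold calibration separates the classes it is given", {
  # perfectly separated band powers -> J = 1; same distribution -> J ~ 0
  cohort <- simulate_cohort(sim_config(seed = 7, n_subjects = 6,
                                       n_control = 3,
                                       trials_per_subject = 1))
  cal <- calibrate_threshold(cohort)
  expect_gte(cal$sensitivity, 0.9)
  expect_gte(cal$specificity, 0.9)
  expect_gt(cal$threshold, 0)

  # single-class cohorts are rejected
  hc_only <- simulate_cohort(sim_config(seed = 8, n_subjects = 2,
                                        n_control = 2,
                                        trials_per_subject = 1))
  expect_error(calibrate_threshold(hc_only), "both tremor and non-tremor")
})

test_that("calibration agrees with an exhaustive confusion-matrix sweep", {
  set.seed(21)
  cohort <- simulate_cohort(sim_config(seed = 21, n_subjects = 4,
                                       n_control = 2,
                                       trials_per_subject = 1))
  cal <- calibrate_threshold(cohort)
  # brute-force oracle: recompute powers and truth labels independently and
  # evaluate J on a dense quantile grid; the sweep's J must not be beaten
  cfg <- tremor_label_config()
  powers <- numeric(0); truth <- logical(0)
  for (entry in cohort) {
    tr <- entry$trial
    segs <- tr$segments[tr$segments$label_code == 1L, ]
    for (si in seq_len(nrow(segs))) {
      idx <- (segs$start[si] + 1):segs$end[si]
      sub <- triaxial_signal(tr$signal$t[idx], tr$signal$ax[idx],
                             tr$signal$ay[idx], tr$signal$az[idx], 50)
      trc <- wristpd:::.tremor_power_trace(norm_highpass(sub), cfg)
      powers <- c(powers, trc$power)
      truth <- c(truth, wristpd:::.window_truth(trc,
                                                entry$truth$tremor_intervals))
    }
  }
  grid <- quantile(powers, seq(0.001, 0.999, length.out = 500))
  Jgrid <- vapply(grid, function(th) {
    mean(powers[truth] > th) + mean(powers[!truth] <= th) - 1
  }, numeric(1))
  expect_gte(cal$J + 1e-9, max(Jgrid))
})
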