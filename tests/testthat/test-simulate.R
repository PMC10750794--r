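sev0 <- full_severities(rep(0, 6))
sev_tremor <- full_severities(c(4, 2, 1, 1, 3, 2))

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42)
  a <- simulate_trial(cfg, "S01", sev_tremor)
  b <- simulate_trial(cfg, "S01", sev_tremor)
  expect_identical(a$trial$signal, b$trial$signal)
  expect_identical(a$truth, b$truth)
  # different subjects / weeks draw different streams
  c_ <- simulate_trial(cfg, "S02", sev_tremor)
  expect_false(identical(a$trial$signal$ax, c_$trial$signal$ax))
})

test_that("severity 0 with no noise leaves static segments at pure gravity", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  res <- simulate_trial(cfg, "S01", sev0)
  tr <- res$trial
  expect_equal(nrow(res$truth$tremor_intervals), 0L)
  rest <- tr$segments[tr$segments$label_code == 1L, ]
  for (si in seq_len(nrow(rest))) {
    idx <- (rest$start[si] + 1):rest$end[si]
    expect_equal(tr$signal$ax[idx], rep(0, length(idx)))
    expect_equal(tr$signal$az[idx], rep(9.81, length(idx)))
    sub <- triaxial_signal(tr$signal$t[idx], tr$signal$ax[idx],
                           tr$signal$ay[idx], tr$signal$az[idx], 50)
    expect_lt(var(movement_norm(sub)$a), 1e-6)
    expect_lt(var(norm_highpass(sub)$a), 1e-6)
  }
})

test_that("severe rest tremor concentrates norm power around its frequency", {
  cfg <- sim_config(seed = 42, noise_sd = 0)
  res <- simulate_trial(cfg, "S01", sev_tremor, tremor_freq_hz = 5)
  tr <- res$trial
  rest <- tr$segments[tr$segments$label_code == 1L, ][1, ]
  idx <- (rest$start + 1):rest$end
  sub <- triaxial_signal(tr$signal$t[idx], tr$signal$ax[idx],
                         tr$signal$ay[idx], tr$signal$az[idx], 50)
  nh <- norm_highpass(sub)
  frac <- periodogram_band_power(nh$a, 50, 4, 6) /
    periodogram_band_power(nh$a, 50, 0.2, 24.9)
  expect_gte(frac, 0.95)
})

test_that("rest-segment tremor-band power is monotone in the amplitude map", {
  powers <- vapply(0:4, function(score) {
    cfg <- sim_config(seed = 10, noise_sd = 0)
    sev <- full_severities(c(score, 0, 0, 0, 0, 0))
    res <- simulate_trial(cfg, "S01", sev, tremor_freq_hz = 5.5)
    tr <- res$trial
    rest <- tr$segments[tr$segments$label_code == 1L, ][1, ]
    idx <- (rest$start + 1):rest$end
    sub <- triaxial_signal(tr$signal$t[idx], tr$signal$ax[idx],
                           tr$signal$ay[idx], tr$signal$az[idx], 50)
    band_power(norm_highpass(sub), 3.5, 7.5)
  }, numeric(1))
  expect_true(all(diff(powers) >= 0))
  expect_lt(powers[1], 1e-10)
})

test_that("invalid severities and degenerate configs are rejected", {
  cfg <- sim_config()
  expect_error(simulate_trial(cfg, "S01", full_severities(c(5, 0, 0, 0, 0, 0))),
               "0..4")
  expect_error(simulate_trial(cfg, "S01", c("3.17" = 1)), "six")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(rest_between_s = 0), "positive")
  expect_error(sim_config(severity_to_tremor_amp = function(s) 0.1 + s),
               "must be 0")
  expect_error(sim_config(severity_to_cycle_rate = function(s) 2 + s),
               "decreasing")
  expect_error(sim_config(severity_probs = c(0, 0, 0, 0, 0)), "mass")
})

test_that("cohort structure: sizes, score persistence, on-disk round-trip", {
  # the study-sized layout: 13 subjects (6 PD + 7 HC); with ~8 weekly trials
  # per subject the cohort holds ~102 single trials. Down-scaled here: the
  # structural contract (counts, groups, zero HC scores) is what is checked.
  cfg <- sim_config(seed = 3, n_subjects = 4, n_control = 2,
                    trials_per_subject = 2, week_jitter_prob = 0)
  d <- withr::local_tempdir()
  co <- simulate_cohort(cfg, out_dir = d)
  expect_length(co, 8)
  groups <- vapply(co, function(r) r$trial$group, character(1))
  expect_equal(sum(groups == "control"), 4L)
  hc <- co[groups == "control"]
  for (r in hc) {
    expect_true(all(r$truth$severities == 0))
    expect_equal(nrow(r$truth$tremor_intervals), 0L)
  }
  # with no week jitter, a subject's severities persist across weeks
  s1 <- co[vapply(co, function(r) r$trial$subject_id, character(1)) == "S01"]
  expect_equal(s1[[1]]$truth$severities, s1[[2]]$truth$severities)
  # files round-trip through session_io
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_length(man$trials, 8)
  tr <- read_trial(file.path(d, man$trials[1]))
  expect_identical(tr$signal$ax, co[[1]]$trial$signal$ax)
  expect_identical(tr$labels, co[[1]]$trial$labels)
  v <- validate_session(d)
  expect_true(v$ok)
})

test_that("a single-trial cohort writes exactly one listed trial", {
  d <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(seed = 2, n_subjects = 1,
                                   trials_per_subject = 1), out_dir = d)
  expect_length(co, 1)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(length(man$trials), 1L)
  expect_true(dir.exists(file.path(d, man$trials[1])))
})

test_that("cohort files are byte-identical under the same seed and config", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(sim_config(seed = 7, n_subjects = 1,
                             trials_per_subject = 1), out_dir = d1)
  simulate_cohort(sim_config(seed = 7, n_subjects = 1,
                             trials_per_subject = 1), out_dir = d2)
  f1 <- file.path(d1, "S01_w01", "samples.csv")
  f2 <- file.path(d2, "S01_w01", "samples.csv")
  expect_identical(readLines(f1), readLines(f2))
})
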