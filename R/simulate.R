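#' Simulation configuration for synthetic motor-protocol cohorts
#'
#' Defines the study conditions the simulator emulates: 50 Hz triaxial wrist
#' acceleration with a gravity offset, the 8-exercise protocol with rest and
#' transition intervals, severity-linked resting/postural tremor in the
#' 3.5-7.5 Hz band, severity-linked slowing and attenuation of
#' pronation-supination cycles, white sensor noise, and paired MDS-UPDRS-like
#' item scores.
#'
#' Severity maps (score 0-4):
#' * `severity_to_tremor_amp`: tremor oscillation amplitude, default
#'   `0.25 * score` m/s^2 (zero at score 0);
#' * `severity_to_cycle_rate`: pronation-supination cycle frequency, default
#'   `2.0 - 0.3 * score` Hz (strictly decreasing, so impaired cycling falls
#'   inside the 1-4 Hz dyskinesia band);
#' * `severity_to_cycle_amp`: cycle amplitude, default `1.5 - 0.25 * score`
#'   m/s^2.
#'
#' @param seed integer master seed; the same seed and config yield
#'   byte-identical output.
#' @param n_subjects number of subjects.
#' @param n_control how many of them are healthy controls (all scores 0).
#' @param trials_per_subject weekly trials per subject.
#' @param sampling_rate_hz sampling rate (default 50 Hz).
#' @param tremor_freq_range tremor fundamental drawn uniformly per subject
#'   from this range (default 3.5-7.5 Hz).
#' @param severity_to_tremor_amp,severity_to_cycle_rate,severity_to_cycle_amp
#'   monotone maps from score 0-4, see Details.
#' @param noise_sd white sensor noise, m/s^2 per axis (default 0.05).
#' @param gravity_vector 3-vector, magnitude 9.81 m/s^2.
#' @param exercise_durations_s named numeric vector `ex1..ex8` of exercise
#'   durations in seconds. Defaults: 30 s postures for exercises 1-2, 10 s
#'   for tapping and hand movements, 5 s pronation-supination; the
#'   unscored hand-to-chest (15 s), sit-to-stand (2 s) and gait (20 s)
#'   durations are package choices.
#' @param rest_between_s rest interval between exercises (default 20 s).
#' @param transition_s_range postural-transition duration range (default
#'   1-3 s).
#' @param tremor_duty fraction of each rest/postural segment carrying tremor
#'   (default 1 = the whole segment).
#' @param severity_probs probability weights over scores 0..4 used to draw
#'   each PD subject's item severities.
#' @param week_jitter_prob probability that a subject's item score moves by
#'   +/-1 (clipped to 0..4) in a given week.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 6L,
                       n_control = 0L,
                       trials_per_subject = 1L,
                       sampling_rate_hz = 50,
                       tremor_freq_range = c(3.5, 7.5),
                       severity_to_tremor_amp = function(s) 0.25 * s,
                       severity_to_cycle_rate = function(s) 2.0 - 0.3 * s,
                       severity_to_cycle_amp = function(s) 1.5 - 0.25 * s,
                       noise_sd = 0.05,
                       gravity_vector = c(0, 0, 9.81),
                       exercise_durations_s = c(ex1 = 30, ex2 = 30, ex3 = 15,
                                                ex4 = 10, ex5 = 10, ex6 = 5,
                                                ex7 = 2, ex8 = 20),
                       rest_between_s = 20,
                       transition_s_range = c(1, 3),
                       tremor_duty = 1,
                       severity_probs = c(0.25, 0.3, 0.2, 0.15, 0.1),
                       week_jitter_prob = 0.2) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_control < 0 || n_control > n_subjects)
    stop("n_control must be in 0..n_subjects")
  if (trials_per_subject < 1) stop("trials_per_subject must be >= 1")
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(exercise_durations_s <= 0) || rest_between_s <= 0 ||
      any(transition_s_range <= 0))
    stop("all durations must be positive")
  if (!identical(sort(names(exercise_durations_s)), paste0("ex", 1:8)))
    stop("exercise_durations_s must be named ex1..ex8")
  if (tremor_duty <= 0 || tremor_duty > 1)
    stop("tremor_duty must be in (0, 1]")
  if (length(severity_probs) != 5 || any(severity_probs < 0) ||
      sum(severity_probs) <= 0)
    stop("severity_probs must be 5 non-negative weights over scores 0..4 ",
         "with positive total mass")
  amps <- vapply(0:4, severity_to_tremor_amp, numeric(1))
  if (any(amps < 0)) stop("severity_to_tremor_amp must be non-negative")
  if (amps[1] != 0) stop("severity_to_tremor_amp(0) must be 0")
  rates <- vapply(0:4, severity_to_cycle_rate, numeric(1))
  if (any(diff(rates) >= 0))
    stop("severity_to_cycle_rate must be strictly decreasing on 0..4")
  if (any(rates <= 0))
    stop("severity_to_cycle_rate must stay positive on 0..4")
  if (any(vapply(0:4, severity_to_cycle_amp, numeric(1)) < 0))
    stop("severity_to_cycle_amp must be non-negative")
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_control = as.integer(n_control),
                 trials_per_subject = as.integer(trials_per_subject),
                 sampling_rate_hz = sampling_rate_hz,
                 tremor_freq_range = tremor_freq_range,
                 severity_to_tremor_amp = severity_to_tremor_amp,
                 severity_to_cycle_rate = severity_to_cycle_rate,
                 severity_to_cycle_amp = severity_to_cycle_amp,
                 noise_sd = noise_sd, gravity_vector = gravity_vector,
                 exercise_durations_s = exercise_durations_s,
                 rest_between_s = rest_between_s,
                 transition_s_range = transition_s_range,
                 tremor_duty = tremor_duty,
                 severity_probs = severity_probs / sum(severity_probs),
                 week_jitter_prob = week_jitter_prob),
            class = "sim_config")
}

# small deterministic trial seed derived from master seed + subject + week
.derive_seed <- function(seed, subject_id, week) {
  h <- sum(utf8ToInt(as.character(subject_id)) *
             seq_along(utf8ToInt(as.character(subject_id))))
  as.integer((as.numeric(seed) * 7919 + h * 131 + week * 17) %% 2147483399) + 1L
}

.rand_unit_vec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Tremor direction: wrist tremor tilts the sensor, so its accelerometer
# signature is dominated by the oscillating projection of gravity; the
# direction therefore keeps a strong gravity-aligned component plus a random
# transverse part. This is what lets the tremor fundamental survive in the
# Euclidean norm (the gravity offset acts as a sign-preserving carrier).
.tremor_direction <- function(gravity_vector) {
  g <- sqrt(sum(gravity_vector^2))
  if (g == 0) return(.rand_unit_vec())
  ghat <- gravity_vector / g
  v <- rnorm(3)
  vperp <- v - sum(v * ghat) * ghat
  nv <- sqrt(sum(vperp^2))
  if (nv > 0) vperp <- vperp / nv
  u <- ghat + 0.5 * vperp
  u / sqrt(sum(u^2))
}

# Band-limited tremor waveform: amplitude-modulated sinusoid whose
# instantaneous frequency performs a bounded random walk (+/- 0.25 Hz around
# the fundamental), so the spectrum is a narrow band rather than a pure line.
.tremor_wave <- function(n, rate, f0, amp) {
  if (amp <= 0 || n == 0) return(numeric(n))
  steps <- rnorm(n, sd = 0.02)
  fjit <- pmin(0.25, pmax(-0.25, cumsum(steps) / sqrt(seq_len(n)) * 0.25))
  phase <- 2 * pi * cumsum(f0 + fjit) / rate + runif(1, 0, 2 * pi)
  am <- 1 + 0.2 * sin(2 * pi * 0.25 * seq_len(n) / rate + runif(1, 0, 2 * pi))
  amp * am * sin(phase)
}

# Simple parametric voluntary-movement templates per exercise. Only the
# rest-tremor and pronation-supination channels need quantitative fidelity;
# the others are plausible oscillation/burst shapes so windows of every
# exercise are populated.
.voluntary_wave <- function(label, n, rate, cfg, scores) {
  t <- seq_len(n) / rate
  switch(as.character(label),
    "3" = 1.0 * sin(2 * pi * 0.67 * t),
    "4" = 0.3 * (1 - 0.15 * scores[["3.4"]]) * sin(2 * pi * 3 * t) *
            abs(sin(2 * pi * 1 * t)),
    "5" = 0.5 * (1 - 0.15 * scores[["3.5"]]) * sin(2 * pi * 2 * t),
    "6" = cfg$severity_to_cycle_amp(scores[["3.6"]]) *
            sin(2 * pi * cfg$severity_to_cycle_rate(scores[["3.6"]]) * t),
    "7" = 1.5 * sin(pi * t / max(t)),
    "8" = 1.2 * (1 - 0.1 * scores[["3.10"]]) * sin(2 * pi * 1.9 * t) +
            0.4 * sin(2 * pi * 3.8 * t),
    numeric(n))
}

#' Simulate one trial of the 8-exercise protocol
#'
#' Builds, in protocol order, a transition / exercise / transition / rest
#' sequence for the eight exercises, on a uniform 50 Hz grid. The signal is
#' `gravity + voluntary-movement template + tremor + white noise`, all in
#' m/s^2. Tremor (a band-limited oscillation at the subject's tremor
#' frequency) is injected during rest/rest-tremor intervals (label 1, scored
#' by item 3.17) and during the postural-tremor hold (exercise 2, item 3.15)
#' with amplitude `severity_to_tremor_amp(score)`. The pronation-supination
#' exercise oscillates at `severity_to_cycle_rate(score 3.6)` with amplitude
#' `severity_to_cycle_amp(score 3.6)`.
#'
#' @param config a [sim_config()].
#' @param subject_id subject identifier.
#' @param severities named integer vector of scores 0-4 for the six scored
#'   items ("3.17","3.15","3.4","3.5","3.6","3.10").
#' @param week trial week index.
#' @param group subject group label.
#' @param tremor_freq_hz optional fixed tremor fundamental; drawn uniformly
#'   from `config$tremor_freq_range` when NULL.
#' @return list with `trial` (a [trial_record()]) and `truth` (list:
#'   `severities`, `tremor_freq_hz`, `tremor_intervals` data.frame of
#'   `start_s`/`end_s` spans where tremor was injected).
#' @export
simulate_trial <- function(config, subject_id, severities, week = 1L,
                           group = "supervised", tremor_freq_hz = NULL) {
  stopifnot(inherits(config, "sim_config"))
  severities <- .validate_scores(severities)
  if (!all(SCORE_ITEMS %in% names(severities)))
    stop("severities must cover all six scored items: ",
         paste(SCORE_ITEMS, collapse = ", "))
  if (any(is.na(severities))) stop("severities must not be missing")
  set.seed(.derive_seed(config$seed, subject_id, week))
  rate <- config$sampling_rate_hz
  f0 <- if (is.null(tremor_freq_hz))
    runif(1, config$tremor_freq_range[1], config$tremor_freq_range[2])
  else tremor_freq_hz
  u_trem <- .tremor_direction(config$gravity_vector)
  # voluntary wrist movements (rotations especially) also modulate the
  # gravity projection, so they share the gravity-biased direction model
  u_vol <- .tremor_direction(config$gravity_vector)

  # protocol layout: [transition, exercise, transition, rest] x 8
  plan <- list()
  for (k in 1:8) {
    plan[[length(plan) + 1L]] <- list(
      kind = "transition", label = 0L,
      dur = runif(1, config$transition_s_range[1],
                  config$transition_s_range[2]))
    plan[[length(plan) + 1L]] <- list(
      kind = "exercise", label = if (k == 1L) 1L else as.integer(k),
      exercise = k, dur = config$exercise_durations_s[[paste0("ex", k)]])
    plan[[length(plan) + 1L]] <- list(
      kind = "transition", label = 0L,
      dur = runif(1, config$transition_s_range[1],
                  config$transition_s_range[2]))
    plan[[length(plan) + 1L]] <- list(kind = "rest", label = 1L,
                                      dur = config$rest_between_s)
  }

  segs_ax <- list(); segs_ay <- list(); segs_az <- list()
  labels <- integer(0)
  tremor_iv <- list()
  t_cursor <- 0
  for (p in plan) {
    n <- max(1L, round(p$dur * rate))
    base <- matrix(0, nrow = n, ncol = 3)
    if (p$kind == "transition") {
      ramp <- 0.8 * (1 - cos(2 * pi * seq_len(n) / n)) / 2
      base <- base + outer(ramp, u_vol)
    } else if (p$kind == "exercise" && p$exercise != 1L) {
      w <- .voluntary_wave(p$exercise, n, rate, config, severities)
      base <- base + outer(w, u_vol)
    }
    # tremor channel: rest / rest-tremor posture uses item 3.17,
    # postural hold (exercise 2) uses item 3.15
    trem_item <- if (p$label == 1L) "3.17"
      else if (p$kind == "exercise" && p$exercise == 2L) "3.15" else NA
    if (!is.na(trem_item)) {
      amp <- config$severity_to_tremor_amp(severities[[trem_item]])
      if (amp > 0) {
        n_trem <- max(1L, round(n * config$tremor_duty))
        w <- c(.tremor_wave(n_trem, rate, f0, amp), numeric(n - n_trem))
        base <- base + outer(w, u_trem)
        tremor_iv[[length(tremor_iv) + 1L]] <-
          c(t_cursor, t_cursor + n_trem / rate)
      }
    }
    if (config$noise_sd > 0)
      base <- base + matrix(rnorm(3 * n, sd = config$noise_sd), ncol = 3)
    segs_ax[[length(segs_ax) + 1L]] <- base[, 1] + config$gravity_vector[1]
    segs_ay[[length(segs_ay) + 1L]] <- base[, 2] + config$gravity_vector[2]
    segs_az[[length(segs_az) + 1L]] <- base[, 3] + config$gravity_vector[3]
    labels <- c(labels, rep(p$label, n))
    t_cursor <- t_cursor + n / rate
  }
  nall <- length(labels)
  sig <- triaxial_signal((seq_len(nall) - 1L) / rate,
                         unlist(segs_ax), unlist(segs_ay), unlist(segs_az),
                         rate)
  trial <- trial_record(subject_id, group, week, sig, labels,
                        scores = severities)
  iv <- if (length(tremor_iv))
    data.frame(start_s = vapply(tremor_iv, `[`, numeric(1), 1),
               end_s = vapply(tremor_iv, `[`, numeric(1), 2))
  else data.frame(start_s = numeric(0), end_s = numeric(0))
  list(trial = trial,
       truth = list(severities = severities, tremor_freq_hz = f0,
                    tremor_intervals = iv))
}

#' Simulate a rest segment with tremor injected in given intervals
#'
#' A focused generator for tremor-labeling experiments: a static (gravity
#' only) rest posture of `duration_s` seconds with a band-limited tremor
#' burst of amplitude `amp` and fundamental `freq_hz` injected over each of
#' `intervals` (seconds), plus white noise.
#'
#' @param duration_s segment duration (s).
#' @param intervals data.frame or 2-column matrix of `start_s`,`end_s` spans.
#' @param amp tremor amplitude (m/s^2).
#' @param freq_hz tremor fundamental (Hz).
#' @param rate sampling rate (Hz).
#' @param noise_sd white-noise level per axis (m/s^2).
#' @param gravity_vector gravity offset.
#' @param seed RNG seed.
#' @return list with `signal` (a [triaxial_signal()]) and `truth`
#'   (the interval data.frame actually used).
#' @export
simulate_rest_segment <- function(duration_s, intervals, amp, freq_hz,
                                  rate = 50, noise_sd = 0.05,
                                  gravity_vector = c(0, 0, 9.81),
                                  seed = 1L) {
  set.seed(seed)
  intervals <- as.data.frame(intervals)
  names(intervals) <- c("start_s", "end_s")
  n <- round(duration_s * rate)
  u <- .tremor_direction(gravity_vector)
  x <- numeric(n)
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals$start_s[i] * rate) + 1L)
    i1 <- min(n, ceiling(intervals$end_s[i] * rate))
    if (i1 >= i0)
      x[i0:i1] <- .tremor_wave(i1 - i0 + 1L, rate, freq_hz, amp)
  }
  base <- outer(x, u)
  if (noise_sd > 0)
    base <- base + matrix(rnorm(3 * n, sd = noise_sd), ncol = 3)
  sig <- triaxial_signal((seq_len(n) - 1L) / rate,
                         base[, 1] + gravity_vector[1],
                         base[, 2] + gravity_vector[2],
                         base[, 3] + gravity_vector[3], rate)
  list(signal = sig, truth = intervals)
}

#' Simulate a full cohort and (optionally) write it to disk
#'
#' Draws per-subject item severities from `config$severity_probs` (healthy
#' controls get 0 on every item), keeps them stable across that subject's
#' weekly trials up to a +/-1 week-to-week jitter, and simulates
#' `trials_per_subject` trials per subject. When `out_dir` is given the
#' trials are written in the session layout (one directory per trial) along
#' with `manifest.json` and `ground_truth.json`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list of per-trial lists (`trial`, `truth`), invisibly carrying
#'   the output directory as attribute `out_dir` when written.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pd <- config$n_subjects - config$n_control
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  is_control <- seq_len(config$n_subjects) > n_pd
  base_sev <- lapply(seq_len(config$n_subjects), function(i) {
    if (is_control[i]) setNames(rep(0, 6), SCORE_ITEMS)
    else setNames(sample(0:4, 6, replace = TRUE,
                         prob = config$severity_probs), SCORE_ITEMS)
  })
  tremor_f <- runif(config$n_subjects, config$tremor_freq_range[1],
                    config$tremor_freq_range[2])
  out <- list()
  for (i in seq_len(config$n_subjects)) {
    sev <- base_sev[[i]]
    for (w in seq_len(config$trials_per_subject)) {
      sev_w <- sev
      if (!is_control[i] && w > 1L) {
        jit <- rbinom(6, 1, config$week_jitter_prob) *
          (2 * rbinom(6, 1, 0.5) - 1)
        sev_w <- setNames(pmin(4, pmax(0, sev + jit)), names(sev))
      }
      res <- simulate_trial(config, subjects[i], sev_w, week = w,
                            group = if (is_control[i]) "control"
                                    else "supervised",
                            tremor_freq_hz = tremor_f[i])
      out[[length(out) + 1L]] <- res
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ids <- vapply(out, function(r)
      sprintf("%s_w%02d", r$trial$subject_id, r$trial$week), character(1))
    for (j in seq_along(out))
      write_trial(out[[j]]$trial, file.path(out_dir, ids[j]))
    jsonlite::write_json(list(trials = ids, seed = config$seed,
                              sampling_rate_hz = config$sampling_rate_hz),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    truths <- lapply(out, function(r) {
      list(trial_id = sprintf("%s_w%02d", r$trial$subject_id, r$trial$week),
           severities = as.list(r$truth$severities),
           tremor_freq_hz = r$truth$tremor_freq_hz,
           tremor_intervals = r$truth$tremor_intervals)
    })
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(out, "out_dir") <- out_dir
  }
  invisible(out)
}
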