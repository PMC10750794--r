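#' Configuration for continuous resting-tremor labeling
#'
#' Tremor presence is decided window by window from the power of the
#' high-passed movement norm inside the wrist tremor band (3.5-7.5 Hz),
#' against an empirical band-power threshold. Supra-threshold windows are
#' dilated to sample spans; gaps shorter than `merge_gap_s` are merged and
#' spans shorter than `min_duration_s` are dropped, yielding interval-style
#' labels a reviewer could correct.
#'
#' @param f_lo,f_hi tremor band edges (Hz), default 3.5-7.5.
#' @param window_samples analysis window length (default 128).
#' @param overlap_fraction window overlap (default 0.5).
#' @param threshold band-power threshold, (m/s^2)^2; see
#'   [calibrate_threshold()].
#' @param min_duration_s minimum reported interval length (default 1 s).
#' @param merge_gap_s sub-threshold gaps up to this length are merged
#'   (default 0.5 s).
#' @return An object of class `tremor_label_config`.
#' @export
tremor_label_config <- function(f_lo = 3.5, f_hi = 7.5,
                                window_samples = 128L,
                                overlap_fraction = 0.5,
                                threshold = 0.01,
                                min_duration_s = 1.0, merge_gap_s = 0.5) {
  if (threshold <= 0) stop("threshold must be positive")
  if (f_lo < 0 || f_hi <= f_lo) stop("band must satisfy 0 <= f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi,
                 window_samples = as.integer(window_samples),
                 overlap_fraction = overlap_fraction, threshold = threshold,
                 min_duration_s = min_duration_s, merge_gap_s = merge_gap_s),
            class = "tremor_label_config")
}

# Per-window tremor-band power trace of a norm signal.
.tremor_power_trace <- function(norm, cfg) {
  rate <- norm$sampling_rate_hz
  wcfg <- windowing_config(cfg$window_samples, cfg$overlap_fraction)
  starts <- .window_starts(length(norm$a), wcfg)
  if (length(starts) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      t_center = numeric(0), power = numeric(0)))
  W <- cfg$window_samples
  power <- vapply(starts, function(s) {
    x <- norm$a[s:(s + W - 1L)]
    band_power(x - mean(x), cfg$f_lo, min(cfg$f_hi, rate / 2 * 0.999),
               rate = rate, nseg = W)
  }, numeric(1))
  data.frame(start = starts, end = starts + W,
             t_center = norm$t[starts] + (W / 2) / rate, power = power)
}

# Merge sample spans whose gap is <= merge_gap samples, drop short ones.
.clean_spans <- function(spans, merge_gap, min_len) {
  if (nrow(spans) == 0) return(spans)
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    j <- nrow(out)
    if (spans$start[i] - out$end[j] <= merge_gap)
      out$end[j] <- max(out$end[j], spans$end[i])
    else out <- rbind(out, spans[i, ])
  }
  out[out$end - out$start >= min_len, , drop = FALSE]
}

#' Label resting-tremor intervals in a rest-segment norm
#'
#' @param norm a [norm_signal()]: the high-passed Euclidean norm of one rest
#'   segment.
#' @param cfg a [tremor_label_config()].
#' @return An object of class `tremor_intervals`: list with `intervals`
#'   (data.frame `start_s`,`end_s`, sorted, non-overlapping, each at least
#'   `min_duration_s`) and `trace` (per-window band-power audit trail).
#' @export
label_tremor <- function(norm, cfg = tremor_label_config()) {
  stopifnot(inherits(norm, "norm_signal"))
  rate <- norm$sampling_rate_hz
  trace <- .tremor_power_trace(norm, cfg)
  if (nrow(trace) == 0)
    warning("segment shorter than one analysis window; no intervals")
  # per-sample strict-majority vote over the overlapping windows covering
  # each sample: plain union of supra-threshold windows would dilate every
  # tremor span by almost a full window on each side
  n <- length(norm$a)
  total <- integer(n)
  supra <- integer(n)
  for (i in seq_len(nrow(trace))) {
    ii <- trace$start[i]:(trace$end[i] - 1L)
    total[ii] <- total[ii] + 1L
    if (trace$power[i] > cfg$threshold) supra[ii] <- supra[ii] + 1L
  }
  lab <- total > 0L & 2L * supra > total
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  hot <- data.frame(start = (c(0L, head(ends, -1L)) + 1L)[runs$values],
                    end = (ends + 1L)[runs$values])
  spans <- .clean_spans(hot, merge_gap = cfg$merge_gap_s * rate,
                        min_len = cfg$min_duration_s * rate)
  t0 <- if (length(norm$t)) norm$t[1] else 0
  intervals <- data.frame(
    start_s = t0 + (spans$start - 1L) / rate,
    end_s = t0 + (spans$end - 1L) / rate)
  structure(list(intervals = intervals, trace = trace, config = cfg),
            class = "tremor_intervals")
}

#' @export
print.tremor_intervals <- function(x, ...) {
  cat(sprintf("<tremor_intervals: %d interval(s), %.1f s labeled, threshold %g>\n",
              nrow(x$intervals), sum(x$intervals$end_s - x$intervals$start_s),
              x$config$threshold))
  invisible(x)
}

# Window-level truth: a window is "tremor" when its center falls inside a
# ground-truth tremor interval.
.window_truth <- function(trace, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(trace)))
  vapply(trace$t_center, function(tc)
    any(tc >= intervals$start_s & tc < intervals$end_s), logical(1))
}

#' Calibrate the tremor band-power threshold on ground-truthed data
#'
#' The study-style thresholds are "empirical"; this provides a reproducible
#' surrogate. It pools the per-window tremor-band powers of every rest
#' (label 1) segment across the cohort, labels each window by the simulator
#' ground truth, and sweeps candidate thresholds (midpoints between sorted
#' distinct powers) to maximize Youden's J = sensitivity + specificity - 1.
#'
#' @param cohort list of `list(trial =, truth =)` entries as returned by
#'   [simulate_cohort()].
#' @param cfg a [tremor_label_config()] (its `threshold` is ignored).
#' @param spec a [filter_spec()] applied to each rest segment.
#' @return list: `threshold`, `J`, `sensitivity`, `specificity`, `n_windows`.
#' @export
calibrate_threshold <- function(cohort, cfg = tremor_label_config(),
                                spec = filter_spec()) {
  powers <- numeric(0)
  truth <- logical(0)
  for (entry in cohort) {
    trial <- entry$trial
    iv <- entry$truth$tremor_intervals
    segs <- trial$segments[trial$segments$label_code == 1L, , drop = FALSE]
    for (si in seq_len(nrow(segs))) {
      idx <- (segs$start[si] + 1L):segs$end[si]
      sub <- triaxial_signal(trial$signal$t[idx], trial$signal$ax[idx],
                             trial$signal$ay[idx], trial$signal$az[idx],
                             trial$signal$sampling_rate_hz)
      nrm <- norm_highpass(sub, spec)
      trace <- .tremor_power_trace(nrm, cfg)
      if (nrow(trace) == 0) next
      powers <- c(powers, trace$power)
      truth <- c(truth, .window_truth(trace, iv))
    }
  }
  if (length(powers) == 0) stop("no rest-segment windows found in cohort")
  if (all(truth) || !any(truth))
    stop("cohort must contain both tremor and non-tremor rest windows")
  o <- order(powers)
  ps <- powers[o]
  cand <- unique((head(ps, -1) + tail(ps, -1)) / 2)
  best <- list(J = -Inf)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  for (th in cand) {
    pred <- powers > th
    sens <- sum(pred & truth) / n_pos
    spec_ <- sum(!pred & !truth) / n_neg
    J <- sens + spec_ - 1
    if (J > best$J)
      best <- list(threshold = th, J = J, sensitivity = sens,
                   specificity = spec_)
  }
  c(best, list(n_windows = length(powers)))
}
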