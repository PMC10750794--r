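#' Default symptom frequency-band registry
#'
#' The seven bands used as per-segment spectral indicators of Parkinsonian
#' motor symptoms: freezing of gait (3-8 Hz), tremor (4-6 Hz), extended
#' tremor (3-8 Hz), bradykinesia/dyskinesia (0-3 Hz), gait (1-3 Hz),
#' dyskinesia (1-4 Hz) and the full human-movement band (0-20 Hz).
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name = c("freeze", "tremor46", "tremor38", "bradydysk", "gait",
             "dysk14", "full"),
    f_lo = c(3, 4, 3, 0, 1, 1, 0),
    f_hi = c(8, 6, 8, 3, 3, 4, 20)
  )
}

.check_band <- function(f_lo, f_hi, nyquist) {
  if (f_lo < 0 || f_hi <= f_lo)
    stop("band must satisfy 0 <= f_lo < f_hi")
  if (f_lo >= nyquist)
    stop(sprintf("band [%g, %g) lies outside [0, Nyquist = %g] Hz",
                 f_lo, f_hi, nyquist))
}

#' Windowing configuration for sliding-window features
#'
#' The default (128 samples, 50% overlap) is 2.56 s at 50 Hz, the standard
#' activity-recognition window length.
#'
#' @param window_samples window length in samples (>= 8).
#' @param overlap_fraction overlap in `[0, 1)`.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_samples = 128L, overlap_fraction = 0.5) {
  if (window_samples < 8) stop("window_samples must be >= 8")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  structure(list(window_samples = as.integer(window_samples),
                 overlap_fraction = overlap_fraction),
            class = "windowing_config")
}

#' Number of full windows in a segment
#'
#' `floor((L - W) / (W * (1 - overlap))) + 1` for `L >= W`, else 0. Windows
#' straddling a segment boundary are never counted: every window lies fully
#' inside one labeled segment.
#'
#' @param n_samples segment length L.
#' @param cfg a [windowing_config()].
#' @return integer window count.
#' @export
window_count <- function(n_samples, cfg = windowing_config()) {
  W <- cfg$window_samples
  if (n_samples < W) return(0L)
  step <- W * (1 - cfg$overlap_fraction)
  as.integer(floor((n_samples - W) / step) + 1)
}

.window_starts <- function(n_samples, cfg) {
  k <- window_count(n_samples, cfg)
  if (k == 0L) return(integer(0))
  step <- cfg$window_samples * (1 - cfg$overlap_fraction)
  1L + as.integer(round((seq_len(k) - 1L) * step))
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended segments of length `min(nseg, length(x))`
#' with 50% overlap, averaged one-sided density scaling: the integral of the
#' returned density over frequency approximates the signal's variance
#' (total power).
#'
#' @param x numeric samples.
#' @param rate sampling rate (Hz).
#' @param nseg maximum segment length (default 256).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate, nseg = 256L) {
  n <- length(x)
  if (n < 8) stop("need at least 8 samples for a PSD estimate")
  nseg <- min(as.integer(nseg), n)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))  # Hann
  scale <- 1 / (rate * sum(w^2))
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nfreq)])^2 * scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * rate / nseg, psd = psd * dbl)
}

# Trapezoidal integral of a PSD over [f_lo, f_hi], with linear interpolation
# of the density at the band edges so that disjoint bands sharing an edge add
# exactly to the power of their union.
.psd_band_integral <- function(freq, psd, f_lo, f_hi) {
  f_hi <- min(f_hi, max(freq))
  f_lo <- max(f_lo, min(freq))
  if (f_hi <= f_lo) return(0)
  inner <- freq > f_lo & freq < f_hi
  fgrid <- c(f_lo, freq[inner], f_hi)
  pgrid <- approx(freq, psd, xout = fgrid, rule = 2)$y
  sum(diff(fgrid) * (head(pgrid, -1L) + tail(pgrid, -1L)) / 2)
}

#' Band power of a norm signal
#'
#' Power in `[f_lo, f_hi)` Hz, defined as the trapezoidal integral of the
#' Welch power spectral density over the band. Units: (m/s^2)^2 when the
#' input is acceleration. Non-negative, and additive over disjoint bands up
#' to discretization error.
#'
#' @param norm a [norm_signal()] (or numeric vector with `rate` given).
#' @param f_lo,f_hi band edges in Hz.
#' @param rate sampling rate; taken from `norm` when it is a `norm_signal`.
#' @param nseg Welch segment length cap (default 256).
#' @return band power (scalar).
#' @export
band_power <- function(norm, f_lo, f_hi, rate = NULL, nseg = 256L) {
  if (inherits(norm, "norm_signal")) {
    rate <- norm$sampling_rate_hz
    x <- norm$a
  } else {
    if (is.null(rate)) stop("rate is required for a plain numeric input")
    x <- as.numeric(norm)
  }
  .check_band(f_lo, f_hi, rate / 2)
  p <- welch_psd(x, rate, nseg)
  .psd_band_integral(p$freq, p$psd, f_lo, f_hi)
}

# Adjusted Fisher-Pearson (bias-corrected) skewness; NA for constant input.
.skewness <- function(x) {
  if (length(x) < 3 || sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}

#' Per-segment feature vector: 8 time-domain + 7 band-power features
#'
#' Computed on the entire segment of the movement norm: standard deviation,
#' mean, median, 25th and 75th percentiles, skewness (bias-corrected),
#' maximum and minimum, plus the power in each band of `bands`. Segments
#' shorter than `min_spectral_s` get time features only (band powers NA);
#' constant segments report skewness as NA (undefined).
#'
#' @param norm a [norm_signal()] holding one segment.
#' @param bands band registry data.frame, see [default_bands()].
#' @param min_spectral_s minimum segment duration for spectral estimates
#'   (default 2 s).
#' @return named numeric vector of 8 + `nrow(bands)` features.
#' @export
segment_features <- function(norm, bands = default_bands(),
                             min_spectral_s = 2) {
  stopifnot(inherits(norm, "norm_signal"))
  x <- norm$a
  if (length(x) == 0) stop("empty segment")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  feats <- c(std = sd(x), mean = mean(x), median = median(x),
             p25 = q[1], p75 = q[2], skewness = .skewness(x),
             max = max(x), min = min(x))
  bp <- setNames(rep(NA_real_, nrow(bands)), paste0("bp_", bands$name))
  if (length(x) >= min_spectral_s * norm$sampling_rate_hz && length(x) >= 8) {
    p <- welch_psd(x - mean(x), norm$sampling_rate_hz)
    for (i in seq_len(nrow(bands))) {
      f_hi <- min(bands$f_hi[i], norm$sampling_rate_hz / 2)
      bp[i] <- .psd_band_integral(p$freq, p$psd, bands$f_lo[i], f_hi)
    }
  }
  c(feats, bp)
}

#' Jerk (time derivative of acceleration)
#'
#' Forward first difference scaled by the sampling rate; output is one sample
#' shorter than the input.
#'
#' @param x numeric channel samples.
#' @param rate sampling rate (Hz).
#' @return numeric vector of length `length(x) - 1`.
#' @export
jerk <- function(x, rate) {
  if (length(x) < 2) stop("jerk needs at least 2 samples")
  diff(x) * rate
}

# --- sliding-window activity-recognition features ---------------------------

.zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

.hist_entropy <- function(x, nbins = 16L) {
  m <- abs(x)
  if (diff(range(m)) == 0) return(0)
  h <- tabulate(pmin(nbins, 1L + floor((m - min(m)) / diff(range(m)) * nbins)),
                nbins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.window_channel_features <- function(x, rate, bands) {
  s <- sd(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  ac1 <- if (s == 0) NA_real_ else {
    xc <- x - mean(x)
    sum(head(xc, -1L) * tail(xc, -1L)) / sum(xc^2)
  }
  tf <- c(mean = mean(x), std = s, median = median(x), mad = mad(x),
          min = min(x), max = max(x), iqr = q[2] - q[1],
          energy = mean(x^2), skewness = .skewness(x),
          kurtosis = if (s == 0) NA_real_ else e1071::kurtosis(x, type = 2),
          ac1 = ac1, zcr = as.numeric(.zero_crossings(x - mean(x))),
          hist_entropy = .hist_entropy(x))
  p <- welch_psd(x - mean(x), rate, nseg = length(x))
  psd <- p$psd
  freq <- p$freq
  tot <- sum(psd)
  sf <- if (tot > 0) {
    pn <- psd / tot
    pn_pos <- pn[pn > 0]
    c(domfreq = freq[which.max(psd)],
      spec_centroid = sum(freq * pn),
      spec_entropy = -sum(pn_pos * log2(pn_pos)) / log2(length(pn)))
  } else {
    c(domfreq = 0, spec_centroid = 0, spec_entropy = 0)
  }
  bp <- vapply(seq_len(nrow(bands)), function(i)
    .psd_band_integral(freq, psd, bands$f_lo[i],
                       min(bands$f_hi[i], rate / 2)),
    numeric(1))
  names(bp) <- paste0("bp_", bands$name)
  c(tf, sf, bp)
}

#' Sliding-window feature table over raw axes, norm and jerk channels
#'
#' High-passes the trial's axes, then computes a registry of
#' activity-recognition features on each full window (2.56 s / 128 samples,
#' 50% overlap by default) of each of eight channels: the three filtered
#' axes, their Euclidean norm, and the jerk of all four. Per-window features
#' per channel: mean, std, median, MAD, min, max, IQR, energy, skewness,
#' kurtosis, lag-1 autocorrelation, zero crossings, histogram entropy of the
#' magnitude, dominant frequency, spectral centroid, normalized spectral
#' entropy, and the band energies of `bands`; plus the signal-magnitude area
#' of each triaxial group. Each row carries the window's segment label and,
#' for scored exercises, the trial's MDS-UPDRS item and score.
#'
#' @param trial a [trial_record()].
#' @param cfg a [windowing_config()].
#' @param bands band registry, see [default_bands()].
#' @param spec a [filter_spec()] applied before feature extraction.
#' @return data.frame: one row per window with metadata columns
#'   `trial_id, subject_id, group, week, label_code, window_index,
#'   score_item, score` followed by the feature columns.
#' @export
windowed_features <- function(trial, cfg = windowing_config(),
                              bands = default_bands(),
                              spec = filter_spec()) {
  stopifnot(inherits(trial, "trial_record"))
  filt <- highpass(trial$signal, spec)
  rate <- filt$sampling_rate_hz
  nrm <- sqrt(filt$ax^2 + filt$ay^2 + filt$az^2)
  chans <- list(ax = filt$ax, ay = filt$ay, az = filt$az, norm = nrm)
  trial_id <- sprintf("%s_w%02d", trial$subject_id, trial$week)
  rows <- list()
  for (si in seq_len(nrow(trial$segments))) {
    seg <- trial$segments[si, ]
    idx <- (seg$start + 1L):seg$end
    starts <- .window_starts(length(idx), cfg)
    if (length(starts) == 0) next
    item <- EXERCISE_ITEMS[as.character(seg$label_code)]
    score <- if (!is.na(item) && item %in% names(trial$scores))
      trial$scores[[item]] else NA_real_
    for (wi in seq_along(starts)) {
      sel <- idx[starts[wi]:(starts[wi] + cfg$window_samples - 1L)]
      f <- unlist(lapply(names(chans), function(nm) {
        x <- chans[[nm]][sel]
        stats <- .window_channel_features(x, rate, bands)
        jx <- jerk(x, rate)
        jstats <- .window_channel_features(jx, rate, bands)
        c(setNames(stats, paste0(nm, "_", names(stats))),
          setNames(jstats, paste0("j", nm, "_", names(jstats))))
      }))
      sma <- mean(abs(chans$ax[sel]) + abs(chans$ay[sel]) + abs(chans$az[sel]))
      jsma <- mean(abs(jerk(chans$ax[sel], rate)) +
                     abs(jerk(chans$ay[sel], rate)) +
                     abs(jerk(chans$az[sel], rate)))
      rows[[length(rows) + 1L]] <- c(
        list(trial_id = trial_id, subject_id = trial$subject_id,
             group = trial$group, week = trial$week,
             label_code = seg$label_code, window_index = wi,
             score_item = if (is.na(item)) NA_character_ else unname(item),
             score = score, sma = sma, jsma = jsma),
        as.list(f))
    }
  }
  if (length(rows) == 0) {
    warning("no segment holds a full window; returning an empty table")
    return(data.frame())
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}

#' Per-segment feature table for a set of trials
#'
#' Computes the high-passed norm per trial ([norm_highpass()] by default:
#' the gravity carrier keeps oscillatory movement sign-preserved at its
#' fundamental, which is what makes the tremor- and dyskinesia-band powers
#' track the injected oscillations) and then [segment_features()] for every
#' labeled segment, carrying the trial's scores alongside. Rest/rest-tremor
#' intervals (label 1) may occur several times per trial; `duration_s` lets
#' downstream analyses pick the exercise posture (the longest label-1
#' segment).
#'
#' @param trials list of [trial_record()] objects.
#' @param bands band registry.
#' @param spec a [filter_spec()].
#' @param norm_fun preprocessing route: [norm_highpass()] (default) or
#'   [movement_norm()] (per-axis filtering before the norm, which rectifies
#'   zero-mean oscillations).
#' @return data.frame: one row per segment with metadata
#'   (`trial_id, subject_id, group, week, label_code, duration_s`),
#'   one `score_<item>` column per MDS-UPDRS item, and the 15 features.
#' @export
segment_feature_table <- function(trials, bands = default_bands(),
                                  spec = filter_spec(),
                                  norm_fun = norm_highpass) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  rows <- lapply(trials, function(trial) {
    nrm <- norm_fun(trial$signal, spec)
    rate <- nrm$sampling_rate_hz
    scores <- setNames(rep(NA_real_, length(SCORE_ITEMS)), SCORE_ITEMS)
    scores[names(trial$scores)] <- trial$scores
    segrows <- lapply(seq_len(nrow(trial$segments)), function(si) {
      seg <- trial$segments[si, ]
      idx <- (seg$start + 1L):seg$end
      f <- segment_features(norm_signal(nrm$t[idx], nrm$a[idx], rate),
                            bands = bands)
      cbind(data.frame(trial_id = sprintf("%s_w%02d", trial$subject_id,
                                          trial$week),
                       subject_id = trial$subject_id, group = trial$group,
                       week = trial$week, label_code = seg$label_code,
                       duration_s = length(idx) / rate),
            as.data.frame(as.list(setNames(scores,
                                           paste0("score_", SCORE_ITEMS)))),
            as.data.frame(as.list(f)))
    })
    do.call(rbind, segrows)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
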