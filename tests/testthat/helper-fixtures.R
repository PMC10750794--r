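# shared fixtures and independent oracles

# uniform-grid triaxial signal from per-axis functions of time
make_signal <- function(fx, fy, fz, duration_s = 30, rate = 50) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  triaxial_signal(t, fx(t), fy(t), fz(t), rate)
}

# Independent band-power oracle: direct (single-window, no taper)
# periodogram integration. Deliberately different estimator from the
# package's Welch route.
periodogram_band_power <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  x <- x - mean(x)
  sp <- abs(fft(x))^2 / (n * rate)           # two-sided density
  k <- 0:(n - 1)
  f <- k * rate / n
  keep <- f >= f_lo & f < f_hi & f <= rate / 2
  keep2 <- (rate - f) >= f_lo & (rate - f) < f_hi & f > rate / 2
  sum(sp[keep | keep2]) * rate / n
}

# random 3x3 rotation matrix via QR decomposition
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

full_severities <- function(v) {
  stopifnot(length(v) == 6)
  stats::setNames(v, c("3.17", "3.15", "3.4", "3.5", "3.6", "3.10"))
}

interval_iou <- function(got, want) {
  inter <- max(0, min(got[2], want[2]) - max(got[1], want[1]))
  inter / ((got[2] - got[1]) + (want[2] - want[1]) - inter)
}

# steady-state amplitude of an oscillatory signal (sd * sqrt(2)), measured
# on the central region to avoid filter edges
steady_amplitude <- function(x) {
  n <- length(x)
  sd(x[round(n / 4):round(3 * n / 4)]) * sqrt(2)
}
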