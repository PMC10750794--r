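#' Construct a triaxial acceleration signal
#'
#' A lightweight container for one trial's raw stream: a uniform time grid and
#' three acceleration axes in m/s^2 (Android sensor convention: gravity
#' included, so a resting sensor reads ~9.81 on the vertical axis).
#'
#' @param t numeric vector, seconds from trial start (strictly increasing).
#' @param ax,ay,az numeric vectors, per-axis acceleration (m/s^2), same length
#'   as `t`.
#' @param sampling_rate_hz nominal sampling rate (Hz).
#' @return An object of class `triaxial_signal`.
#' @export
triaxial_signal <- function(t, ax, ay, az, sampling_rate_hz) {
  n <- length(t)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("all three axes must have the same length as t")
  if (n >= 2 && any(diff(t) <= 0))
    stop("t must be strictly increasing")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  structure(list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "triaxial_signal")
}

#' @export
length.triaxial_signal <- function(x) length(x$t)

#' @export
print.triaxial_signal <- function(x, ...) {
  cat(sprintf("<triaxial_signal: %d samples @ %g Hz, %.2f s>\n",
              length(x$t), x$sampling_rate_hz,
              if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

#' Construct a norm (magnitude) signal
#'
#' @param t numeric vector of seconds.
#' @param a numeric vector, the per-sample signal magnitude (m/s^2).
#' @param sampling_rate_hz sampling rate (Hz).
#' @return An object of class `norm_signal`.
#' @export
norm_signal <- function(t, a, sampling_rate_hz) {
  if (length(t) != length(a)) stop("t and a must have the same length")
  if (any(!is.finite(a))) stop("norm signal must be finite")
  structure(list(t = as.numeric(t), a = as.numeric(a),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "norm_signal")
}

#' High-pass filter specification
#'
#' Defaults follow the standard gravity-removal recipe for wrist
#' accelerometry: third-order Butterworth high-pass with a 0.5 Hz cutoff.
#' `zero_phase = TRUE` applies the filter forward and backward
#' (zero phase distortion, squared magnitude response); the causal single-pass
#' mode is kept for streaming-equivalent analyses.
#'
#' @param order filter order (default 3).
#' @param cutoff_hz cutoff frequency in Hz (default 0.5).
#' @param zero_phase logical; forward-backward application (default TRUE).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 3L, cutoff_hz = 0.5, zero_phase = TRUE) {
  if (order < 1) stop("filter order must be >= 1")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "high", zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Odd (point-reflected) padding as used by forward-backward filtering:
# extends the signal beyond each end by mirroring around the end value,
# which avoids step discontinuities that would excite the filter transient.
.reflect_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  left <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  list(x = c(left, x, right), npad = npad)
}

# Steady-state initial filter state for a unit-step input (direct form II
# transposed): scaling it by the first sample removes the startup transient,
# so a constant (gravity-only) input maps to an exactly-zero high-pass output.
.lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1L, n - 1L)  # companion matrix of a
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), B)
}

# Direct form II transposed IIR filter with initial state zi.
.lfilter <- function(b, a, x, zi) {
  n <- length(x)
  m <- length(a) - 1L
  y <- numeric(n)
  z <- c(zi, 0)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    for (k in seq_len(m)) z[k] <- b[k + 1L] * xi - a[k + 1L] * yi + z[k + 1L]
    y[i] <- yi
  }
  y
}

.butter_apply <- function(x, b, a, zero_phase, order) {
  zi <- .lfilter_zi(b, a)
  if (!zero_phase) return(.lfilter(b, a, x, zi * x[1L]))
  p <- .reflect_pad(x, max(12L * order, 36L))
  y <- .lfilter(b, a, p$x, zi * p$x[1L])
  y <- rev(.lfilter(b, a, rev(y), zi * y[length(y)]))
  y[seq(p$npad + 1L, p$npad + length(x))]
}

#' High-pass filter a triaxial signal (gravity removal)
#'
#' Applies the Butterworth high-pass of `spec` identically to each axis,
#' removing the quasi-static gravity component so that the Euclidean norm
#' reflects movement only. Edges are handled by odd-reflection padding of
#' at least three filter lengths, which suppresses startup transients on
#' segments as short as a few seconds.
#'
#' @param sig a [triaxial_signal()].
#' @param spec a [filter_spec()].
#' @return A `triaxial_signal` with filtered axes.
#' @export
highpass <- function(sig, spec = filter_spec()) {
  stopifnot(inherits(sig, "triaxial_signal"))
  fs <- sig$sampling_rate_hz
  if (spec$cutoff_hz >= fs / 2)
    stop(sprintf("cutoff_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 spec$cutoff_hz, fs / 2))
  minlen <- 3L * spec$order + 1L
  if (length(sig$t) <= minlen)
    stop(sprintf("signal too short for stable filtering: need > %d samples",
                 minlen))
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "high")
  triaxial_signal(
    sig$t,
    .butter_apply(sig$ax, bf$b, bf$a, spec$zero_phase, spec$order),
    .butter_apply(sig$ay, bf$b, bf$a, spec$zero_phase, spec$order),
    .butter_apply(sig$az, bf$b, bf$a, spec$zero_phase, spec$order),
    fs
  )
}

#' Per-sample Euclidean norm of a triaxial signal
#'
#' a[i] = sqrt(ax[i]^2 + ay[i]^2 + az[i]^2): the orientation-independent
#' magnitude of acceleration from which the per-segment feature set is
#' computed.
#'
#' @param sig a [triaxial_signal()].
#' @return A [norm_signal()].
#' @export
euclidean_norm <- function(sig) {
  stopifnot(inherits(sig, "triaxial_signal"))
  norm_signal(sig$t, sqrt(sig$ax^2 + sig$ay^2 + sig$az^2),
              sig$sampling_rate_hz)
}

#' High-passed Euclidean norm of the raw signal (tremor-band route)
#'
#' Computes the Euclidean norm of the raw (gravity-included) axes and then
#' high-pass filters that scalar stream. Because movement accelerations at
#' the wrist are small relative to gravity, the raw norm is, to first order,
#' `|g| + projection of movement onto the gravity direction`: the gravity
#' offset acts as a sign-preserving carrier, so an oscillation at frequency
#' f keeps its power at f (filtering the axes first and then taking the norm
#' rectifies a zero-mean oscillation, moving its power to 2f and the
#' envelope). This route is therefore the one used for tremor-band magnitude
#' analysis; the per-segment feature set uses [movement_norm()].
#'
#' @inheritParams highpass
#' @return A [norm_signal()]; values may be signed after filtering.
#' @export
norm_highpass <- function(sig, spec = filter_spec()) {
  stopifnot(inherits(sig, "triaxial_signal"))
  fs <- sig$sampling_rate_hz
  if (spec$cutoff_hz >= fs / 2)
    stop(sprintf("cutoff_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 spec$cutoff_hz, fs / 2))
  minlen <- 3L * spec$order + 1L
  if (length(sig$t) <= minlen)
    stop(sprintf("signal too short for stable filtering: need > %d samples",
                 minlen))
  a <- sqrt(sig$ax^2 + sig$ay^2 + sig$az^2)
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "high")
  norm_signal(sig$t, .butter_apply(a, bf$b, bf$a, spec$zero_phase,
                                   spec$order), fs)
}

#' Gravity removal plus norm in one step
#'
#' Convenience wrapper: high-pass each axis, then take the Euclidean norm.
#' Filtering the signed axes before the norm is the order that actually
#' removes gravity; the norm itself is non-negative and gravity-dominated,
#' so filtering it instead would leave an orientation-dependent bias.
#'
#' @inheritParams highpass
#' @return A [norm_signal()].
#' @export
movement_norm <- function(sig, spec = filter_spec()) {
  euclidean_norm(highpass(sig, spec))
}
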