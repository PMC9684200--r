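# Trial-level conditioning: linear detrend, 50 Hz IIR notch, 20-250 Hz
# Butterworth bandpass, applied to the whole trial before windowing.

#' Filter specification for the conditioning chain
#'
#' @param notch_freq mains frequency to reject, Hz.
#' @param notch_bandwidth -3 dB width of the notch, Hz. The default 2 Hz
#'   (Q = 25 at 50 Hz) is narrow enough to spare the EMG band.
#' @param bandpass_low,bandpass_high Butterworth band edges, Hz.
#' @param bandpass_order Butterworth design order per band edge (the
#'   band-pass transfer function has `2 * bandpass_order` poles, the usual
#'   convention of `butter(n, c(lo, hi))` designs).
#' @param phase_mode `"causal"` (single forward pass, the real-time choice)
#'   or `"zero-phase"` (forward-backward, for offline parity studies).
#' @param detrend `"linear"` removes the least-squares line per channel;
#'   `"constant"` removes only the mean.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_bandwidth = 2,
                        bandpass_low = 20, bandpass_high = 250,
                        bandpass_order = 4,
                        phase_mode = c("causal", "zero-phase"),
                        detrend = c("linear", "constant")) {
  phase_mode <- match.arg(phase_mode)
  detrend <- match.arg(detrend)
  stopifnot(notch_freq > 0, notch_bandwidth > 0,
            bandpass_low > 0, bandpass_high > bandpass_low,
            bandpass_order >= 1)
  structure(list(
    notch_freq = notch_freq, notch_order = 2L,
    notch_bandwidth = notch_bandwidth,
    bandpass_low = bandpass_low, bandpass_high = bandpass_high,
    bandpass_order = as.integer(bandpass_order),
    phase_mode = phase_mode, detrend = detrend
  ), class = "filter_spec")
}

#' Design the 2nd-order IIR notch for a given sampling rate
#'
#' Constrained biquad notch: zeros on the unit circle at the notch frequency,
#' poles pulled inside so the -3 dB width equals `notch_bandwidth`. Stability
#' (all poles strictly inside the unit circle) is checked at design time.
#'
#' @param spec a [filter_spec()].
#' @param sampling_rate Hz.
#' @return A `signal::Arma` filter object.
#' @export
design_notch <- function(spec, sampling_rate) {
  f0 <- spec$notch_freq
  if (f0 >= sampling_rate / 2) {
    stop("notch frequency must be below the Nyquist frequency", call. = FALSE)
  }
  w0 <- 2 * pi * f0 / sampling_rate
  q <- f0 / spec$notch_bandwidth
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  .check_stable(flt, "notch")
  flt
}

#' Design the Butterworth bandpass for a given sampling rate
#'
#' @inheritParams design_notch
#' @return A `signal::Arma` filter object.
#' @export
design_bandpass <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  if (spec$bandpass_high >= nyq) {
    stop("bandpass edges must lie below the Nyquist frequency", call. = FALSE)
  }
  bt <- signal::butter(spec$bandpass_order,
                       c(spec$bandpass_low, spec$bandpass_high) / nyq,
                       type = "pass")
  flt <- signal::Arma(b = bt$b, a = bt$a)
  .check_stable(flt, "bandpass")
  flt
}

.check_stable <- function(flt, what) {
  poles <- polyroot(rev(flt$a))
  if (any(Mod(poles) >= 1)) {
    stop(sprintf("designed %s filter is unstable", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Gain of a designed filter at given frequencies
#'
#' @param flt a `signal::Arma` filter.
#' @param freq frequencies, Hz.
#' @param sampling_rate Hz.
#' @return Magnitude gain (linear, not dB) at each frequency.
#' @export
filter_gain <- function(flt, freq, sampling_rate) {
  w <- 2 * pi * freq / sampling_rate
  z <- exp(1i * w)
  num <- outer(z, 0:(length(flt$b) - 1), function(zz, k) zz^(-k)) %*% flt$b
  den <- outer(z, 0:(length(flt$a) - 1), function(zz, k) zz^(-k)) %*% flt$a
  as.numeric(Mod(num / den))
}

.as_samples <- function(x) {
  if (inherits(x, "emg_recording")) x$samples else as.matrix(x)
}

.rewrap <- function(x, samples) {
  if (inherits(x, "emg_recording")) { x$samples <- samples; x } else samples
}

.apply_filter <- function(flt, samples, phase_mode) {
  out <- samples
  for (j in seq_len(ncol(samples))) {
    out[, j] <- if (phase_mode == "zero-phase") {
      signal::filtfilt(flt, samples[, j])
    } else {
      as.numeric(signal::filter(flt, samples[, j]))
    }
  }
  out
}

#' Remove the per-channel linear trend
#'
#' Subtracts the least-squares straight line (or, with
#' `spec$detrend = "constant"`, just the mean) from each channel over the
#' whole trial.
#'
#' @param x an `emg_recording` or an n x channels numeric matrix.
#' @param spec a [filter_spec()]; only its `detrend` field is used.
#' @return Same type as `x`.
#' @export
detrend_linear <- function(x, spec = filter_spec()) {
  samples <- .as_samples(x)
  n <- nrow(samples)
  if (n < 2L) stop("detrending needs at least 2 samples", call. = FALSE)
  if (spec$detrend == "constant") {
    out <- sweep(samples, 2, colMeans(samples))
  } else {
    tt <- seq_len(n)
    X <- cbind(1, tt - mean(tt))
    coef <- qr.solve(X, samples)          # least-squares line per channel
    out <- samples - X %*% coef
  }
  .rewrap(x, out)
}

#' Apply the 2nd-order 50 Hz IIR notch
#'
#' @param x an `emg_recording` or numeric matrix.
#' @param spec a [filter_spec()].
#' @param sampling_rate required when `x` is a bare matrix; taken from the
#'   recording otherwise.
#' @return Same type as `x`.
#' @export
notch_filter <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  fs <- if (inherits(x, "emg_recording")) x$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate must be supplied for matrix input",
                        call. = FALSE)
  flt <- design_notch(spec, fs)
  .rewrap(x, .apply_filter(flt, .as_samples(x), spec$phase_mode))
}

#' Apply the Butterworth bandpass
#'
#' @inheritParams notch_filter
#' @return Same type as `x`.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  fs <- if (inherits(x, "emg_recording")) x$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate must be supplied for matrix input",
                        call. = FALSE)
  flt <- design_bandpass(spec, fs)
  .rewrap(x, .apply_filter(flt, .as_samples(x), spec$phase_mode))
}

#' Full conditioning chain for one trial
#'
#' Detrend, then notch, then bandpass, applied to the whole trial before any
#' windowing. A recording is marked `preprocessed` afterwards and refuses a
#' second pass.
#'
#' @param recording an `emg_recording`.
#' @param spec a [filter_spec()].
#' @return The preprocessed `emg_recording`, with the applied spec recorded
#'   in its provenance.
#' @export
preprocess_trial <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "emg_recording"))
  if (isTRUE(recording$preprocessed)) {
    stop("recording has already been preprocessed; re-filtering would ",
         "distort the signal", call. = FALSE)
  }
  out <- detrend_linear(recording, spec)
  out <- notch_filter(out, spec)
  out <- bandpass_filter(out, spec)
  out$preprocessed <- TRUE
  out$provenance$preprocessing <- list(
    detrend = spec$detrend, notch_freq = spec$notch_freq,
    notch_order = spec$notch_order, notch_bandwidth = spec$notch_bandwidth,
    bandpass = c(spec$bandpass_low, spec$bandpass_high),
    bandpass_order = spec$bandpass_order, phase_mode = spec$phase_mode
  )
  out
}
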