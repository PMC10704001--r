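#' Two-channel bounded audio buffer
#'
#' A `waveform` is the container for every synthesized signal in the package:
#' a numeric sample matrix (one column per channel) bounded to \[-1, 1\],
#' together with its sample rate and the measured per-channel level in dB re
#' full-scale RMS (0 dB = an RMS of 1.0).
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel;
#'   all values must lie in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `waveform` with elements `samples` (matrix),
#'   `sample_rate`, `n_channels`, and `rms_db` (per-channel level in dB FS).
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)) * 0.1, 8000)
#' w$rms_db
#' @export
waveform <- function(samples, sample_rate) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  dimnames(samples) <- NULL
  storage.mode(samples) <- "double"
  if (!ncol(samples) %in% c(1L, 2L)) {
    stop("waveform supports 1 or 2 channels, got ", ncol(samples))
  }
  if (anyNA(samples)) stop("waveform samples contain NA")
  peak <- max(abs(samples))
  if (peak > 1 + 1e-12) {
    stop(sprintf("waveform samples exceed full scale (peak %.4f > 1)", peak))
  }
  structure(
    list(
      samples = samples,
      sample_rate = as.numeric(sample_rate),
      n_channels = ncol(samples),
      rms_db = apply(samples, 2, amp_to_db_rms)
    ),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d ch, %d samples (%.3f s @ %g Hz), RMS %s dB FS\n",
    x$n_channels, nrow(x$samples), nrow(x$samples) / x$sample_rate,
    x$sample_rate, paste(sprintf("%.1f", x$rms_db), collapse = " / ")
  ))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave A `waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(wave) nrow(wave$samples) / wave$sample_rate

# dB re full-scale RMS of a sample vector; -Inf for silence
amp_to_db_rms <- function(x) {
  r <- sqrt(mean(x^2))
  if (r == 0) -Inf else 20 * log10(r)
}

#' Per-channel RMS level in dB re full scale
#' @param wave A `waveform`.
#' @return Numeric vector, one dB-FS value per channel.
#' @export
rms_db <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  apply(wave$samples, 2, amp_to_db_rms)
}

db_to_amp <- function(db) 10^(db / 20)

#' Calibration reference level with fixed headroom
#'
#' Every task presents a calibration sound whose measured level anchors the
#' playback volume the listener chooses; task stimuli are then constrained to
#' at most `max_headroom_db` (6 dB) above that reference.
#'
#' @param rms_db Reference level in dB re full-scale RMS (scalar; for stereo
#'   calibration sounds, the maximum across channels).
#' @param max_headroom_db Permitted excess of any stimulus over the reference,
#'   in dB. Fixed at 6 by the study design.
#' @return An object of class `calibration_reference`.
#' @export
calibration_reference <- function(rms_db, max_headroom_db = 6) {
  stopifnot(is.finite(rms_db), max_headroom_db >= 0)
  structure(
    list(rms_db = rms_db, max_headroom_db = max_headroom_db),
    class = "calibration_reference"
  )
}

#' Check a stimulus against the calibration headroom limit
#'
#' @param wave A `waveform`.
#' @param reference A [calibration_reference()].
#' @return `TRUE` if every channel of `wave` is no more than the permitted
#'   headroom above the reference level, else `FALSE`.
#' @export
check_headroom <- function(wave, reference) {
  stopifnot(inherits(wave, "waveform"),
            inherits(reference, "calibration_reference"))
  all(rms_db(wave) <= reference$rms_db + reference$max_headroom_db + 1e-9)
}

# ---- internal DSP primitives ------------------------------------------------

# Raised-cosine (Hann) on/off taper applied in place.
# ramp_dur in seconds; each taper spans ramp_dur at the ends of x.
apply_hann_ramps <- function(x, sample_rate, ramp_dur) {
  n <- length(x)
  nr <- round(ramp_dur * sample_rate)
  if (nr <= 0) return(x)
  if (2 * nr > n) stop("ramps longer than the signal")
  ramp <- sin(pi * (seq_len(nr) - 0.5) / (2 * nr))^2
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(ramp)
  x
}

# Pure tone at a given level (dB FS RMS, exact after ramping); phase in
# radians.
pure_tone <- function(frequency, duration, sample_rate, level_db = -30,
                      ramp_dur = 0, phase = 0) {
  t <- seq_len(round(duration * sample_rate)) / sample_rate
  x <- sin(2 * pi * frequency * t + phase)
  x <- apply_hann_ramps(x, sample_rate, ramp_dur)
  x / sqrt(mean(x^2)) * db_to_amp(level_db)
}

# Gaussian noise band-limited to [low, high] Hz by spectral masking.
# Scaled to level_db (dB FS RMS). Deterministic under the caller's RNG state.
band_noise <- function(low, high, duration, sample_rate, level_db = -30) {
  if (!(0 < low && low < high && high < sample_rate / 2)) {
    stop("noise band edges must satisfy 0 < low < high < Nyquist")
  }
  n <- round(duration * sample_rate)
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  freq <- (seq_len(n) - 1) * sample_rate / n
  freq <- pmin(freq, sample_rate - freq) # fold to [0, Nyquist]
  spec[freq < low | freq > high] <- 0
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  y / sqrt(mean(y^2)) * db_to_amp(level_db)
}

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  spec <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(spec * h, inverse = TRUE) / n
}

# Amplitude envelope, optionally smoothed with a moving average of
# smooth_dur seconds (for comparing 10-Hz modulators across carriers).
envelope <- function(x, sample_rate, smooth_dur = 0) {
  env <- Mod(analytic_signal(x))
  if (smooth_dur > 0) {
    k <- max(1, round(smooth_dur * sample_rate))
    env <- stats::filter(env, rep(1 / k, k), sides = 2)
    env <- env[!is.na(env)]
  }
  as.numeric(env)
}

# Instantaneous frequency (Hz) from the unwrapped analytic phase.
instantaneous_frequency <- function(x, sample_rate) {
  ph <- Arg(analytic_signal(x))
  d <- diff(ph)
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  d * sample_rate / (2 * pi)
}

# Power-spectrum fraction inside [low, high] Hz.
band_power_fraction <- function(x, sample_rate, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * sample_rate / n
  freq <- pmin(freq, sample_rate - freq)
  sum(p[freq >= low & freq <= high]) / sum(p)
}

# Amplitude-weighted spectral centroid in Hz.
spectral_centroid <- function(x, sample_rate) {
  n <- length(x)
  half <- seq_len(floor(n / 2))
  p <- Mod(stats::fft(x))[half]^2
  freq <- (half - 1) * sample_rate / n
  sum(freq * p) / sum(p)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
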