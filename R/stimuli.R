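#' Equivalent rectangular bandwidth of the auditory filter
#'
#' Glasberg–Moore ERB of the normal auditory filter at a given centre
#' frequency: `24.7 * (4.37 * F_kHz + 1)` Hz.
#'
#' @param center_frequency Centre frequency in Hz (vectorised, must be >= 0).
#' @return Bandwidth in Hz.
#' @examples
#' erb_bandwidth(1000) # ~132.6 Hz
#' @export
erb_bandwidth <- function(center_frequency) {
  if (any(center_frequency < 0)) stop("center_frequency must be >= 0")
  24.7 * (4.37 * center_frequency / 1000 + 1)
}

#' Default synthesis parameters
#'
#' Shared synthesis settings: sample rate, presentation level, and inter
#' stimulus interval. Individual synthesis functions override what they need.
#'
#' @param sample_rate Hz; 48 kHz is the browser-standard rate.
#' @param level_db Nominal per-channel presentation level, dB re full-scale
#'   RMS. Kept well below 0 so antiphase sums and multi-band maskers never
#'   clip.
#' @param isi Inter-stimulus silence within a trial, seconds.
#' @return A named list of parameters.
#' @export
synth_params <- function(sample_rate = 48000, level_db = -30, isi = 0.25) {
  list(sample_rate = sample_rate, level_db = level_db, isi = isi)
}

silence <- function(duration, sample_rate, n_channels = 2) {
  matrix(0, nrow = round(duration * sample_rate), ncol = n_channels)
}

#' Antiphase-triad headphone check trial
#'
#' Three sequential low-frequency tones. The target is 6 dB softer than the
#' two foils; one foil is presented in opposite polarity to the two channels
#' ("antiphase"). Over free-field speakers the antiphase foil partially
#' cancels acoustically and can sound softer than the target, so listeners
#' without stereo headphones tend to pick the wrong tone. Over a single
#' channel the antiphase manipulation is inaudible (each channel alone is a
#' plain tone), which is the blind spot the companion chirp task covers.
#'
#' @param target_position Position (1-3) of the softer target tone.
#' @param antiphase_position Position of the antiphase foil; defaults to a
#'   random choice among the two foil positions (uses the current RNG).
#' @param frequency Tone frequency, Hz.
#' @param duration Tone duration, seconds.
#' @param ramp Hann taper duration, seconds.
#' @param params See [synth_params()].
#' @return A list with `waveforms` (list of three stereo [waveform()]s, in
#'   presentation order), `answer` (the target position) and
#'   `antiphase_position`.
#' @export
synth_antiphase_triad <- function(target_position,
                                  antiphase_position = NULL,
                                  frequency = 200, duration = 1,
                                  ramp = 0.02, params = synth_params()) {
  if (!target_position %in% 1:3) stop("target_position must be 1, 2, or 3")
  foils <- setdiff(1:3, target_position)
  if (is.null(antiphase_position)) {
    antiphase_position <- foils[sample.int(2, 1)]
  }
  if (!antiphase_position %in% foils) {
    stop("antiphase_position must be a foil position")
  }
  waves <- lapply(1:3, function(pos) {
    lev <- params$level_db - if (pos == target_position) 6 else 0
    x <- pure_tone(frequency, duration, params$sample_rate, lev, ramp)
    right <- if (pos == antiphase_position) -x else x
    waveform(cbind(x, right), params$sample_rate)
  })
  list(waveforms = waves, answer = target_position,
       antiphase_position = antiphase_position)
}

#' Dichotic chirp-in-noise headphone check trial (N0S-pi)
#'
#' A low-frequency chirp (150–400 Hz) embedded in low-frequency noise. The
#' noise is identical in both channels (N0) while the chirp is polarity
#' inverted between them (S-pi). The per-channel SNR is set low enough that
#' the chirp is near-undetectable monaurally, but the binaural masking level
#' difference makes the pitch direction easy to report over stereo
#' headphones. Listeners report rising, falling, or flat pitch (3AFC).
#'
#' @param direction `"rising"`, `"falling"`, or `"flat"`.
#' @param snr_db Per-channel chirp-to-noise RMS ratio in dB (default -16).
#' @param duration Trial duration, seconds.
#' @param f_lo,f_hi Chirp sweep endpoints, Hz. The flat variant sits at their
#'   geometric mean.
#' @param noise_band Masker band edges, Hz.
#' @param ramp Hann taper, seconds.
#' @param params See [synth_params()].
#' @return A list with `waveform` (stereo), `answer` (the direction), and
#'   `chirp` (the clean chirp samples, for verification).
#' @export
synth_bmld_chirp_trial <- function(direction = c("rising", "falling", "flat"),
                                   snr_db = -16, duration = 1,
                                   f_lo = 150, f_hi = 400,
                                   noise_band = c(100, 500),
                                   ramp = 0.02, params = synth_params()) {
  direction <- match.arg(direction)
  sr <- params$sample_rate
  t <- seq_len(round(duration * sr)) / sr
  sweep <- switch(direction,
    rising  = c(f_lo, f_hi),
    falling = c(f_hi, f_lo),
    flat    = rep(sqrt(f_lo * f_hi), 2)
  )
  # linear sweep: phase(t) = 2*pi*(f0 t + (f1 - f0) t^2 / (2 T))
  phase <- 2 * pi * (sweep[1] * t + (sweep[2] - sweep[1]) * t^2 / (2 * duration))
  chirp_level <- params$level_db + snr_db
  chirp <- db_to_amp(chirp_level) * sqrt(2) * sin(phase)
  chirp <- apply_hann_ramps(chirp, sr, ramp)
  noise <- band_noise(noise_band[1], noise_band[2], duration, sr,
                      params$level_db)
  noise <- apply_hann_ramps(noise, sr, ramp)
  left <- noise + chirp
  right <- noise - chirp
  list(waveform = waveform(cbind(left, right), sr),
       answer = direction, chirp = chirp, noise = noise)
}

#' Modulation-rate envelope of a noise band
#'
#' Extracts the amplitude envelope (Hilbert magnitude) and band-limits it to
#' the DC and modulation-rate components by least-squares projection onto
#' `{1, cos(2 pi rate t), sin(2 pi rate t)}`. This isolates the imposed
#' modulator from the carrier's intrinsic envelope fluctuations, so
#' correlating the result across noise bands measures modulator coherence
#' (+1 for co-modulated, -1 for anticorrelated bands).
#'
#' @param x Sample vector.
#' @param sample_rate Hz.
#' @param rate Modulation rate to extract, Hz.
#' @return The fitted modulator time series, same length as `x`.
#' @export
modulation_envelope <- function(x, sample_rate, rate = 10) {
  env <- Mod(analytic_signal(x))
  t <- seq_along(env) / sample_rate
  basis <- cbind(1, cos(2 * pi * rate * t), sin(2 * pi * rate * t))
  as.numeric(basis %*% qr.coef(qr(basis), env))
}

#' One interval of the F0-discrimination task
#'
#' A sequence of four 200-ms harmonic complex tones (F0 = 110 Hz,
#' equal-amplitude harmonics 1–10 in sine phase, 20-ms Hann tapers). In a
#' target interval, tones 1 and 3 carry a symmetric F0 shift centred on the
#' base F0 (tone 1 up, tone 3 down, each by `delta_f0 / 2`); in a foil
#' interval all four tones sit at the base F0.
#'
#' @param delta_f0 Total F0 excursion in Hz (>= 0), split +/- `delta_f0 / 2`.
#' @param is_target If `TRUE`, apply the shift to tones 1 and 3.
#' @param f0 Base fundamental, Hz.
#' @param tone_dur Duration of each complex, seconds.
#' @param gap Silent gap between successive tones, seconds.
#' @param ramp Hann taper, seconds.
#' @param n_harmonics Number of equal-amplitude harmonics.
#' @param params See [synth_params()].
#' @return A mono [waveform()] of the four-tone sequence.
#' @export
synth_f0dl_interval <- function(delta_f0, is_target, f0 = 110,
                                tone_dur = 0.2, gap = 0.05, ramp = 0.02,
                                n_harmonics = 10, params = synth_params()) {
  if (delta_f0 < 0) stop("delta_f0 must be >= 0")
  if (f0 - delta_f0 / 2 <= 0) stop("delta_f0 would make F0 non-positive")
  sr <- params$sample_rate
  f0s <- rep(f0, 4)
  if (is_target) f0s[c(1, 3)] <- f0 + c(1, -1) * delta_f0 / 2
  tones <- lapply(f0s, function(f) {
    t <- seq_len(round(tone_dur * sr)) / sr
    x <- rowSums(sapply(seq_len(n_harmonics), function(h) sin(2 * pi * h * f * t)))
    x <- x / sqrt(mean(x^2)) * db_to_amp(params$level_db)
    apply_hann_ramps(x, sr, ramp)
  })
  pad <- numeric(round(gap * sr))
  seq_x <- tones[[1]]
  for (i in 2:4) seq_x <- c(seq_x, pad, tones[[i]])
  waveform(seq_x, sr)
}

#' One interval of the gap-detection task
#'
#' Two 125-ms 4-kHz tone markers (1-ms Hann tapers) separated by `gap_ms` of
#' tone silence, embedded in a band of noise spanning half an octave either
#' side of 4 kHz at 10 dB below the tone. The noise starts 50 ms before the
#' first marker (10-ms onset taper), runs uninterrupted through the gap, and
#' extends 50 ms past the second marker. A 0-ms gap is the two ramped markers
#' abutted, which is the foil stimulus.
#'
#' @param gap_ms Gap duration in milliseconds (>= 0).
#' @param tone_freq Marker frequency, Hz.
#' @param marker_dur Marker duration, seconds.
#' @param marker_ramp Marker Hann taper, seconds.
#' @param noise_snr_db Tone-to-noise RMS ratio, dB (tone above noise).
#' @param noise_lead Noise lead/lag relative to the markers, seconds.
#' @param noise_ramp Noise onset/offset taper, seconds.
#' @param params See [synth_params()].
#' @return A list with `waveform` (mono mixture), `tone` and `noise` sample
#'   vectors (for verification).
#' @export
synth_gap_trial <- function(gap_ms, tone_freq = 4000, marker_dur = 0.125,
                            marker_ramp = 0.001, noise_snr_db = 10,
                            noise_lead = 0.05, noise_ramp = 0.01,
                            params = synth_params()) {
  if (gap_ms < 0) stop("gap_ms must be >= 0")
  sr <- params$sample_rate
  marker <- pure_tone(tone_freq, marker_dur, sr, params$level_db, marker_ramp)
  tone <- c(
    numeric(round(noise_lead * sr)),
    marker,
    numeric(round(gap_ms / 1000 * sr)),
    marker,
    numeric(round(noise_lead * sr))
  )
  dur_total <- length(tone) / sr
  band <- tone_freq * 2^c(-0.5, 0.5)
  noise <- band_noise(band[1], band[2], dur_total, sr,
                      params$level_db - noise_snr_db)
  noise <- apply_hann_ramps(noise, sr, noise_ramp)
  mix <- tone + noise
  list(waveform = waveform(mix, sr), tone = tone, noise = noise)
}

#' Two-interval interaural time difference (ITD) pair
#'
#' Two tone bursts whose leading ear switches between intervals, so the sound
#' image jumps left-to-right or right-to-left. For pure tones the ITD is
#' realized exactly as an interaural carrier phase of `2 * pi * f * ITD`
#' (envelope shared), with a whole-waveform sample delay available as an
#' alternative.
#'
#' @param itd_us ITD magnitude in microseconds (>= 0).
#' @param order `"LR"` (first interval left-leading) or `"RL"`.
#' @param frequency Carrier, Hz (500 Hz by convention for ITD).
#' @param duration Burst duration, seconds.
#' @param ramp Hann taper, seconds.
#' @param method `"phase"` (carrier phase shift, exact for tones) or
#'   `"delay"` (whole-waveform delay rounded to samples).
#' @param params See [synth_params()].
#' @return A list with `intervals` (two stereo [waveform()]s) and `answer`
#'   (the order).
#' @export
synth_itd_pair <- function(itd_us, order = c("LR", "RL"), frequency = 500,
                           duration = 0.3, ramp = 0.02,
                           method = c("phase", "delay"),
                           params = synth_params()) {
  order <- match.arg(order)
  method <- match.arg(method)
  if (itd_us < 0) stop("itd_us must be >= 0")
  itd <- itd_us * 1e-6
  dphi <- 2 * pi * frequency * itd
  if (method == "phase" && dphi > pi) {
    stop(sprintf("ITD %g us implies interaural phase %.2f > pi at %g Hz",
                 itd_us, dphi, frequency))
  }
  sr <- params$sample_rate
  one_interval <- function(lead_left) {
    s <- if (lead_left) 1 else -1
    if (method == "phase") {
      # leading ear has phase advance +dphi/2; shared envelope
      l <- pure_tone(frequency, duration, sr, params$level_db, ramp,
                     phase = s * dphi / 2)
      r <- pure_tone(frequency, duration, sr, params$level_db, ramp,
                     phase = -s * dphi / 2)
    } else {
      nd <- round(itd * sr)
      base <- pure_tone(frequency, duration, sr, params$level_db, ramp)
      lag <- c(numeric(nd), base)
      lead <- c(base, numeric(nd))
      if (s > 0) { l <- lead; r <- lag } else { l <- lag; r <- lead }
    }
    waveform(cbind(l, r), sr)
  }
  first_left <- order == "LR"
  list(intervals = list(one_interval(first_left), one_interval(!first_left)),
       answer = order)
}

#' Two-interval interaural level difference (ILD) pair
#'
#' Two 4-kHz tone bursts; the more intense ear switches between intervals.
#' The difference is split symmetrically (+/- `ild_db / 2`) so the mean of
#' the two channel levels equals the nominal level.
#'
#' @param ild_db ILD magnitude in dB (>= 0).
#' @param order `"LR"` (first interval louder on the left) or `"RL"`.
#' @param frequency Carrier, Hz.
#' @param duration Burst duration, seconds.
#' @param ramp Hann taper, seconds.
#' @param params See [synth_params()].
#' @return A list with `intervals` (two stereo [waveform()]s) and `answer`.
#' @export
synth_ild_pair <- function(ild_db, order = c("LR", "RL"), frequency = 4000,
                           duration = 0.3, ramp = 0.02,
                           params = synth_params()) {
  order <- match.arg(order)
  if (ild_db < 0) stop("ild_db must be >= 0")
  sr <- params$sample_rate
  one_interval <- function(loud_left) {
    s <- if (loud_left) 1 else -1
    l <- pure_tone(frequency, duration, sr, params$level_db + s * ild_db / 2,
                   ramp)
    r <- pure_tone(frequency, duration, sr, params$level_db - s * ild_db / 2,
                   ramp)
    waveform(cbind(l, r), sr)
  }
  first_left <- order == "LR"
  list(intervals = list(one_interval(first_left), one_interval(!first_left)),
       answer = order)
}

#' Co-modulation masking release (CMR) trial
#'
#' Tone-in-noise detection stimulus: a 1-ERB-wide on-band noise centred at
#' 4 kHz with 10-Hz raised-sine amplitude modulation (100% depth), plus, in
#' the flanked conditions, two 1-ERB-wide flanking bands whose near edges sit
#' 2 ERB from the on-band edges. `CORR` flankers share the on-band modulator,
#' `ACORR` flankers use the inverted (pi-shifted) modulator, and `REF` has no
#' flankers. When `tone_present`, a 4-kHz tone is added at `snr_db` relative
#' to the on-band noise RMS.
#'
#' @param condition `"REF"`, `"CORR"`, or `"ACORR"`.
#' @param snr_db Tone-to-on-band-noise RMS ratio, dB.
#' @param tone_present Whether the target tone is present.
#' @param center Frequency of the on-band centre and tone, Hz.
#' @param mod_rate Modulation rate, Hz.
#' @param duration Stimulus duration, seconds.
#' @param ramp Hann taper, seconds.
#' @param params See [synth_params()].
#' @return A list with `waveform` (mono mixture) and the component sample
#'   vectors `on_band`, `flanker_lo`, `flanker_hi` (zero vectors for REF),
#'   and `tone`.
#' @export
synth_cmr_trial <- function(condition = c("REF", "CORR", "ACORR"),
                            snr_db = -10, tone_present = TRUE,
                            center = 4000, mod_rate = 10, duration = 0.5,
                            ramp = 0.02, params = synth_params()) {
  condition <- match.arg(condition)
  sr <- params$sample_rate
  e <- erb_bandwidth(center)
  on_edges <- center + c(-0.5, 0.5) * e
  lo_edges <- c(on_edges[1] - 3 * e, on_edges[1] - 2 * e)
  hi_edges <- c(on_edges[2] + 2 * e, on_edges[2] + 3 * e)
  if (hi_edges[2] >= sr / 2) stop("flanker band exceeds Nyquist frequency")
  n <- round(duration * sr)
  t <- seq_len(n) / sr
  modulator <- (1 - cos(2 * pi * mod_rate * t)) / 2       # raised sine, 100%
  inv_modulator <- (1 + cos(2 * pi * mod_rate * t)) / 2   # pi-shifted
  make_band <- function(edges, mod) {
    x <- band_noise(edges[1], edges[2], duration, sr, 0) * mod
    x / sqrt(mean(x^2)) * db_to_amp(params$level_db)
  }
  on_band <- make_band(on_edges, modulator)
  flank_mod <- if (condition == "CORR") modulator else inv_modulator
  flanker_lo <- if (condition == "REF") numeric(n) else
    make_band(lo_edges, flank_mod)
  flanker_hi <- if (condition == "REF") numeric(n) else
    make_band(hi_edges, flank_mod)
  tone <- if (tone_present) {
    pure_tone(center, duration, sr, params$level_db + snr_db, ramp)
  } else numeric(n)
  mix <- apply_hann_ramps(on_band + flanker_lo + flanker_hi, sr, ramp) + tone
  list(waveform = waveform(mix, sr), on_band = on_band,
       flanker_lo = flanker_lo, flanker_hi = flanker_hi, tone = tone)
}

#' Calibration sound for a task
#'
#' Concatenates representative stimuli from the task (as deployed, long
#' strings of task stimuli) so the calibration sound shares the task's
#' spectrotemporal character; its measured RMS defines the
#' [calibration_reference()] against which all task stimuli must sit within
#' 6 dB.
#'
#' @param task_id One of `"hp_triad"`, `"hp_bmld"`, `"f0dl"`, `"gap"`,
#'   `"itd"`, `"ild"`, `"cmr"`.
#' @param min_duration Minimum calibration duration, seconds.
#' @param seed RNG seed for the noise-based tasks.
#' @param params See [synth_params()].
#' @return A list with `waveform`, `reference` (a [calibration_reference()]),
#'   and `task_id`.
#' @export
make_calibration_sound <- function(task_id, min_duration = 3, seed = 1,
                                   params = synth_params()) {
  known <- c("hp_triad", "hp_bmld", "f0dl", "gap", "itd", "ild", "cmr")
  if (!task_id %in% known) {
    stop("unknown task '", task_id, "'; registered tasks: ",
         paste(known, collapse = ", "))
  }
  piece <- function() {
    switch(task_id,
      hp_triad = {
        tr <- synth_antiphase_triad(2, antiphase_position = 1, params = params)
        do.call(rbind, lapply(tr$waveforms, function(w) w$samples))
      },
      hp_bmld = synth_bmld_chirp_trial("rising", params = params)$waveform$samples,
      f0dl = synth_f0dl_interval(0, FALSE, params = params)$samples,
      gap = synth_gap_trial(0, params = params)$waveform$samples,
      itd = {
        p <- synth_itd_pair(0, "LR", params = params)
        rbind(p$intervals[[1]]$samples, p$intervals[[2]]$samples)
      },
      ild = {
        p <- synth_ild_pair(0, "LR", params = params)
        rbind(p$intervals[[1]]$samples, p$intervals[[2]]$samples)
      },
      cmr = synth_cmr_trial("REF", tone_present = FALSE,
                            params = params)$waveform$samples
    )
  }
  with_seed(seed, {
    chunks <- list()
    total <- 0
    while (total < min_duration * params$sample_rate) {
      s <- piece()
      chunks[[length(chunks) + 1]] <- s
      total <- total + nrow(s)
    }
    samples <- do.call(rbind, chunks)
    wave <- waveform(samples, params$sample_rate)
    list(waveform = wave,
         reference = calibration_reference(max(rms_db(wave))),
         task_id = task_id)
  })
}
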