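SR <- 48000

test_that("ERB bandwidth follows the Glasberg-Moore formula", {
  expect_equal(erb_bandwidth(0), 24.7)
  expect_equal(erb_bandwidth(1000), 24.7 * (4.37 + 1), tolerance = 1e-12)
  expect_equal(erb_bandwidth(4000), 24.7 * (4.37 * 4 + 1), tolerance = 1e-12)
  expect_error(erb_bandwidth(-1), "must be >= 0")
})

test_that("waveform invariants hold: bounds, channel lengths, level metadata", {
  set.seed(1)
  stimuli <- list(
    synth_antiphase_triad(1, antiphase_position = 2)$waveforms[[1]],
    synth_bmld_chirp_trial("rising")$waveform,
    synth_f0dl_interval(0.4, TRUE),
    synth_gap_trial(8)$waveform,
    synth_itd_pair(64, "LR")$intervals[[1]],
    synth_ild_pair(2, "RL")$intervals[[2]],
    synth_cmr_trial("CORR", -8, TRUE)$waveform
  )
  for (w in stimuli) {
    expect_true(all(abs(w$samples) <= 1))
    expect_equal(ncol(w$samples), w$n_channels)
    expect_equal(w$rms_db, apply(w$samples, 2, function(x) db_of(x)),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
  expect_error(waveform(c(0, 1.5), 48000), "full scale")
})

test_that("antiphase triad: cancellation, -6 dB target, mono blind spot", {
  for (pos in 1:3) {
    anti <- setdiff(1:3, pos)[1]
    tr <- synth_antiphase_triad(pos, antiphase_position = anti)
    expect_equal(tr$answer, pos)
    s_anti <- tr$waveforms[[anti]]$samples
    # antiphase foil: L + R cancels exactly (>= 60 dB below one channel)
    expect_lt(db_of(s_anti[, 1] + s_anti[, 2]) - db_of(s_anti[, 1]), -60)
    # target is 6 dB below each foil, per channel
    inphase_foil <- setdiff(1:3, c(pos, anti))
    for (ch in 1:2) {
      expect_equal(tr$waveforms[[pos]]$rms_db[ch] -
                     tr$waveforms[[inphase_foil]]$rms_db[ch],
                   -6, tolerance = 0.01)
      expect_equal(tr$waveforms[[pos]]$rms_db[ch] -
                     tr$waveforms[[anti]]$rms_db[ch],
                   -6, tolerance = 0.01)
    }
    # over a single channel the target is still softest: the mono blind spot
    # that motivates the companion chirp check
    for (ch in 1:2) {
      levels <- vapply(tr$waveforms, function(w) w$rms_db[ch], numeric(1))
      expect_equal(which.min(levels), pos)
    }
  }
  expect_error(synth_antiphase_triad(4), "1, 2, or 3")
  expect_error(synth_antiphase_triad(1, antiphase_position = 1), "foil")
})

test_that("BMLD chirp trial realizes the N0S-pi configuration", {
  set.seed(7)
  for (dir in c("rising", "falling", "flat")) {
    tr <- synth_bmld_chirp_trial(dir)
    s <- tr$waveform$samples
    diff_ch <- (s[, 1] - s[, 2]) / 2
    sum_ch <- (s[, 1] + s[, 2]) / 2
    # difference channel isolates the chirp
    expect_gt(cor(diff_ch, tr$chirp), 0.999)
    # sum channel is the noise alone; chirp residual >= 60 dB down
    resid <- sum_ch - tr$noise
    expect_lt(db_of(resid + 1e-30) - db_of(tr$chirp), -60)
  }
  # flat variant: constant instantaneous frequency at the geometric mean
  tr <- synth_bmld_chirp_trial("flat")
  ifq <- audscreen:::instantaneous_frequency((tr$waveform$samples[, 1] -
                                                tr$waveform$samples[, 2]) / 2,
                                             SR)
  core <- ifq[round(length(ifq) * 0.1):round(length(ifq) * 0.9)]
  expect_lt(max(abs(core - sqrt(150 * 400))) / sqrt(150 * 400), 0.01)
  # rising sweep moves upward through the band
  tr2 <- synth_bmld_chirp_trial("rising")
  ifq2 <- audscreen:::instantaneous_frequency((tr2$waveform$samples[, 1] -
                                                 tr2$waveform$samples[, 2]) / 2,
                                              SR)
  n <- length(ifq2)
  expect_lt(mean(ifq2[2000:6000]), mean(ifq2[(n - 6000):(n - 2000)]))
  # per-channel SNR honours the requested value
  tr3 <- synth_bmld_chirp_trial("flat", snr_db = -16)
  expect_equal(db_of(tr3$chirp) - db_of(tr3$noise), -16, tolerance = 0.1)
  expect_error(synth_bmld_chirp_trial("sideways"), "arg")
})

test_that("F0 intervals carry the +/- delta/2 shift on tones 1 and 3", {
  tone_n <- round(0.2 * SR)
  gap_n <- round(0.05 * SR)
  starts <- (0:3) * (tone_n + gap_n)
  segment_f0 <- function(wave, i) {
    est_f0(wave$samples[starts[i] + seq_len(tone_n), 1], SR)
  }
  foil <- synth_f0dl_interval(3.2, is_target = FALSE)
  for (i in 1:4) expect_equal(segment_f0(foil, i), 110, tolerance = 0.05)
  target <- synth_f0dl_interval(3.2, is_target = TRUE)
  expect_equal(segment_f0(target, 1), 111.6, tolerance = 0.05)
  expect_equal(segment_f0(target, 2), 110, tolerance = 0.05)
  expect_equal(segment_f0(target, 3), 108.4, tolerance = 0.05)
  expect_equal(segment_f0(target, 4), 110, tolerance = 0.05)
  # zero shift makes target and foil numerically identical
  expect_identical(synth_f0dl_interval(0, TRUE)$samples, foil$samples)
  expect_error(synth_f0dl_interval(-1, TRUE), ">= 0")
  expect_error(synth_f0dl_interval(250, TRUE), "non-positive")
})

test_that("gap trials: additive duration, band-limited noise, +10 dB SNR", {
  set.seed(11)
  for (gap_ms in c(0, 4, 16)) {
    tr <- synth_gap_trial(gap_ms)
    expected_dur <- 0.05 + 0.125 + gap_ms / 1000 + 0.125 + 0.05
    expect_equal(wave_duration(tr$waveform), expected_dur, tolerance = 1e-4)
    # >= 99% of noise power within the one-octave band around 4 kHz
    expect_gt(audscreen:::band_power_fraction(tr$noise, SR,
                                              4000 * 2^-0.5, 4000 * 2^0.5),
              0.99)
    # tone markers sit 10 dB above the noise
    marker <- tr$tone[tr$tone != 0]
    expect_equal(db_of(marker) - db_of(tr$noise), 10, tolerance = 0.2)
  }
  expect_error(synth_gap_trial(-1), ">= 0")
})

test_that("ITD pairs: zero-delay identity, carrier phase, lag sign flip", {
  z <- synth_itd_pair(0, "LR")
  expect_identical(z$intervals[[1]]$samples[, 1], z$intervals[[1]]$samples[, 2])
  expect_identical(z$intervals[[2]]$samples[, 1], z$intervals[[2]]$samples[, 2])
  # 128 us at 500 Hz -> interaural carrier phase 2*pi*500*128e-6 = 0.402 rad
  tr <- synth_itd_pair(128, "LR")
  s <- tr$intervals[[1]]$samples
  xspec <- sum(audscreen:::analytic_signal(s[, 1]) *
                 Conj(audscreen:::analytic_signal(s[, 2])))
  expect_equal(Arg(xspec), 2 * pi * 500 * 128e-6, tolerance = 1e-3)
  # cross-correlation peaks at the lag nearest +/- 128 us, flipping sign
  lag_of <- function(s) {
    cc <- stats::ccf(s[, 1], s[, 2], lag.max = 12, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expected_lag <- round(128e-6 * SR)
  l1 <- lag_of(tr$intervals[[1]]$samples)
  l2 <- lag_of(tr$intervals[[2]]$samples)
  expect_equal(abs(l1), expected_lag)
  expect_equal(l2, -l1)
  expect_error(synth_itd_pair(1100, "LR"), "pi")
  # whole-waveform delay alternative agrees on the lag
  trd <- synth_itd_pair(128, "LR", method = "delay")
  expect_equal(abs(lag_of(trd$intervals[[1]]$samples)), expected_lag)
})

test_that("ILD pairs split the level difference symmetrically", {
  z <- synth_ild_pair(0, "LR")
  expect_equal(z$intervals[[1]]$rms_db[1], z$intervals[[1]]$rms_db[2],
               tolerance = 1e-9)
  tr <- synth_ild_pair(0.8, "LR")
  for (i in 1:2) {
    lv <- tr$intervals[[i]]$rms_db
    ratio <- 10^((max(lv) - min(lv)) / 20)
    expect_equal(ratio, 10^(0.8 / 20), tolerance = 1e-4)
    expect_equal(mean(lv), -30, tolerance = 0.01) # nominal level preserved
  }
  # the louder ear swaps between intervals
  expect_gt(tr$intervals[[1]]$rms_db[1], tr$intervals[[1]]$rms_db[2])
  expect_lt(tr$intervals[[2]]$rms_db[1], tr$intervals[[2]]$rms_db[2])
  expect_error(synth_ild_pair(-0.5, "LR"), ">= 0")
})

test_that("CMR conditions realize the flanker-modulator geometry", {
  set.seed(23)
  cm <- synth_cmr_trial("CORR", tone_present = FALSE)
  ac <- synth_cmr_trial("ACORR", tone_present = FALSE)
  env_cor <- function(a, b) {
    cor(modulation_envelope(a, SR, 10), modulation_envelope(b, SR, 10))
  }
  expect_gt(env_cor(cm$on_band, cm$flanker_lo), 0.95)
  expect_gt(env_cor(cm$on_band, cm$flanker_hi), 0.95)
  expect_lt(env_cor(ac$on_band, ac$flanker_lo), -0.9)
  expect_lt(env_cor(ac$on_band, ac$flanker_hi), -0.9)
  # REF: spectral power outside the on-band +/- 1 ERB region >= 40 dB down
  ref <- synth_cmr_trial("REF", tone_present = FALSE)
  e <- erb_bandwidth(4000)
  inside <- audscreen:::band_power_fraction(ref$waveform$samples[, 1], SR,
                                            4000 - 1.5 * e, 4000 + 1.5 * e)
  expect_gt(10 * log10(inside / (1 - inside)), 40)
  # tone present at the requested SNR re the on-band noise
  tp <- synth_cmr_trial("REF", snr_db = -5, tone_present = TRUE)
  expect_equal(db_of(tp$tone) - db_of(tp$on_band), -5, tolerance = 0.1)
})

test_that("calibration sounds bound task stimuli within 6 dB headroom", {
  cal <- make_calibration_sound("f0dl", seed = 5)
  expect_gte(wave_duration(cal$waveform), 3)
  set.seed(5)
  stims <- lapply(c(0.05, 0.4, 3.2), synth_f0dl_interval, is_target = TRUE)
  for (s in stims) expect_true(check_headroom(s, cal$reference))
  # spectral centroid of the calibration within 1/3 octave of the stimuli
  cal_cent <- audscreen:::spectral_centroid(cal$waveform$samples[, 1], SR)
  stim_cent <- mean(vapply(stims, function(s) {
    audscreen:::spectral_centroid(s$samples[, 1], SR)
  }, numeric(1)))
  expect_lt(abs(log2(cal_cent / stim_cent)), 1 / 3)
  expect_error(make_calibration_sound("nonsense"), "unknown task")
})

test_that("synthesis is reproducible: same seed, bit-identical samples", {
  a <- make_calibration_sound("cmr", seed = 42)$waveform$samples
  b <- make_calibration_sound("cmr", seed = 42)$waveform$samples
  expect_identical(a, b)
  c2 <- make_calibration_sound("cmr", seed = 43)$waveform$samples
  expect_false(identical(a, c2))
})
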