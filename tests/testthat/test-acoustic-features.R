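test_that("pitch tracking is accurate on tones, glides, and noise", {
  fs <- 22050
  tone <- waveform(0.9 * sin(2 * pi * 220 * (0:(fs - 1)) / fs), fs)
  p <- track_pitch(tone, 75, 500)
  expect_gt(mean(p$voiced), 0.95)
  expect_true(all(abs(p$f0_hz[p$voiced] - 220) < 1))

  noise <- waveform(voicemarkers:::with_seed(3L, rnorm(fs)) / 4, fs)
  pn <- track_pitch(noise, 75, 500)
  expect_gte(mean(!pn$voiced), 0.9)

  sp <- voice_spec(1.2, 150, 250, jitter_frac = 0, noise_db = -50)
  w <- synthesize_voice(sp, 2)
  pg <- track_pitch(w)
  truth <- voice_contour(sp, pg$frame_times[pg$voiced])
  expect_lt(max(abs(pg$f0_hz[pg$voiced] - truth) / truth), 0.03)
})

test_that("f0 statistics match their definitions on a hand example", {
  p <- structure(
    list(frame_times = c(0.1, 0.2, 0.3),
         f0_hz = c(180, 160, 220),
         voiced = rep(TRUE, 3),
         r_peak = rep(0.9, 3)),
    call_length = 0.4, frame_step = 0.1, class = "pitch_track"
  )
  s <- f0_statistics(p)
  expect_equal(s$f0_min, 160)
  expect_equal(s$f0_max, 220)
  expect_equal(s$f0_mnpozr, 0.5)
  expect_equal(s$f0_mxpozr, 0.75)
  expect_equal(s$f0_change, 40)
  expect_equal(s$f0_range, 60)
  expect_equal(s$f0_st, 180)
  expect_equal(s$f0_end, 220)
  p$voiced <- c(TRUE, FALSE, FALSE)
  expect_warning(s2 <- f0_statistics(p), "voiced")
  expect_true(all(is.na(unlist(s2))))
})

test_that("pulse extraction recovers the glottal cycles", {
  sp <- voice_spec(1, 100, 100, jitter_frac = 0, noise_db = -50)
  w <- synthesize_voice(sp, 3)
  p <- track_pitch(w)
  s <- extract_pulses(w, p)
  expect_true(abs(length(s$pulse_times) - 100) <= 3)
  per <- diff(s$pulse_times)
  expect_lt(sd(per) / mean(per), 0.005)

  spj <- voice_spec(1, 100, 100, jitter_frac = 0.05, noise_db = -50)
  wj <- synthesize_voice(spj, 3)
  sj <- extract_pulses(wj, track_pitch(wj))
  truth <- pulse_jitter(attr(wj, "pulse_times"))
  expect_lt(abs(jitter_features(sj)$ppj - truth) / truth, 0.2)
})

test_that("jitter features follow the local-jitter formula", {
  mk <- function(periods) list(pulse_times = cumsum(c(0, periods)),
                               voiced_duration = sum(periods))
  expect_equal(jitter_features(mk(rep(0.010, 10)))$ppj, 0)
  j <- jitter_features(mk(c(0.010, 0.012, 0.010, 0.012)))
  expect_equal(j$ppj, 2 / 11, tolerance = 1e-12)
  expect_equal(j$ppp, 5)
  expect_true(is.na(jitter_features(mk(0.01))$ppj))
  # 1 s voiced at 100 Hz
  j2 <- jitter_features(mk(rep(0.01, 100)))
  expect_equal(j2$ppp, 101)
  expect_equal(j2$ppm, 101, tolerance = 0.01)
})

test_that("harmonicity matches its closed forms and noise ordering", {
  w <- synthesize_voice(voice_spec(1.2, 181, 181, jitter_frac = 0,
                                   noise_db = -Inf), 1)
  p <- track_pitch(w)
  expect_gte(harmonicity(w, p)$HNR, 30)

  w0 <- synthesize_voice(voice_spec(1.2, 181, 181, jitter_frac = 0,
                                    noise_db = 0), 1)
  p0 <- track_pitch(w0)
  expect_lt(abs(harmonicity(w0, p0)$HNR), 2)  # r = 0.5 -> 0 dB

  hnrs <- vapply(c(-40, -25, -15), function(nz) {
    ww <- synthesize_voice(voice_spec(1, 181, 181, jitter_frac = 0,
                                      noise_db = nz), 4)
    harmonicity(ww, track_pitch(ww))$HNR
  }, numeric(1))
  expect_true(all(diff(hnrs) < 0))
})

test_that("Wiener entropy separates flat, tonal, and mixed spectra", {
  fs <- 22050
  noise <- waveform(voicemarkers:::with_seed(5L, rnorm(2 * fs)) / 4, fs)
  tone <- waveform(0.9 * sin(2 * pi * 1000 * (0:(fs - 1)) / fs), fs)
  mix <- waveform(0.45 * sin(2 * pi * 1000 * (0:(fs - 1)) / fs) +
                    voicemarkers:::with_seed(5L, rnorm(fs)) / 8, fs)
  e_noise <- wiener_entropy(noise)
  e_tone <- wiener_entropy(tone)
  e_mix <- wiener_entropy(mix)
  expect_gt(e_noise, -0.5)
  expect_lte(e_noise, 0)
  expect_lt(e_tone, -5)
  expect_true(e_tone < e_mix && e_mix < e_noise)
})

test_that("spectral shape treats the spectrum as a distribution", {
  fs <- 22050
  t <- (0:(2 * fs - 1)) / fs
  one <- waveform(0.9 * sin(2 * pi * 1000 * t), fs)
  s1 <- spectral_shape(one)
  expect_equal(s1$CG, 1000, tolerance = 5 / 1000)
  expect_lt(s1$DevFreq, 50)

  two <- waveform(0.45 * sin(2 * pi * 1000 * t) +
                    0.45 * sin(2 * pi * 3000 * t), fs)
  s2 <- spectral_shape(two)
  expect_equal(s2$CG, 2000, tolerance = 10 / 2000)
  expect_equal(s2$BEn, 0.5, tolerance = 0.02)
  expect_equal(s2$EnergyDiff, 0, tolerance = 0.2)
  expect_equal(s2$Sk, 0, tolerance = 0.05)
  expect_equal(s2$cmoment, 0, tolerance = 0.05 * s2$DevFreq^3)
  expect_error(spectral_shape(waveform(numeric(100), 8000)), "12 kHz")
})

test_that("formant dispersion recovers synthesis ground truth and scales", {
  sp <- voice_spec(1.2, 180, 180, jitter_frac = 0, noise_db = -40)
  w <- synthesize_voice(sp, 6)
  p <- track_pitch(w)
  dF <- formant_dispersion(w, p, 5500)
  expect_equal(as.numeric(dF), 1000, tolerance = 0.05)

  sp2 <- voice_spec(1.2, 200, 200, jitter_frac = 0,
                    formants_hz = c(600, 1700, 2600, 3600, 4700),
                    noise_db = -40)
  w2 <- synthesize_voice(sp2, 6)
  dF2 <- formant_dispersion(w2, track_pitch(w2), 5500)
  expect_equal(as.numeric(dF2), 1025, tolerance = 0.05)

  sp3 <- voice_spec(1.2, 180, 180, jitter_frac = 0,
                    formants_hz = c(500, 1500, 2500, 3500, 4500) * 1.1,
                    noise_db = -40)
  w3 <- synthesize_voice(sp3, 6)
  dF3 <- formant_dispersion(w3, track_pitch(w3), 5500)
  expect_equal(as.numeric(dF3) / as.numeric(dF), 1.1, tolerance = 0.05)

  silent_track <- track_pitch(waveform(numeric(22050), 22050))
  expect_warning(
    out <- formant_dispersion(waveform(numeric(22050), 22050), silent_track),
    "voiced")
  expect_true(is.na(out))
})

test_that("the composed feature vector is complete, deterministic, and scale invariant", {
  sp <- voice_spec(1.2, 190, 170, jitter_frac = 0.02, noise_db = -30)
  w <- synthesize_voice(sp, 5)
  f1 <- extract_features(w)
  expect_s3_class(f1, "feature_vector")
  expect_named(f1, feature_names())
  expect_true(all(is.finite(unlist(f1))))

  f2 <- extract_features(w)
  expect_identical(unlist(f1), unlist(f2))

  w_amp <- waveform(w$samples * 3.7, w$sample_rate_hz)
  f3 <- extract_features(w_amp)
  expect_equal(unlist(f1), unlist(f3), tolerance = 1e-10)

  # consistency identities hold exactly
  expect_identical(f1$f0_range, f1$f0_max - f1$f0_min)
  expect_identical(f1$f0_change, f1$f0_end - f1$f0_st)
  expect_true(f1$f0_mnpozr >= 0 && f1$f0_mnpozr <= 1)
  expect_true(f1$f0_mxpozr >= 0 && f1$f0_mxpozr <= 1)
  expect_lte(f1$ent, 0)
  expect_gte(f1$ppj, 0)

  expect_warning(fs <- extract_features(waveform(numeric(22050), 22050)),
                 "silent")
  expect_true(all(is.na(unlist(fs))))
})

test_that("batch extraction yields one row per sentence", {
  prof <- speaker_profiles(3, seed = 8)
  prof$duration_mean <- 0.8; prof$duration_sd <- 0.02
  corp <- sample_corpus(prof, 2, seed = 3, sample_rate_hz = 22050)
  tab <- suppressWarnings(extract_features_corpus(corp))
  expect_equal(nrow(tab), 6)
  expect_true(all(feature_names() %in% names(tab)))
  expect_equal(tab$speaker_id, corp$manifest$speaker_id)
})
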