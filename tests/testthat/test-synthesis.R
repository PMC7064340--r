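test_that("harmonics are exact integer multiples of the fundamental", {
  expect_identical(harmonic_frequency(150, 12), 1800)
  expect_identical(harmonic_frequency(123.4, 1), 123.4)
  expect_identical(harmonic_frequency(164, 10), 1640)
})

test_that("a flat unity filter passes all harmonics at equal level", {
  f <- seq(10, 8000, by = 10)
  flat <- frequency_response(f, rep(0, length(f)))
  src <- glottal_source_spec(f0 = 150, n_harmonics = 20, tilt_db_per_octave = 0)
  clip <- synthesize_static(src, flat, duration = 0.6, fs = 44100)
  h <- measured_harmonic_levels(clip, 150, n_max = 20)
  expect_true(all(!h$missing))
  expect_lt(diff(range(h$level_db)), 1)
})

test_that("synthesis is linear: output level = source level + filter gain within 1 dB", {
  f <- seq(10, 8000, by = 10)
  set.seed(42)
  gains <- as.numeric(stats::filter(stats::rnorm(length(f), 0, 12),
                                    rep(1 / 80, 80), circular = TRUE))
  fr <- frequency_response(f, gains)
  src <- glottal_source_spec(f0 = 150, n_harmonics = 20)
  clip <- synthesize_static(src, fr, duration = 0.6, fs = 44100)
  h <- measured_harmonic_levels(clip, 150, n_max = 20)
  src_db <- src$tilt_db_per_octave * log2(h$k)
  g_at <- stats::approx(f, gains, xout = h$k * 150)$y
  pred <- src_db + g_at
  resid <- (h$level_db - pred) - (h$level_db[1] - pred[1])  # common offset
  expect_true(all(abs(resid) < 1))
})

test_that("the converged focus filter makes harmonic 12 dominate the 1-2 kHz band", {
  h <- measured_harmonic_levels(fx_clip_focused(), 150, n_max = 14)
  in_band <- h[h$freq_hz >= 1000 & h$freq_hz <= 2000, ]
  expect_equal(in_band$k[which.max(in_band$level_db)], 12)
  # overtones flanking the focused one are strongly suppressed
  expect_lt(h$level_db[11], h$level_db[12] - 10)
  expect_lt(h$level_db[13], h$level_db[12] - 10)
})

test_that("area-function interpolation hits its endpoints and is idempotent on equals", {
  a <- fx_a0()
  b <- fx_focus_1800()$af
  expect_equal(interpolate_area_functions(a, b, 0)$A, a$A)
  expect_equal(interpolate_area_functions(a, b, 1)$A, b$A)
  expect_equal(interpolate_area_functions(a, a, 0.5)$A, a$A)
  expect_error(interpolate_area_functions(a, resample_area_function(b, 30), 0.5),
               "grid")
})

test_that("a constant normal scenario reproduces the static synthesis spectrum", {
  scenario <- make_song_scenario("normal", f0_hz = 150, seed = 2, duration = 1)
  clip_dyn <- synthesize_dynamic(scenario, fx_a0(), fx_focus_1800()$af,
                                 fx_const())
  src <- glottal_source_spec(f0 = 150)
  clip_sta <- synthesize_static(src, fx_response_neutral(), duration = 1)
  hd <- measured_harmonic_levels(clip_dyn, 150, n_max = 15)
  hs <- measured_harmonic_levels(clip_sta, 150, n_max = 15)
  resid <- (hd$level_db - hs$level_db) - (hd$level_db[1] - hs$level_db[1])
  expect_true(all(abs(resid[hs$level_db > -60]) < 1))
})

test_that("synthesized spectra contain no subharmonic energy", {
  # long Hann window: sidelobe leakage from the strong harmonics stays well
  # below the -60 dB criterion at the half-integer positions
  sp <- compute_spectrogram(fx_clip_focused(), window_samples = 8192,
                            window_type = "hann")
  mid <- sp$mag_db[, ncol(sp$mag_db) %/% 2]
  half <- (1:10 + 0.5) * 150
  for (f in half) {
    sel <- which(abs(sp$freqs - f) < 30)
    expect_lt(max(mid[sel]), -60)
  }
})

test_that("disabling vibrato yields a constant measured f0", {
  scenario <- make_song_scenario("normal", f0_hz = 150, seed = 3, duration = 1)
  clip <- synthesize_dynamic(scenario, fx_a0(), fx_a0(), fx_const())
  sp <- compute_spectrogram(clip)
  f0s <- apply(sp$mag_db[, seq(5, ncol(sp$mag_db) - 5, by = 20)], 2,
               function(m) estimate_f0(sp$freqs, m))
  halfbin <- (sp$freqs[2] - sp$freqs[1]) / 2
  expect_lt(diff(range(f0s)), halfbin)
})

test_that("relative harmonic levels are invariant to peak normalization", {
  f <- seq(10, 8000, by = 10)
  fr <- frequency_response(f, rep(0, length(f)))
  src <- glottal_source_spec(f0 = 150, n_harmonics = 10)
  clip <- synthesize_static(src, fr, duration = 0.5)
  expect_equal(max(abs(clip$samples)), 1, tolerance = 1e-12)
  h <- measured_harmonic_levels(clip, 150, n_max = 10)
  # levels in dB re clip max depend only on ratios, which normalization keeps
  expect_equal(h$level_db - h$level_db[1],
               src$tilt_db_per_octave * log2(1:10), tolerance = 1)
})
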