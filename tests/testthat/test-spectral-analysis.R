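test_that("a pure tone produces a single spectral ridge in every frame", {
  fs <- 44100
  t <- (0:(fs - 1)) / fs
  clip <- audio_clip(sin(2 * pi * 1000 * t), fs)
  sp <- compute_spectrogram(clip)
  ridge <- apply(sp$mag_db, 2, function(m) sp$freqs[which.max(m)])
  expect_true(all(abs(ridge - 1000) < sp$freqs[2] - sp$freqs[1]))
})

test_that("white noise gives a flat frame-averaged spectrum within 3 dB", {
  set.seed(99)
  fs <- 16000
  clip <- audio_clip(peak <- {x <- stats::rnorm(fs * 2); x / max(abs(x))}, fs)
  sp <- compute_spectrogram(clip)
  avg <- 20 * log10(rowMeans(10^(sp$mag_db / 20)))
  sel <- sp$freqs > 200 & sp$freqs < 7000
  expect_lt(stats::sd(avg[sel]) * 2, 3)
  smoothed <- stats::filter(avg[sel], rep(1 / 50, 50))
  expect_lt(diff(range(smoothed, na.rm = TRUE)), 3)
})

test_that("default STFT at 96 kHz matches the published analysis settings", {
  clip <- audio_clip(sin(2 * pi * 150 * (0:19199) / 96000), 96000)
  sp <- compute_spectrogram(clip)
  expect_identical(sp$params$window_samples, 4096L)
  expect_equal(sp$freqs[2] - sp$freqs[1], 96000 / 4096)   # ~23.4 Hz bins
  expect_identical(sp$params$hop, 204L)                   # floor(5% of 4096)
  expect_error(compute_spectrogram(audio_clip(numeric(100) , 96000)),
               "window longer")
})

test_that("f0 is recovered from harmonic frames and undefined for silence", {
  fs <- 44100
  t <- (0:(fs / 2 - 1)) / fs
  mk <- function(f0) {
    y <- rowSums(sapply(1:10, function(k) sin(2 * pi * k * f0 * t) / k))
    audio_clip(y / max(abs(y)), fs)
  }
  for (f0 in c(150, 164)) {
    sp <- compute_spectrogram(mk(f0))
    est <- estimate_f0(sp$freqs, sp$mag_db[, 3])
    expect_lt(abs(est - f0), 1)
  }
  sp0 <- compute_spectrogram(audio_clip(numeric(44100), fs))
  expect_true(is.na(estimate_f0(sp0$freqs, sp0$mag_db[, 1])))
})

test_that("harmonic picking finds the comb, flags gaps, and ignores inharmonic partials", {
  fs <- 44100
  t <- (0:(fs / 2 - 1)) / fs
  full <- rowSums(sapply(1:12, function(k) sin(2 * pi * k * 150 * t)))
  gap <- rowSums(sapply(setdiff(1:12, 5), function(k) sin(2 * pi * k * 150 * t)))
  sp_f <- compute_spectrogram(audio_clip(full / max(abs(full)), fs))
  h <- pick_harmonics(sp_f$freqs, sp_f$mag_db[, 3], 150, n_max = 12)
  expect_true(all(!h$missing))
  expect_true(all(abs(h$freq_hz - 150 * h$k) < (sp_f$freqs[2] - sp_f$freqs[1]) / 2))

  sp_g <- compute_spectrogram(audio_clip(gap / max(abs(gap)), fs))
  hg <- pick_harmonics(sp_g$freqs, sp_g$mag_db[, 3], 150, n_max = 12)
  expect_true(hg$missing[5] || hg$level_db[5] < max(hg$level_db, na.rm = TRUE) - 40)

  two <- sin(2 * pi * 150 * t) + sin(2 * pi * 517 * t)    # inharmonic partner
  sp_t <- compute_spectrogram(audio_clip(two / max(abs(two)), fs))
  ht <- pick_harmonics(sp_t$freqs, sp_t$mag_db[, 3], 150, n_max = 6)
  strong <- ht[!ht$missing & ht$level_db > -30, ]
  expect_true(all(strong$k %in% c(1, 3)))   # 517 is read as a (mistuned) k=3
})

test_that("the envelope trend recovers a single focused peak and stays flat on a flat comb", {
  sp <- compute_spectrogram(fx_clip_focused())
  tr <- estimate_formant_trend(sp$freqs, sp$mag_db[, ncol(sp$mag_db) %/% 2], 150)
  expect_false(is.null(tr))
  top <- tr$formants[which.max(tr$formants$level_db), ]
  expect_lt(abs(top$freq_hz - 1800), 50)

  fs <- 44100
  t <- (0:(fs / 2 - 1)) / fs
  comb <- rowSums(sapply(1:25, function(k) sin(2 * pi * k * 150 * t)))
  spc <- compute_spectrogram(audio_clip(comb / max(abs(comb)), fs))
  trc <- estimate_formant_trend(spc$freqs, spc$mag_db[, 3], 150)
  mid <- trc$envelope$level_db[trc$envelope$freq_hz > 300 &
                                 trc$envelope$freq_hz < 3400]
  expect_lt(diff(range(mid)), 1.5)

  # neutral-filter frame shows several well-separated envelope peaks
  spn <- compute_spectrogram(fx_clip_normal())
  trn <- estimate_formant_trend(spn$freqs, spn$mag_db[, 10], 150)
  expect_gte(sum(trn$formants$freq_hz < 4000), 3)
})

test_that("the energy ratio follows its closed-form values on constructed spectra", {
  freqs <- seq(0, 8000, by = 1)
  # single tone at 1.5 kHz: all magnitude inside the band
  tone <- rep(-300, length(freqs)); tone[freqs == 1500] <- 0
  expect_equal(energy_ratio(freqs, tone, 1000, 2000, 8000), 1, tolerance = 1e-6)
  # flat magnitude over the full range: band holds 1/8 of the integral
  flat <- rep(0, length(freqs))
  expect_equal(energy_ratio(freqs, flat, 1000, 2000, 8000), (1 / 8)^2,
               tolerance = 5e-3)   # discrete band edges vs the exact integral
})

test_that("eR arithmetic matches the printed definition exactly", {
  freqs <- seq(0, 8000, by = 1)
  two <- rep(-300, length(freqs))
  two[freqs == 1500] <- 20 * log10(3)   # in-band magnitude 3
  two[freqs == 3000] <- 0               # out-of-band magnitude 1
  r <- energy_ratio(freqs, two, 1000, 2000, 8000)
  expect_equal(r, (3 / 4)^2, tolerance = 1e-4)
  # power variant is the prose reading: square then integrate, no outer square
  rp <- energy_ratio(freqs, two, 1000, 2000, 8000, variant = "power")
  expect_equal(rp, 9 / 10, tolerance = 1e-4)
})

test_that("eR is bounded, equals 1 on the full band, and grows with band width", {
  sp <- compute_spectrogram(fx_clip_focused())
  m <- sp$mag_db[, 5]
  expect_equal(energy_ratio(sp$freqs, m, 0, 8000, 8000), 1)
  widths <- cbind(c(1400, 1200, 1000, 600), c(1900, 2000, 2400, 3000))
  vals <- apply(widths, 1, function(b)
    energy_ratio(sp$freqs, m, b[1], b[2], 8000))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) >= -1e-12))
  tr <- focus_trace(sp)
  expect_true(all(tr$eR >= 0 & tr$eR <= 1))
  # constant clip: trace constant within 0.05
  expect_lt(diff(range(tr$eR)), 0.05)
  # silent clip: all frames undefined
  tr0 <- focus_trace(compute_spectrogram(audio_clip(numeric(44100), 44100)))
  expect_true(all(is.na(tr0$eR)))
})

test_that("transition detection fires once on steps and ignores chatter", {
  mk_trace <- function(eR, hop = 0.01)
    structure(list(times = seq_along(eR) * hop, eR = eR,
                   band = c(1000, 2000), fmax = 8000), class = "focus_trace")
  step <- mk_trace(c(rep(0.1, 200), rep(0.7, 200)))
  tt <- detect_transitions(step)
  expect_identical(nrow(tt), 1L)
  expect_lt(abs(tt$entry - 2.01), 0.011)

  expect_identical(nrow(detect_transitions(mk_trace(rep(0.3, 300)))), 0L)

  set.seed(1)
  chatter <- mk_trace(c(rep(0.1, 100),
                        0.35 + stats::runif(200, -0.02, 0.02),
                        rep(0.1, 100)))
  tt_c <- detect_transitions(chatter)
  expect_lte(nrow(tt_c), 1)   # one sustained entry at most, never chatter
})
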