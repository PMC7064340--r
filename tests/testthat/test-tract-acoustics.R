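test_that("lossless uniform closed-open tube resonates at odd quarter-wave frequencies", {
  af <- area_function(seq(0, 17.5, length.out = 44), rep(3, 44))
  const <- lossless_constants()
  fr <- compute_frequency_response(af, const, fmin = 10, fmax = 3000, df = 1)
  fm <- pick_formants(fr, n_max = 3)
  expected <- (2 * (1:3) - 1) * 35000 / (4 * 17.5)   # 500, 1500, 2500
  expect_true(all(abs(fm$freqs - expected) / expected < 0.01))

  # doubling the length halves every resonance
  af2 <- area_function(seq(0, 35, length.out = 44), rep(3, 44))
  fm2 <- pick_formants(compute_frequency_response(af2, const, fmin = 10,
                                                  fmax = 3000, df = 1), 3)
  expect_true(all(abs(fm2$freqs - expected / 2) / (expected / 2) < 0.01))

  # lossless formants are invariant to overall area scaling
  af3 <- area_function(af$x, af$A * 2.7)
  fm3 <- pick_formants(compute_frequency_response(af3, const, fmin = 10,
                                                  fmax = 3000, df = 1), 3)
  expect_true(all(abs(fm3$freqs - fm$freqs) <= 2))
})

test_that("losses shift peaks by less than 5% and make their heights finite", {
  af <- area_function(seq(0, 17.5, length.out = 44), rep(3, 44))
  fr_lossy <- compute_frequency_response(af, acoustic_constants(),
                                         fmin = 10, fmax = 3000, df = 1)
  fm_lossy <- pick_formants(fr_lossy, 3)
  expected <- (2 * (1:3) - 1) * 35000 / (4 * 17.5)
  expect_true(all(abs(fm_lossy$freqs - expected) / expected < 0.05))
  expect_true(all(is.finite(fm_lossy$levels_db)))
  expect_true(all(fm_lossy$levels_db < 80))   # far below the lossless spikes
})

test_that("peak picking resolves single resonances and flags coalesced pairs", {
  f <- seq(100, 4000, by = 2)
  lorentz <- function(f0, bw) 10 * log10(1 / (1 + ((f - f0) / (bw / 2))^2))
  fr1 <- frequency_response(f, lorentz(1800, 120))
  fm1 <- pick_formants(fr1)
  expect_length(fm1$freqs, 1)
  expect_equal(fm1$freqs, 1800, tolerance = 1e-3)

  # two constructed peaks 30 Hz apart with a 100 Hz separation rule
  fr2 <- frequency_response(f, pmax(lorentz(1500, 60), lorentz(1530, 60)))
  fm2 <- pick_formants(fr2, min_separation_hz = 100)
  expect_length(fm2$freqs, 1)
  expect_true(fm2$merged[1])

  expect_warning(fm0 <- pick_formants(frequency_response(f, rep(0, length(f)))),
                 "no formant")
  expect_length(fm0$freqs, 0)
})

test_that("F1 sensitivity is negative near the glottis and positive near the lips, summing to zero", {
  af <- area_function(seq(0, 17.5, length.out = 44), rep(3, 44))
  s <- compute_sensitivity(af, lossless_constants(), 1, fmax = 3000, df = 1)
  expect_lt(s$values[2], 0)
  expect_gt(s$values[43], 0)
  # uniform area scaling leaves lossless formants unchanged
  expect_lt(abs(sum(s$values)), 1e-6)
})

test_that("sensitivity predictions match finite-difference formant shifts within 10%", {
  const <- lossless_constants()
  for (seed in c(3, 8)) {
    af <- random_smooth_tract(seed)
    for (fi in 1:3) {
      s <- compute_sensitivity(af, const, fi, df = 1)
      for (n in c(5, 12, 30, 40)) {
        pred <- s$values[n] * 0.01 * s$formant_hz
        if (abs(pred) < 0.02) next    # shift below the oracle's resolution
        fd <- fd_formant_shift(af, const, s$formant_hz, n)
        expect_lt(abs(pred - fd) / abs(fd), 0.10)
      }
    }
  }
})

test_that("perturbation merges F2 and F3 on the 1800 Hz target", {
  res <- fx_focus_1800()
  expect_true(res$converged)
  expect_true(res$merged)
  fr <- compute_frequency_response(res$af, fx_const(), df = 2)
  fm <- pick_formants(fr, n_max = 5)
  # the merged peak is the second tracked formant and sits on the target
  expect_lt(abs(fm$freqs[2] - 1800) / 1800, 0.01)
  # the next peak is far above: F2 and F3 have become one
  expect_gt(fm$freqs[3], 2600)
  # geometry contract: floor respected, grid untouched
  expect_true(all(res$af$A >= 0.05 - 1e-12))
  expect_equal(length(res$af$A), length(fx_a0()$A))
  expect_equal(res$af$L, fx_a0()$L)
})

test_that("an already-focused tract is a fixed point of the perturbation", {
  res <- fx_focus_1800()
  fm <- pick_formants(compute_frequency_response(res$af, fx_const(), df = 2), 5)
  res2 <- perturb_to_focus(res$af, fx_const(), fm$freqs[2])
  expect_true(res2$converged)
  expect_lte(res2$iterations, 2)
  expect_lt(max(abs(res2$af$A - res$af$A) / res$af$A), 0.01)
})

test_that("a target below the F1 region is reported unreachable, not an error", {
  res <- perturb_to_focus(fx_a0(), fx_const(), 300)
  expect_false(res$converged)
  expect_identical(res$reason, "unreachable")
})
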