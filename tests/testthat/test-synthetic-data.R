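test_that("the designed neutral tract has widely spaced formants", {
  af <- fx_a0()
  expect_true(is_uniform_area_function(af))
  expect_true(all(af$A > 0))
  expect_equal(af$L, 17.5)
  fm <- pick_formants(compute_frequency_response(af, fx_const(), df = 2), 6)
  expect_gte(sum(fm$freqs < 4500), 4)
  expect_gt(fm$freqs[3] - fm$freqs[2], 500)
})

test_that("tightening the oral constriction CO pulls F2 and F3 together", {
  p <- tract_design_params()
  p2 <- tract_design_params(co_area = p$co_area * 0.5)
  gap <- function(pp) {
    fm <- pick_formants(compute_frequency_response(
      make_designed_area_function(pp), fx_const(), df = 2), 4)
    fm$freqs[3] - fm$freqs[2]
  }
  expect_lt(gap(p2), gap(p))
})

test_that("tightening the pharyngeal constriction CP moves the merged-formant frequency", {
  af <- fx_focus_1800()$af
  af2 <- af
  cp_region <- af$x > 5 & af$x < 9
  af2$A[cp_region] <- pmax(af$A[cp_region] * 0.5, 0.05)
  f_before <- refine_formant(af, fx_const(), 1800, radius_hz = 300)
  f_after <- refine_formant(af2, fx_const(), f_before, radius_hz = 400)
  expect_gte(abs(f_after - f_before), 50)
})

test_that("synthetic profiles carry their exact ground truth", {
  af <- area_function(seq(0, 17.5, length.out = 44), rep(3, 44))
  sp <- make_synthetic_profile(af, curvature = 0)
  D_expected <- 2 * sqrt(3 / pi)
  expect_equal(sp$profile$inner[, 2], rep(D_expected / 2, 44))
  expect_equal(sp$profile$outer[, 2], rep(-D_expected / 2, 44))
  expect_equal(sp$truth$D, rep(D_expected, 44))

  # 90-degree bend of a uniform tube produces concentric annular arcs
  sp90 <- make_synthetic_profile(af, curvature = 90)
  R <- 17.5 / (pi / 2)
  ri <- sqrt(rowSums(sweep(sp90$profile$inner, 2,
                           c(0, R), "-")^2))
  expect_true(all(abs(ri - (R - D_expected / 2)) < 1e-9))

  expect_error(make_synthetic_profile(af, curvature = 1200), "too tight")
})

test_that("scenario generation is seeded, style-consistent and in the published ranges", {
  s_norm <- make_song_scenario("normal", seed = 4)
  expect_identical(sum(s_norm$segments$state == "focused"), 0L)

  s1 <- make_song_scenario("sygyt", seed = 21)
  s2 <- make_song_scenario("sygyt", seed = 21)
  expect_identical(s1, s2)
  focus <- s1$segments$focus_hz[2]
  expect_true(focus >= 1500 && focus <= 2000)
  expect_true(s1$transition_ms >= 40 && s1$transition_ms <= 60)

  sd2 <- make_song_scenario("sygyt_double", seed = 5)
  second <- sd2$segments$second_focus_hz
  second <- second[!is.na(second)]
  expect_true(all(second >= 3000 & second <= 3500))
  expect_lt(diff(range(second)) / mean(second), 0.01)  # static across the clip

  expect_error(make_song_scenario("polka"), "arg")
})

test_that("generated tracts always satisfy the area-function invariants", {
  for (seed in 1:5) {
    af <- random_smooth_tract(seed)
    expect_true(all(af$A > 0))
    expect_true(all(diff(af$x) > 0))
    expect_equal(af$L, max(af$x))
  }
})

test_that("a full scenario survives the synthesis-analysis loop", {
  e <- fx_e2e()
  sp <- compute_spectrogram(e$clip, overlap = 0.5)
  tr <- focus_trace(sp)
  tt <- detect_transitions(tr)
  expect_identical(nrow(tt), 1L)
  hop_s <- sp$params$hop / e$clip$fs
  t_true <- e$scenario$segments$t_start[2] + e$scenario$transition_ms / 1000
  expect_lt(abs(tt$entry[1] - t_true), hop_s + 1e-9)

  late <- which(sp$times > t_true + 0.3)
  m <- rowMeans(sp$mag_db[, late])
  band <- sp$freqs >= 1000 & sp$freqs <= 2000
  recovered <- sp$freqs[band][which.max(m[band])]
  expect_lt(abs(recovered - e$scenario$segments$focus_hz[2]), 100)
})
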