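# Shared fixtures, built lazily and cached for the whole test run.
# The focusing runs are the expensive pieces (~10 s each); everything that
# needs them reuses the same converged result.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fx_const <- function() acoustic_constants()

fx_a0 <- function() fixture("a0", function() make_designed_area_function())

# converged focused tract for the canonical 12 x 150 = 1800 Hz target
fx_focus_1800 <- function() fixture("focus_1800", function()
  perturb_to_focus(fx_a0(), fx_const(), 1800))

fx_response_neutral <- function() fixture("fr_neutral", function()
  compute_frequency_response(fx_a0(), fx_const(), df = 2,
                             kind = "radiated_pressure"))

fx_response_focused <- function() fixture("fr_focused", function()
  compute_frequency_response(fx_focus_1800()$af, fx_const(), df = 2,
                             kind = "radiated_pressure"))

fx_clip_focused <- function() fixture("clip_focused", function()
  synthesize_static(glottal_source_spec(f0 = 150), fx_response_focused(),
                    duration = 2, fs = 44100))

fx_clip_normal <- function() fixture("clip_normal", function()
  synthesize_static(glottal_source_spec(f0 = 150), fx_response_neutral(),
                    duration = 2, fs = 44100))

# end-to-end scenario fixture: seeded sygyt scenario, focused tract built for
# the overtone nearest the scenario's focus frequency, dynamic synthesis
fx_e2e <- function() fixture("e2e", function() {
  scenario <- make_song_scenario("sygyt", f0_hz = 150, seed = 7)
  focus_hz <- scenario$segments$focus_hz[2]
  target <- round(focus_hz / scenario$f0_hz) * scenario$f0_hz
  res <- perturb_to_focus(fx_a0(), fx_const(), target)
  clip <- synthesize_dynamic(scenario, fx_a0(), res$af, fx_const())
  list(scenario = scenario, target = target, focus = res, clip = clip)
})

# independent finite-difference oracle for formant shifts: perturb one
# section, relocate the formant by direct recomputation of the response
fd_formant_shift <- function(af, const, near_hz, n, eps = 0.01) {
  up <- af; up$A[n] <- up$A[n] * (1 + eps)
  dn <- af; dn$A[n] <- dn$A[n] * (1 - eps)
  (refine_formant(up, const, near_hz) - refine_formant(dn, const, near_hz)) / 2
}

# random smooth tract on a uniform grid (log-area Fourier bumps)
random_smooth_tract <- function(seed, n = 44, L = 17.5, A0 = 3) {
  set.seed(seed)
  x <- seq(0, L, length.out = n)
  la <- log(A0) +
    stats::rnorm(1, 0, 0.3) * sin(pi * x / L + stats::runif(1, 0, pi)) +
    stats::rnorm(1, 0, 0.2) * sin(2 * pi * x / L + stats::runif(1, 0, pi))
  area_function(x, exp(la))
}

# harmonic levels of a clip measured from an averaged spectrogram frame
measured_harmonic_levels <- function(clip, f0, n_max = 20) {
  sp <- compute_spectrogram(clip)
  mid <- ncol(sp$mag_db) %/% 2
  pick_harmonics(sp$freqs, sp$mag_db[, mid], f0, n_max = n_max)
}
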