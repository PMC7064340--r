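#' Parameters for a designed vocal-tract area function
#'
#' Describes a parametric "designed" tract: a smooth baseline tube of area
#' `A_rest` with a cosine-tapered narrowing toward the glottis (the
#' epilaryngeal region), two Gaussian-profile (in log-area) constrictions —
#' CP near the uvula in the upper pharynx and CO near the alveolar ridge in
#' the oral cavity — and a large sublingual expansion just anterior to CO
#' (the retroflex tongue position opens this space). With the sizeable
#' expansion the front cavity acts as a Helmholtz-type resonator whose mode
#' lies between the back-cavity modes, so tightening CO monotonically pulls
#' F2 and F3 together while CP sets the frequency at which they meet.
#'
#' @param L Tract length, glottis to lips (cm).
#' @param A_rest Baseline area (cm^2).
#' @param A_glottis Area at the glottal end of the taper (cm^2).
#' @param taper_len Length of the glottal cosine taper (cm).
#' @param cp_position,cp_area Pharyngeal (uvular) constriction: location from
#'   the glottis (cm) and area at its center (cm^2).
#' @param co_position,co_area Oral (alveolar-ridge) constriction: location
#'   (cm) and area (cm^2).
#' @param sublingual_expansion_area Area of the expansion anterior to CO
#'   (cm^2).
#' @param taper_width Gaussian sigma of the constriction profiles (cm).
#' @param n_sections Number of tube sections.
#' @return Object of class `tract_design_params`.
#' @export
tract_design_params <- function(L = 17.5, A_rest = 2.5, A_glottis = 0.5,
                                taper_len = 2.5,
                                cp_position = 7, cp_area = 2.2,
                                co_position = 14, co_area = 1.6,
                                sublingual_expansion_area = 9,
                                taper_width = 1, n_sections = 44) {
  p <- list(L = L, A_rest = A_rest, A_glottis = A_glottis,
            taper_len = taper_len,
            cp_position = cp_position, cp_area = cp_area,
            co_position = co_position, co_area = co_area,
            sublingual_expansion_area = sublingual_expansion_area,
            taper_width = taper_width, n_sections = n_sections)
  with(p, {
    if (!(L > 0 && A_rest > 0 && A_glottis > 0 && cp_area > 0 && co_area > 0 &&
          sublingual_expansion_area > 0 && taper_width > 0 && n_sections >= 8))
      stop("invalid tract design parameters")
    if (!(cp_position > 0 && cp_position < L && co_position > 0 && co_position < L))
      stop("constriction positions must lie inside (0, L)")
    if (cp_position >= co_position)
      stop("cp_position must be glottis-ward of co_position")
    if (co_position - cp_position < 2 * taper_width)
      stop("constriction supports overlap beyond taper limits")
  })
  structure(p, class = "tract_design_params")
}

#' Build a designed area function
#'
#' Constructs the parametric tract described by [tract_design_params()]. The
#' defaults yield a neutral-vowel-like configuration with widely spaced
#' formants (F3 - F2 well above 500 Hz), a suitable starting point for the
#' formant-merging perturbation.
#'
#' @param p A [tract_design_params()].
#' @return A uniform-grid [area_function()].
#' @export
make_designed_area_function <- function(p = tract_design_params()) {
  stopifnot(inherits(p, "tract_design_params"))
  x <- seq(0, p$L, length.out = p$n_sections)
  la <- rep(log(p$A_rest), p$n_sections)
  ramp <- ifelse(x < p$taper_len, 0.5 * (1 + cos(pi * x / p$taper_len)), 0)
  la <- la + (log(p$A_glottis) - log(p$A_rest)) * ramp
  g <- function(pos, area, sig) (log(area) - log(p$A_rest)) *
    exp(-(x - pos)^2 / (2 * sig^2))
  la <- la + g(p$cp_position, p$cp_area, p$taper_width)
  la <- la + g(p$co_position, p$co_area, p$taper_width)
  la <- la + g(p$co_position + 1.75, p$sublingual_expansion_area,
               0.75 * p$taper_width)
  area_function(x, exp(la))
}

#' Generate a synthetic midsagittal profile from an area function
#'
#' Oracle generator for [extract_centerline()]: builds a centerline (straight
#' or a circular-arc bend), converts areas to cross-distances with the
#' circular approximation `D = sqrt(A / (pi/4))`, and offsets the two
#' contours by `+/- D/2` along the local normal. The exact centerline and
#' cross-distance series are returned as ground truth.
#'
#' @param af An [area_function()].
#' @param curvature Total bend angle in degrees (0 = straight tube). The
#'   bend radius is `L / angle`; an error is raised if the inner contour
#'   would self-intersect.
#' @return List with elements `profile` (a [sagittal_profile()]) and `truth`
#'   (a [cross_section_series()]).
#' @export
make_synthetic_profile <- function(af, curvature = 0) {
  stopifnot(inherits(af, "area_function"))
  D <- sqrt(af$A / (pi / 4))
  x <- af$x
  if (abs(curvature) < 1e-9) {
    center <- cbind(x, rep(0, length(x)))
    normal <- cbind(rep(0, length(x)), rep(1, length(x)))
  } else {
    theta_tot <- curvature * pi / 180
    R <- af$L / abs(theta_tot)
    if (R - max(D) / 2 <= 0.05)
      stop("bend too tight: inner contour would self-intersect")
    s <- sign(theta_tot)
    th <- x / R                               # unsigned arc angle
    center <- cbind(R * sin(th), s * R * (1 - cos(th)))
    # unit normal toward the bend center: the inner contour lies on that side
    normal <- cbind(-sin(th), s * cos(th))
  }
  inner <- center + normal * (D / 2)
  outer <- center - normal * (D / 2)
  profile <- sagittal_profile(inner, outer)
  truth <- cross_section_series(center, x, D)
  list(profile = profile, truth = truth)
}

#' Song scenario: a parametric timeline for synthesis
#'
#' A scenario is the ground-truth description of a (synthetic) performance:
#' fundamental frequency, a sequence of normal / focused segments with their
#' focus frequencies, the ramp duration of state transitions, and vibrato.
#' It drives [synthesize_dynamic()] and serves as ground truth for the
#' recovery tests of the analysis stage.
#'
#' @param duration Clip duration (s).
#' @param f0_hz Fundamental frequency (Hz).
#' @param segments Data frame with columns `t_start` (s), `state` ("normal"
#'   or "focused"), `focus_hz` (NA for normal), optional `second_focus_hz`.
#'   Must be ordered by `t_start`, first segment at 0.
#' @param transition_ms Ramp duration of state changes (ms); the fast
#'   transitions of real performances are ~40-60 ms.
#' @param vibrato_rate Vibrato rate (Hz).
#' @param vibrato_depth_cents Vibrato depth (cents, 0 = off).
#' @param seed Integer seed recorded with the scenario.
#' @return Object of class `song_scenario`.
#' @export
song_scenario <- function(duration, f0_hz, segments, transition_ms = 50,
                          vibrato_rate = 5, vibrato_depth_cents = 0,
                          seed = NA_integer_) {
  stopifnot(duration > 0, f0_hz > 0, transition_ms > 0)
  segments <- as.data.frame(segments)
  if (!all(c("t_start", "state", "focus_hz") %in% names(segments)))
    stop("segments need columns t_start, state, focus_hz")
  if (!("second_focus_hz" %in% names(segments)))
    segments$second_focus_hz <- NA_real_
  if (is.unsorted(segments$t_start, strictly = TRUE))
    stop("segments must be ordered by t_start")
  if (abs(segments$t_start[1]) > 1e-9) stop("first segment must start at 0")
  if (!all(segments$state %in% c("normal", "focused")))
    stop("segment states must be 'normal' or 'focused'")
  structure(list(duration = duration, f0_hz = f0_hz, segments = segments,
                 transition_ms = transition_ms,
                 vibrato_rate = vibrato_rate,
                 vibrato_depth_cents = vibrato_depth_cents,
                 seed = seed),
            class = "song_scenario")
}

#' @export
print.song_scenario <- function(x, ...) {
  cat(sprintf("<song_scenario> %.1f s, f0 = %.0f Hz, %d segment(s), transition %.0f ms\n",
              x$duration, x$f0_hz, nrow(x$segments), x$transition_ms))
  invisible(x)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a reproducible song scenario
#'
#' Three styles are available. `"normal"` is a plain sustained tone with no
#' focused segment. `"sygyt"` starts in the normal state and transitions
#' once into a focused state whose focus frequency is drawn uniformly from
#' 1500-2000 Hz (the band where real performances place the whistle-like
#' melodic overtone). `"sygyt_double"` additionally carries a static second
#' focus drawn from 3000-3500 Hz, constant over the clip, emulating singers
#' who hold a second focused formant fixed while the first one moves.
#'
#' @param style One of `"normal"`, `"sygyt"`, `"sygyt_double"`.
#' @param f0_hz Fundamental (Hz); real performances sit near 140-165 Hz.
#' @param seed Integer seed; scenarios are bit-reproducible given the seed.
#' @param duration Clip duration (s).
#' @param transition_time Time of the normal-to-focused transition (s).
#' @return A [song_scenario()].
#' @export
make_song_scenario <- function(style = c("normal", "sygyt", "sygyt_double"),
                               f0_hz = 150, seed = 1, duration = 4,
                               transition_time = duration / 2) {
  style <- match.arg(style)
  with_local_seed(seed, {
    transition_ms <- stats::runif(1, 40, 60)
    if (style == "normal") {
      seg <- data.frame(t_start = 0, state = "normal", focus_hz = NA_real_,
                        second_focus_hz = NA_real_)
    } else {
      focus <- stats::runif(1, 1500, 2000)
      second <- if (style == "sygyt_double") stats::runif(1, 3000, 3500)
                else NA_real_
      seg <- data.frame(
        t_start = c(0, transition_time),
        state = c("normal", "focused"),
        focus_hz = c(NA_real_, focus),
        second_focus_hz = c(NA_real_, second))
    }
    song_scenario(duration, f0_hz, seg, transition_ms = transition_ms,
                  seed = seed)
  })
}

#' Read / write scenario files (YAML)
#'
#' @param path File path.
#' @return `read_scenario_yaml` returns a [song_scenario()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(y$segments, function(s)
    data.frame(t_start = s$t_start, state = s$state,
               focus_hz = if (is.null(s$focus_hz)) NA_real_ else s$focus_hz,
               second_focus_hz = if (is.null(s$second_focus_hz)) NA_real_
                                 else s$second_focus_hz)))
  song_scenario(y$duration, y$f0_hz, seg,
                transition_ms = y$transition_ms %||% 50,
                vibrato_rate = y$vibrato$rate %||% 5,
                vibrato_depth_cents = y$vibrato$depth_cents %||% 0,
                seed = y$seed %||% NA_integer_)
}

#' @rdname read_scenario_yaml
#' @param scenario A [song_scenario()].
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "song_scenario"))
  segs <- lapply(seq_len(nrow(scenario$segments)), function(i) {
    s <- scenario$segments[i, ]
    out <- list(t_start = s$t_start, state = s$state)
    if (!is.na(s$focus_hz)) out$focus_hz <- s$focus_hz
    if (!is.na(s$second_focus_hz)) out$second_focus_hz <- s$second_focus_hz
    out
  })
  y <- list(duration = scenario$duration, f0_hz = scenario$f0_hz,
            segments = segs, transition_ms = scenario$transition_ms,
            vibrato = list(rate = scenario$vibrato_rate,
                           depth_cents = scenario$vibrato_depth_cents),
            seed = scenario$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
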