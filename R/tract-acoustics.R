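#' Physical constants and loss switches for the transmission-line model
#'
#' The tract is modeled in CGS units as a chain of uniform tube sections with
#' frequency-dependent losses. The paper-level mechanisms are yielding walls,
#' viscous friction, heat conduction and acoustic radiation at the lips; the
#' numeric values below are the standard ones of the classic transmission-line
#' literature (body-temperature moist air; soft-tissue wall impedance).
#'
#' @param c Speed of sound (cm/s).
#' @param rho Air density (g/cm^3).
#' @param wall_resistance Wall mechanical resistance per unit wall area
#'   (dyn s/cm^3).
#' @param wall_mass Wall mass per unit wall area (g/cm^2).
#' @param wall_compliance Wall stiffness per unit wall area (dyn/cm^3).
#' @param mu Dynamic viscosity of air (g/(cm s)).
#' @param lambda Thermal conductivity (cal/(cm s degC)).
#' @param cp Specific heat of air at constant pressure (cal/(g degC)).
#' @param eta Adiabatic constant (ratio of specific heats).
#' @param include_walls,include_viscous_thermal,include_radiation Loss
#'   switches; all `TRUE` by default. With all three `FALSE` the model is the
#'   lossless rigid-walled tube (useful for analytic checks).
#' @return An object of class `acoustic_constants`.
#' @export
acoustic_constants <- function(c = 35000, rho = 1.14e-3,
                               wall_resistance = 1600, wall_mass = 1.5,
                               wall_compliance = 3e5,
                               mu = 1.86e-4, lambda = 5.5e-5, cp = 0.24,
                               eta = 1.4,
                               include_walls = TRUE,
                               include_viscous_thermal = TRUE,
                               include_radiation = TRUE) {
  stopifnot(c > 0, rho > 0, wall_resistance >= 0, wall_mass >= 0,
            wall_compliance >= 0, mu >= 0, lambda >= 0)
  structure(list(c = c, rho = rho,
                 wall_resistance = wall_resistance, wall_mass = wall_mass,
                 wall_compliance = wall_compliance,
                 mu = mu, lambda = lambda, cp = cp, eta = eta,
                 include_walls = isTRUE(include_walls),
                 include_viscous_thermal = isTRUE(include_viscous_thermal),
                 include_radiation = isTRUE(include_radiation)),
            class = "acoustic_constants")
}

#' Lossless constants (rigid walls, no viscous/thermal loss, no radiation)
#' @param ... Overrides passed to [acoustic_constants()].
#' @export
lossless_constants <- function(...) {
  acoustic_constants(include_walls = FALSE, include_viscous_thermal = FALSE,
                     include_radiation = FALSE, ...)
}

#' Frequency response container
#'
#' @param freq Frequency grid (Hz), strictly increasing, starting above 0.
#' @param gain_db Gain (dB) relative to the model reference.
#' @param kind Transfer-function definition: `"volume_velocity"` is
#'   U(lips)/U(glottis); `"radiated_pressure"` adds the lip radiation
#'   characteristic (+6 dB/octave).
#' @return An object of class `frequency_response`.
#' @export
frequency_response <- function(freq, gain_db, kind = "volume_velocity") {
  freq <- as.numeric(freq); gain_db <- as.numeric(gain_db)
  if (length(freq) != length(gain_db)) stop("freq and gain_db length mismatch")
  if (freq[1] <= 0 || any(diff(freq) <= 0))
    stop("freq must be strictly increasing and start above 0")
  if (!all(is.finite(gain_db))) stop("gain_db must be finite")
  structure(list(freq = freq, gain_db = gain_db, kind = kind),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> [%s] %.0f-%.0f Hz, %d points\n",
              x$kind, min(x$freq), max(x$freq), length(x$freq)))
  invisible(x)
}

# per-section chain (ABCD) parameters at all frequencies; returns list of
# complex vectors a, b, c (matrix entries; d == a for a symmetric section)
section_chain <- function(w, A, l, const) {
  rho <- const$rho; cs <- const$c
  S <- 2 * sqrt(pi * A)                      # circumference (circular section)
  Zs <- 1i * w * rho / A                     # series inertance per unit length
  Ys <- 1i * w * A / (rho * cs^2)            # shunt compliance per unit length
  if (const$include_viscous_thermal) {
    Zs <- Zs + (S / A^2) * sqrt(w * rho * const$mu / 2)
    Ys <- Ys + S * (const$eta - 1) / (rho * cs^2) *
      sqrt(const$lambda * w / (2 * const$cp * rho))
  }
  if (const$include_walls) {
    zw <- const$wall_resistance + 1i * w * const$wall_mass +
      const$wall_compliance / (1i * w)
    Ys <- Ys + S / zw
  }
  gam <- sqrt(Zs * Ys)
  gam <- ifelse(Re(gam) < 0, -gam, gam)
  Zc <- sqrt(Zs / Ys)
  gl <- gam * l
  list(a = cosh(gl), b = Zc * sinh(gl), c = sinh(gl) / Zc)
}

# radiation impedance at the lips: piston in an infinite baffle (low-ka form)
radiation_impedance <- function(w, A_lip, const) {
  a <- sqrt(A_lip / pi)
  k <- w / const$c
  (const$rho * const$c / A_lip) * ((k * a)^2 / 2 + 1i * 8 * k * a / (3 * pi))
}

# complex U(lips)/U(glottis) at angular frequencies w for a uniform-grid af
tract_transfer <- function(af, const, w) {
  N <- length(af$A)
  l <- af$L / N
  Ac <- complex(real = rep(1, length(w)))
  Bc <- complex(real = rep(0, length(w)))
  Cc <- Bc; Dc <- Ac
  for (n in seq_len(N)) {
    m <- section_chain(w, af$A[n], l, const)
    A2 <- Ac * m$a + Bc * m$c
    B2 <- Ac * m$b + Bc * m$a
    C2 <- Cc * m$a + Dc * m$c
    D2 <- Cc * m$b + Dc * m$a
    Ac <- A2; Bc <- B2; Cc <- C2; Dc <- D2
  }
  Zr <- if (const$include_radiation) radiation_impedance(w, af$A[N], const) else 0
  1 / (Cc * Zr + Dc)
}

#' Compute the transmission-line frequency response of an area function
#'
#' The tract is a cascade of uniform tube sections (two-port chain matrices
#' with complex propagation constants carrying the enabled loss terms),
#' terminated at the lips by a piston-in-baffle radiation load and driven at
#' the glottis by an ideal volume-velocity source. Peaks of the returned gain
#' curve are the formants.
#'
#' @param af A uniform-grid [area_function()] (see
#'   [resample_area_function()]).
#' @param const [acoustic_constants()].
#' @param fmin,fmax,df Frequency grid (Hz): `seq(fmin, fmax, by = df)`.
#' @param kind `"volume_velocity"` (default) or `"radiated_pressure"`; the
#'   latter adds the +6 dB/octave lip radiation characteristic and is what a
#'   microphone records. Formant frequencies are insensitive to the choice.
#' @return A [frequency_response()].
#' @export
compute_frequency_response <- function(af, const = acoustic_constants(),
                                       fmin = 10, fmax = 8000, df = 2,
                                       kind = c("volume_velocity",
                                                "radiated_pressure")) {
  stopifnot(inherits(af, "area_function"), inherits(const, "acoustic_constants"))
  kind <- match.arg(kind)
  if (!(fmin > 0 && fmax > fmin && df > 0))
    stop("need 0 < fmin < fmax and df > 0")
  if (!is_uniform_area_function(af))
    stop("area function must be resampled to uniform sections first")
  f <- seq(fmin, fmax, by = df)
  H <- tract_transfer(af, const, 2 * pi * f)
  g <- 20 * log10(pmax(Mod(H), 1e-30))
  if (kind == "radiated_pressure")
    g <- g + 20 * log10(f / 1000)   # radiation characteristic, ref 1 kHz
  frequency_response(f, g, kind = kind)
}

#' Formant set (ordered resonance peaks)
#'
#' @param freqs Ascending formant frequencies (Hz).
#' @param levels_db Peak levels (dB).
#' @param merged Logical: peak absorbed a neighbor (two tracked formants
#'   coalesced into one).
#' @return Object of class `formant_set`.
#' @export
formant_set <- function(freqs, levels_db, merged = rep(FALSE, length(freqs))) {
  if (length(freqs) && any(diff(freqs) <= 0)) stop("formants must be ascending")
  structure(list(freqs = freqs, levels_db = levels_db, merged = merged),
            class = "formant_set")
}

#' @export
print.formant_set <- function(x, ...) {
  if (!length(x$freqs)) { cat("<formant_set> (empty)\n"); return(invisible(x)) }
  lab <- sprintf("F%d=%.0f%s", seq_along(x$freqs), x$freqs,
                 ifelse(x$merged, "*", ""))
  cat("<formant_set>", paste(lab, collapse = " "), "Hz (* = merged)\n")
  invisible(x)
}

# indices of local maxima with prominence (dB); ties broken toward lower freq
local_peaks <- function(y) {
  n <- length(y)
  which(diff(sign(diff(y))) < 0) + 1
}

peak_prominence <- function(y, p) {
  h <- y[p]
  side_saddle <- function(idx) {
    if (!length(idx)) return(min(y))           # runs off the data edge
    higher <- idx[y[idx] > h]
    if (!length(higher)) return(min(y[idx]))
    if (idx[1] < p) min(y[max(higher):p]) else min(y[p:min(higher)])
  }
  left <- side_saddle(seq_len(p - 1))
  right <- side_saddle(if (p < length(y)) (p + 1):length(y) else integer())
  h - max(left, right)
}

# quadratic (parabolic) refinement of a peak position on a uniform grid
refine_peak <- function(freq, y, p) {
  if (p <= 1 || p >= length(y)) return(c(freq[p], y[p]))
  a <- y[p - 1]; b <- y[p]; cc <- y[p + 1]
  denom <- a - 2 * b + cc
  if (abs(denom) < 1e-12) return(c(freq[p], b))
  d <- 0.5 * (a - cc) / denom
  d <- max(min(d, 0.5), -0.5)
  c(freq[p] + d * (freq[2] - freq[1]), b - 0.25 * (a - cc) * d)
}

#' Pick formants from a frequency response
#'
#' Local maxima meeting a prominence threshold, with a minimum-separation
#' rule: peaks closer than `min_separation_hz` are merged into one (the
#' higher peak is kept and flagged), which is how the coalescence of two
#' formants into a single focused peak is detected. Peak positions are
#' refined by quadratic interpolation around the grid maximum.
#'
#' @param fr A [frequency_response()].
#' @param n_max Maximum number of formants returned (lowest frequencies
#'   first).
#' @param min_prominence_db Minimum peak prominence (dB).
#' @param min_separation_hz Minimum spacing between distinct formants (Hz).
#' @return A [formant_set()]; empty (with a warning) if no peak qualifies.
#' @export
pick_formants <- function(fr, n_max = 5, min_prominence_db = 1,
                          min_separation_hz = 80) {
  stopifnot(inherits(fr, "frequency_response"))
  y <- fr$gain_db
  p <- local_peaks(y)
  if (length(p)) {
    prom <- vapply(p, function(i) peak_prominence(y, i), numeric(1))
    p <- p[prom >= min_prominence_db]
  }
  if (!length(p)) {
    warning("no formant peaks found")
    return(formant_set(numeric(0), numeric(0), logical(0)))
  }
  ref <- t(vapply(p, function(i) refine_peak(fr$freq, y, i), numeric(2)))
  freqs <- ref[, 1]; levels <- ref[, 2]
  merged <- rep(FALSE, length(freqs))
  repeat {
    gaps <- diff(freqs)
    k <- which(gaps < min_separation_hz)
    if (!length(k)) break
    k <- k[1]
    keep <- if (levels[k] >= levels[k + 1]) k else k + 1   # tie: lower freq
    drop <- if (keep == k) k + 1 else k
    merged[keep] <- TRUE
    freqs <- freqs[-drop]; levels <- levels[-drop]; merged <- merged[-drop]
  }
  n <- min(n_max, length(freqs))
  formant_set(freqs[seq_len(n)], levels[seq_len(n)], merged[seq_len(n)])
}

# acoustic energy distributions inside the tract at angular frequency w,
# driven with unit volume velocity at the lips (scale cancels on normalizing)
tract_energy_profile <- function(af, const, w) {
  N <- length(af$A)
  l <- af$L / N
  Zr <- if (const$include_radiation) radiation_impedance(w, af$A[N], const) else 0
  U <- 1 + 0i
  P <- Zr * U
  KE <- numeric(N); PE <- numeric(N)
  rho <- const$rho; c2 <- const$c^2
  for (n in rev(seq_len(N))) {          # walk from the lips back to glottis
    m <- section_chain(w, af$A[n], l, const)
    P_in <- m$a * P + m$b * U
    U_in <- m$c * P + m$a * U
    u2 <- (Mod(U)^2 + Mod(U_in)^2) / 2
    p2 <- (Mod(P)^2 + Mod(P_in)^2) / 2
    KE[n] <- rho * l / (2 * af$A[n]) * u2
    PE[n] <- af$A[n] * l / (2 * rho * c2) * p2
    P <- P_in; U <- U_in
  }
  list(KE = KE, PE = PE)
}

# sensitivity values at a known resonance frequency (Hz)
sensitivity_at <- function(af, const, f_hz) {
  e <- tract_energy_profile(af, const, 2 * pi * f_hz)
  (e$KE - e$PE) / sum(e$KE + e$PE)
}

#' Acoustic sensitivity of a formant to local area perturbations
#'
#' For tube section `n`, the sensitivity is the normalized difference of
#' kinetic and potential acoustic energy stored in that section at the
#' formant frequency, `S(n) = (KE_n - PE_n) / sum(KE + PE)`. It predicts the
#' fractional formant shift produced by a small fractional area perturbation
#' pattern `delta(n)`:  `dF/F ~ sum_n S(n) * delta(n)`. Widening the tube
#' where kinetic energy dominates (velocity antinodes) raises the formant;
#' widening where potential energy dominates (pressure antinodes) lowers it.
#'
#' @param af A uniform-grid [area_function()].
#' @param const [acoustic_constants()].
#' @param formant_index Which formant (1 = F1, ...), resolved via
#'   [pick_formants()] on the response of `af`.
#' @param fmax,df Grid for the formant search (Hz).
#' @return Object of class `sensitivity_function` with fields
#'   `formant_index`, `formant_hz` and `values` (one per tube section).
#' @export
compute_sensitivity <- function(af, const = acoustic_constants(),
                                formant_index = 1, fmax = 8000, df = 2) {
  fr <- compute_frequency_response(af, const, fmax = fmax, df = df)
  fmts <- pick_formants(fr, n_max = max(formant_index, 5))
  if (length(fmts$freqs) < formant_index)
    stop("formant F", formant_index, " not found in the response")
  f <- fmts$freqs[formant_index]
  structure(list(formant_index = formant_index, formant_hz = f,
                 values = sensitivity_at(af, const, f)),
            class = "sensitivity_function")
}

#' @export
print.sensitivity_function <- function(x, ...) {
  cat(sprintf("<sensitivity_function> F%d at %.0f Hz, %d sections, sum=%.3g\n",
              x$formant_index, x$formant_hz, length(x$values), sum(x$values)))
  invisible(x)
}

moving_average3 <- function(v) {
  n <- length(v)
  out <- v
  if (n >= 3) out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  if (n >= 2) {
    out[1] <- (v[1] + v[2]) / 2
    out[n] <- (v[n - 1] + v[n]) / 2
  }
  out
}

#' Perturb an area function until two formants merge on a target frequency
#'
#' Implements the sensitivity-based focusing procedure: at each iteration the
#' two tracked formants and their sensitivity functions are computed, and the
#' areas receive a fractional update
#' `dA(n)/A(n) = step * (Shat_i(n) (T - Fi)/Fi + Shat_j(n) (T - Fj)/Fj)`
#' where `Shat = S / sum(S^2)` is the sensitivity normalized so that a unit
#' step closes a `step`-sized fraction of the remaining frequency gap per
#' iteration (geometric convergence); the raw-sensitivity update moves the
#' formants only fractions of a hertz per iteration. Updates are smoothed
#' with a 3-section moving average, clipped at +/- 20% per iteration and
#' floored at `area_floor`. The iteration stops when both formants are
#' within `tol * target` of the target, or when the picked response shows a
#' single merged peak within `tol * target` of it. Once the two peaks have
#' coalesced, the update continues on the merged peak with a doubled drive
#' until it reaches the target.
#'
#' @param af0 Starting uniform-grid [area_function()].
#' @param const [acoustic_constants()].
#' @param target_hz Target frequency (Hz), e.g. an overtone `n * f0`.
#' @param formant_indices Length-2 integer vector, default `c(2, 3)`.
#' @param step Update gain per iteration.
#' @param max_iter Iteration cap; reaching it yields a non-convergence
#'   result (not an error) carrying the trace.
#' @param area_floor Minimum allowed section area (cm^2).
#' @param tol Relative tolerance on the target.
#' @param df Frequency-grid step (Hz) used during iteration.
#' @param fmax Upper frequency bound (Hz) of the response used during
#'   iteration.
#' After the merge, an optional "deep focus" stage (`sharpen = TRUE`)
#' progressively tightens the controlling (narrowest) constriction toward
#' `area_floor`, re-centering the merged peak on the target in between.
#' This is the oral-constriction mechanism made explicit: the degree of
#' constriction sets how completely the two formants coalesce, and without
#' it the two poles stall ~150 Hz apart, leaving a broad merged peak. The
#' deep stage yields the strong suppression of the overtones flanking the
#' focused one (~25 dB) seen in real performances.
#'
#' @return Object of class `focus_result`: fields `af` (final area
#'   function), `converged`, `merged`, `reason`, `iterations`, `target_hz`,
#'   and `trace` (data frame with per-iteration formant frequencies).
#' @export
perturb_to_focus <- function(af0, const = acoustic_constants(), target_hz,
                             formant_indices = c(2, 3),
                             step = 0.1, max_iter = 200, area_floor = 0.05,
                             tol = 0.01, df = 2, fmax = 8000,
                             sharpen = TRUE) {
  stopifnot(inherits(af0, "area_function"), length(formant_indices) == 2)
  i <- min(formant_indices); j <- max(formant_indices)
  if (j != i + 1) stop("formant_indices must be adjacent formants")
  if (!(target_hz > 0 && target_hz < fmax)) stop("target_hz outside (0, fmax)")

  pick <- function(af) pick_formants(compute_frequency_response(
    af, const, fmax = fmax, df = df), n_max = 8)

  count_low <- function(fm) sum(fm$freqs < 5000)
  empty_trace <- data.frame(iter = integer(), Fi = numeric(),
                            Fj = numeric(), merged = logical())
  result <- function(af, converged, merged, reason, it, trace) {
    structure(list(af = af, converged = converged, merged = merged,
                   reason = reason, iterations = it, target_hz = target_hz,
                   trace = trace),
              class = "focus_result")
  }

  fm0 <- pick(af0)
  if (length(fm0$freqs) < j) stop("formants ", i, ",", j, " not found on af0")
  if (target_hz < 0.8 * fm0$freqs[1])
    return(result(af0, FALSE, FALSE, "unreachable", 0, empty_trace))
  # already-merged tract: formant i sits on the target and the next tracked
  # peak is far away (what indexes as "Fj" is really the formant above the
  # merged pair)
  if (abs(fm0$freqs[i] - target_hz) <= tol * target_hz &&
      abs(fm0$freqs[j] - target_hz) > 0.3 * target_hz)
    return(result(af0, TRUE, TRUE, "already_converged", 0, empty_trace))
  n0 <- count_low(fm0)

  af <- af0
  trace <- vector("list", max_iter)
  converged <- FALSE; merged_final <- FALSE; reason <- "max_iter"
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    fm <- pick(af)
    n_now <- count_low(fm)
    is_merged <- length(fm$freqs) >= i &&
      (n_now < n0 || isTRUE(fm$merged[i]))
    if (is_merged) {
      Fm <- fm$freqs[i]
      trace[[it]] <- data.frame(iter = it, Fi = Fm, Fj = NA_real_, merged = TRUE)
      if (abs(Fm - target_hz) <= tol * target_hz) {
        converged <- TRUE; merged_final <- TRUE; reason <- "merged_on_target"
        break
      }
      S <- sensitivity_at(af, const, Fm)
      S <- S / sum(S^2)
      delta <- step * S * 2 * (target_hz - Fm) / Fm
    } else {
      if (length(fm$freqs) < j) { reason <- "formants_lost"; break }
      Fi <- fm$freqs[i]; Fj <- fm$freqs[j]
      trace[[it]] <- data.frame(iter = it, Fi = Fi, Fj = Fj, merged = FALSE)
      if (abs(Fi - target_hz) <= tol * target_hz &&
          abs(Fj - target_hz) <= tol * target_hz) {
        converged <- TRUE; merged_final <- isTRUE(fm$merged[i])
        reason <- "formants_on_target"
        break
      }
      Si <- sensitivity_at(af, const, Fi)
      Sj <- sensitivity_at(af, const, Fj)
      delta <- step * (Si / sum(Si^2) * (target_hz - Fi) / Fi +
                       Sj / sum(Sj^2) * (target_hz - Fj) / Fj)
    }
    delta <- moving_average3(delta)
    delta <- pmax(pmin(delta, 0.2), -0.2)
    af <- area_function(af$x, pmax(af$A * (1 + delta), area_floor))
  }
  if (converged && merged_final && sharpen)
    af <- deepen_focus(af, const, target_hz, area_floor = area_floor,
                       tol = tol, step = step)
  structure(list(af = af, converged = converged, merged = merged_final,
                 reason = reason, iterations = it, target_hz = target_hz,
                 trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))])),
            class = "focus_result")
}

# deep-focus stage: tighten the narrowest constriction toward the floor,
# keeping the merged peak centered on the target with sensitivity steps
deepen_focus <- function(af, const, target_hz, area_floor = 0.05, tol = 0.01,
                         step = 0.1, dip_step = 0.8, max_tighten = 20) {
  recenter <- function(af) {
    for (r in 1:2) {
      Fm <- refine_formant(af, const, target_hz, radius_hz = 250)
      if (abs(Fm - target_hz) < 0.2 * tol * target_hz) break
      S <- sensitivity_at(af, const, Fm)
      delta <- 3 * step * S / sum(S^2) * 2 * (target_hz - Fm) / Fm
      delta <- pmax(pmin(moving_average3(delta), 0.2), -0.2)
      af <- area_function(af$x, pmax(af$A * (1 + delta), area_floor))
    }
    af
  }
  # the controlling constriction: deepest interior local minimum of the area
  # profile (the boundary taper at the glottal end is not an articulator)
  find_dip <- function(A) {
    n <- length(A)
    i <- 2:(n - 1)
    loc <- i[A[i] <= A[i - 1] & A[i] <= A[i + 1]]
    if (!length(loc)) which.min(A) else loc[which.min(A[loc])]
  }
  for (k in seq_len(max_tighten)) {
    imin <- find_dip(af$A)
    if (af$A[imin] <= 1.05 * area_floor) break
    dip <- which(af$A < 2 * af$A[imin] & abs(seq_along(af$A) - imin) <= 4)
    af$A[dip] <- pmax(af$A[dip] * dip_step, area_floor)
    af <- recenter(af)
  }
  recenter(af)
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> target %.0f Hz: %s after %d iterations (%s)\n",
              x$target_hz,
              if (x$converged) "converged" else "did not converge",
              x$iterations, x$reason))
  invisible(x)
}

#' Locate a formant frequency to sub-grid precision
#'
#' Maximizes the continuous transfer-function magnitude near a given
#' frequency by golden-section search. Useful when formant shifts far below
#' the frequency-grid resolution must be resolved, e.g. when validating
#' sensitivity functions against direct recomputation of the response.
#'
#' @param af A uniform-grid [area_function()].
#' @param const [acoustic_constants()].
#' @param near_hz Frequency near the formant (Hz), e.g. from
#'   [pick_formants()].
#' @param radius_hz Half-width of the search bracket (Hz).
#' @return The refined formant frequency (Hz).
#' @export
refine_formant <- function(af, const, near_hz, radius_hz = 60) {
  stats::optimize(function(f) -Mod(tract_transfer(af, const, 2 * pi * f)),
                  c(near_hz - radius_hz, near_hz + radius_hz),
                  tol = 1e-4)$minimum
}

#' Write a frequency response as CSV (columns freq_hz, gain_db)
#' @param fr A [frequency_response()].
#' @param path File path.
#' @export
write_response_csv <- function(fr, path) {
  stopifnot(inherits(fr, "frequency_response"))
  utils::write.csv(data.frame(freq_hz = fr$freq, gain_db = fr$gain_db), path,
                   row.names = FALSE)
  invisible(path)
}
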