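#' Short-time Fourier spectrogram
#'
#' STFT magnitude in dB relative to the global maximum, with a -120 dB
#' floor. The defaults follow the analysis settings used for the study's
#' recordings: a 4096-sample Hamming window at 96 kHz (~43 ms) with 95%
#' fractional overlap; at other sample rates the window defaults to the
#' power of two closest to the same ~43 ms span. The hop is
#' `floor(0.05 * window)` samples (204 for a 4096 window).
#'
#' @param audio An [audio_clip()].
#' @param window_samples Window length in samples; `NULL` picks the power of
#'   two nearest `0.0427 * fs`.
#' @param overlap Fractional overlap in `[0, 1)`; default 0.95.
#' @param window_type `"hamming"` (default) or `"hann"`.
#' @param floor_db Magnitude floor (dB re max).
#' @return Object of class `spectrogram`: `times` (frame centers, s),
#'   `freqs` (bin centers, Hz), `mag_db` (freq x time matrix, <= 0), and
#'   `params`.
#' @export
compute_spectrogram <- function(audio, window_samples = NULL, overlap = 0.95,
                                window_type = c("hamming", "hann"),
                                floor_db = -120) {
  stopifnot(inherits(audio, "audio_clip"))
  window_type <- match.arg(window_type)
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  fs <- audio$fs
  x <- audio$samples
  if (is.null(window_samples))
    window_samples <- 2^round(log2(0.0427 * fs))
  nwin <- as.integer(window_samples)
  if (nwin > length(x)) stop("window longer than the signal")
  hop <- max(1L, as.integer(floor((1 - overlap) * nwin)))
  i <- seq_len(nwin)
  win <- if (window_type == "hamming")
    0.54 - 0.46 * cos(2 * pi * (i - 1) / (nwin - 1))
  else
    0.5 - 0.5 * cos(2 * pi * (i - 1) / (nwin - 1))
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + nwin - 1)] * win,
                   numeric(nwin))
  spec <- stats::mvfft(frames)
  nb <- nwin %/% 2 + 1
  mag <- Mod(spec[seq_len(nb), , drop = FALSE])
  mx <- max(mag)
  if (mx <= 0) {
    mag_db <- matrix(floor_db, nrow = nb, ncol = length(starts))
  } else {
    mag_db <- pmax(20 * log10(pmax(mag / mx, 1e-300)), floor_db)
  }
  structure(list(
    times = (starts - 1 + nwin / 2) / fs,
    freqs = (seq_len(nb) - 1) * fs / nwin,
    mag_db = mag_db,
    params = list(window_samples = nwin, overlap = overlap,
                  window_type = window_type, fs = fs, hop = hop,
                  floor_db = floor_db, silent = mx <= 0)),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, %.1f s, df = %.2f Hz, hop = %d samples\n",
              ncol(x$mag_db), nrow(x$mag_db), max(x$times),
              x$freqs[2] - x$freqs[1], x$params$hop))
  invisible(x)
}

# quadratic interpolation of a spectral peak on a uniform frequency grid;
# returns the refined frequency and level (removes the scalloping loss of
# reading levels at bin centers)
interp_peak <- function(freqs, mag_db, p) {
  if (p <= 1 || p >= length(mag_db)) return(c(freqs[p], mag_db[p]))
  a <- mag_db[p - 1]; b <- mag_db[p]; cc <- mag_db[p + 1]
  den <- a - 2 * b + cc
  if (abs(den) < 1e-12) return(c(freqs[p], b))
  d <- max(min(0.5 * (a - cc) / den, 0.5), -0.5)
  c(freqs[p] + d * (freqs[2] - freqs[1]), b - 0.25 * (a - cc) * d)
}

interp_peak_freq <- function(freqs, mag_db, p) interp_peak(freqs, mag_db, p)[1]

#' Estimate the fundamental frequency from one spectral frame
#'
#' The strongest spectral peak below `max_f0` (default 500 Hz), refined by
#' quadratic interpolation around the bin. Returns `NA` (undefined f0) if
#' no peak rises above the noise criterion.
#'
#' @param freqs Bin frequencies (Hz).
#' @param mag_db Frame magnitudes (dB re max).
#' @param max_f0 Upper bound of the f0 search (Hz).
#' @param min_level_db Minimum level (dB re clip max) for a valid f0 peak.
#' @return f0 estimate in Hz, or `NA_real_`.
#' @export
estimate_f0 <- function(freqs, mag_db, max_f0 = 500, min_level_db = -60) {
  sel <- which(freqs <= max_f0)
  if (length(sel) < 3) return(NA_real_)
  y <- mag_db[sel]
  p <- local_peaks(y)
  p <- p[y[p] >= min_level_db]
  if (!length(p)) return(NA_real_)
  p <- p[which.max(y[p])]
  interp_peak_freq(freqs[sel], y, p)
}

#' Pick the harmonic ladder in one spectral frame
#'
#' For each harmonic number `k = 1..n_max`, the strongest local peak within
#' `+/- f0/2` of `k * f0` is returned with its level; harmonics without a
#' local peak in their search band are flagged missing.
#'
#' @param freqs,mag_db Frame spectrum.
#' @param f0 Fundamental (Hz), e.g. from [estimate_f0()].
#' @param n_max Number of harmonics to search.
#' @return Data frame with columns `k`, `freq_hz`, `level_db`, `missing`.
#' @export
pick_harmonics <- function(freqs, mag_db, f0, n_max = 40) {
  if (is.na(f0) || f0 <= 0) stop("f0 undefined")
  out <- data.frame(k = seq_len(n_max), freq_hz = NA_real_,
                    level_db = NA_real_, missing = TRUE)
  for (k in seq_len(n_max)) {
    sel <- which(freqs >= (k - 0.5) * f0 & freqs <= (k + 0.5) * f0)
    if (length(sel) < 3) next
    y <- mag_db[sel]
    p <- local_peaks(y)
    if (!length(p)) next
    p <- p[which.max(y[p])]
    pk <- interp_peak(freqs[sel], y, p)
    out$freq_hz[k] <- pk[1]
    out$level_db[k] <- pk[2]
    out$missing[k] <- FALSE
  }
  out
}

#' Estimate the spectral-envelope trend and its peaks ("formants")
#'
#' The harmonic-peak levels are resampled onto a grid upsampled by
#' `upsample_factor` (default 10) with a lowpass interpolating FIR filter
#' ([signal::interp()]); peaks of the interpolated envelope are returned as
#' formant estimates. Frames with fewer than 4 usable harmonic points are
#' skipped (returns `NULL`).
#'
#' @param freqs,mag_db Frame spectrum.
#' @param f0 Fundamental (Hz).
#' @param upsample_factor Envelope upsampling factor.
#' @param n_max Harmonics considered.
#' @return `NULL`, or a list with `envelope` (data frame `freq_hz`,
#'   `level_db`) and `formants` (data frame `freq_hz`, `level_db`).
#' @export
estimate_formant_trend <- function(freqs, mag_db, f0, upsample_factor = 10,
                                   n_max = 40) {
  h <- pick_harmonics(freqs, mag_db, f0, n_max = n_max)
  h <- h[!h$missing, ]
  if (nrow(h) < 4) return(NULL)
  # uniform in harmonic number; band-limited upsampling of the level series
  lev <- h$level_db
  env <- signal::interp(lev, upsample_factor)
  env <- env[seq_len((nrow(h) - 1) * upsample_factor + 1)]
  fgrid <- h$freq_hz[1] +
    (seq_along(env) - 1) / upsample_factor * f0
  p <- local_peaks(env)
  if (length(p)) {
    prom <- vapply(p, function(i) peak_prominence(env, i), numeric(1))
    p <- p[prom >= 1]
  }
  list(envelope = data.frame(freq_hz = fgrid, level_db = env),
       formants = data.frame(freq_hz = fgrid[p], level_db = env[p]))
}

#' Band energy ratio of one spectral frame
#'
#' The focus statistic: spectral magnitude is converted to linear ordinate,
#' integrated over the band `[fL, fH]` and over the full range
#' `[0, fmax]`, and the ratio of the two integrals is squared:
#' `eR = (int_fL^fH P df / int_0^fmax P df)^2`, a dimensionless value in
#' `[0, 1]`. The alternative `"power"` variant squares the magnitude before
#' integrating (ratio of band power to total power, not squared again);
#' both are bounded in `[0, 1]`.
#'
#' @param freqs,mag_db Frame spectrum (dB re max).
#' @param fL,fH Band limits (Hz), `0 <= fL < fH <= fmax`.
#' @param fmax Full-range upper limit (Hz); ~8 kHz spans the energy of
#'   vocal output.
#' @param variant `"magnitude"` (integrate magnitude, square the ratio; the
#'   default) or `"power"`.
#' @return eR in `[0, 1]`, or `NA_real_` when the frame has no energy.
#' @export
energy_ratio <- function(freqs, mag_db, fL = 1000, fH = 2000, fmax = 8000,
                         variant = c("magnitude", "power")) {
  variant <- match.arg(variant)
  if (!(fL >= 0 && fL < fH && fH <= fmax)) stop("need 0 <= fL < fH <= fmax")
  P <- 10^(mag_db / 20)
  if (variant == "power") P <- P^2
  full <- freqs <= fmax
  band <- freqs >= fL & freqs <= fH
  tot <- sum(P[full])
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  r <- sum(P[band & full]) / tot
  if (variant == "magnitude") r^2 else r
}

#' Focus trace: eR over time
#'
#' Applies [energy_ratio()] to every spectrogram frame. If the requested
#' `fmax` exceeds Nyquist it is clipped with a warning. Frames of a silent
#' clip are undefined (`NA`).
#'
#' @param spec A [spectrogram()][compute_spectrogram].
#' @param fL,fH Band limits (Hz); default 1-2 kHz.
#' @param fmax Full-range limit (Hz); default 8 kHz.
#' @param variant Passed to [energy_ratio()].
#' @return Object of class `focus_trace`: `times`, `eR`, `band`, `fmax`.
#' @export
focus_trace <- function(spec, fL = 1000, fH = 2000, fmax = 8000,
                        variant = "magnitude") {
  stopifnot(inherits(spec, "spectrogram"))
  nyq <- spec$params$fs / 2
  if (fmax > nyq) {
    warning("fmax clipped to Nyquist")
    fmax <- nyq
  }
  eR <- if (isTRUE(spec$params$silent)) {
    rep(NA_real_, ncol(spec$mag_db))
  } else {
    apply(spec$mag_db, 2, function(m)
      energy_ratio(spec$freqs, m, fL, fH, fmax, variant))
  }
  structure(list(times = spec$times, eR = eR, band = c(fL, fH), fmax = fmax),
            class = "focus_trace")
}

#' @export
print.focus_trace <- function(x, ...) {
  cat(sprintf("<focus_trace> %d frames, band [%.0f, %.0f] Hz, median eR = %.3f\n",
              length(x$eR), x$band[1], x$band[2],
              stats::median(x$eR, na.rm = TRUE)))
  invisible(x)
}

#' Detect transitions into / out of the focused state
#'
#' Schmitt-trigger detection on a focus trace: the state switches on when
#' eR rises to `threshold` and off when it falls below
#' `threshold - hysteresis`; on-periods shorter than `min_hold` are
#' discarded as chatter.
#'
#' @param trace A [focus_trace()].
#' @param threshold Entry threshold on eR.
#' @param hysteresis Hysteresis width.
#' @param min_hold Minimum duration (s) of a focused period.
#' @return Data frame with columns `entry` and `exit` (s); `exit` is `NA`
#'   when the clip ends in the focused state.
#' @export
detect_transitions <- function(trace, threshold = 0.35, hysteresis = 0.1,
                               min_hold = 0.1) {
  stopifnot(inherits(trace, "focus_trace"))
  eR <- trace$eR
  t <- trace$times
  if (!length(eR)) stop("empty focus trace")
  on <- FALSE
  entries <- numeric(0); exits <- numeric(0)
  for (i in seq_along(eR)) {
    v <- eR[i]
    if (is.na(v)) next
    if (!on && v >= threshold) {
      on <- TRUE
      entries <- c(entries, t[i])
    } else if (on && v < threshold - hysteresis) {
      on <- FALSE
      exits <- c(exits, t[i])
    }
  }
  if (length(exits) < length(entries)) exits <- c(exits, NA_real_)
  keep <- is.na(exits) | (exits - entries >= min_hold)
  data.frame(entry = entries[keep], exit = exits[keep])
}

#' Write a focus trace as CSV (columns time_s, eR)
#' @param trace A [focus_trace()].
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "focus_trace"))
  utils::write.csv(data.frame(time_s = trace$times, eR = trace$eR), path,
                   row.names = FALSE)
  invisible(path)
}
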