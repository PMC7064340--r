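#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats used for voice recordings:
#' PCM 16/24/32-bit integer and IEEE float 32/64-bit, mono or stereo
#' (stereo is averaged to mono with a warning). Samples are normalized to
#' `[-1, 1]`.
#'
#' @param path File path.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("I/O error: not a RIFF file: ", path)
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("I/O error: not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (id == "fmt ") {
      fmt_raw <- readBin(con, raw(), sz)
      u16 <- function(off) sum(as.integer(fmt_raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(fmt_raw[off + 1:4]) * 256^(0:3))
      fmt <- list(code = u16(0), channels = u16(2), fs = u32(4),
                  bits = u16(14))
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), sz)
    } else {
      invisible(readBin(con, raw(), sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("I/O error: missing fmt/data chunk in ", path)
  code <- fmt$code
  if (code == 65534 && fmt$bits %in% c(32, 64)) code <- 3  # extensible float
  x <- if (code == 1 && fmt$bits == 16) {
    readBin(data_raw, integer(), length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (code == 1 && fmt$bits == 24) {
    n <- length(data_raw) / 3
    b <- matrix(as.integer(data_raw), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v[v >= 2^23] <- v[v >= 2^23] - 2^24
    v / 2^23
  } else if (code == 1 && fmt$bits == 32) {
    readBin(data_raw, integer(), length(data_raw) / 4, 4, endian = "little") / 2^31
  } else if (code == 3 && fmt$bits == 32) {
    readBin(data_raw, numeric(), length(data_raw) / 4, 4, endian = "little")
  } else if (code == 3 && fmt$bits == 64) {
    readBin(data_raw, numeric(), length(data_raw) / 8, 8, endian = "little")
  } else {
    stop("I/O error: unsupported WAV format (code ", fmt$code, ", ",
         fmt$bits, " bits)")
  }
  if (fmt$channels == 2) {
    warning("stereo averaged to mono")
    x <- (x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]) / 2
  } else if (fmt$channels != 1) {
    stop("I/O error: unsupported channel count ", fmt$channels)
  }
  m <- max(abs(x), 1e-12)
  if (m > 1) x <- x / m
  audio_clip(x, fmt$fs)
}

#' Write a WAV file
#'
#' @param clip An [audio_clip()].
#' @param path File path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bits = 16) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(clip$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(if (bits == 16) 1 else 3); w16(1)
  w32(clip$fs); w32(clip$fs * bytes_per); w16(bytes_per); w16(bits)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bits == 16) {
    writeBin(as.integer(round(pmax(pmin(clip$samples, 1), -1) * 32767)),
             con, 2, endian = "little")
  } else {
    writeBin(clip$samples, con, 4, endian = "little")
  }
  invisible(path)
}

run_config_defaults <- function() {
  list(
    c = 35000, rho = 1.14e-3,
    wall_resistance = 1600, wall_mass = 1.5, wall_compliance = 3e5,
    include_walls = TRUE, include_viscous_thermal = TRUE,
    include_radiation = TRUE,
    stft_window = NULL, stft_overlap = 0.95, stft_window_type = "hamming",
    er_band = c(1000, 2000), er_fmax = 8000, er_variant = "magnitude",
    focus_step = 0.1, focus_max_iter = 200, focus_area_floor = 0.05,
    focus_tol = 0.01,
    fs = 44100, seed = 1
  )
}

#' Assemble and validate a run configuration
#'
#' Collects the knobs shared across pipeline stages (acoustic constants,
#' STFT parameters, eR band and variant, perturbation options, sample rate,
#' seed). Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param ... Named overrides of the defaults, or a single named list.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- run_config_defaults()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$c > 0, cfg$rho > 0,
            cfg$stft_overlap >= 0, cfg$stft_overlap < 1,
            cfg$er_band[1] >= 0, cfg$er_band[1] < cfg$er_band[2],
            cfg$er_band[2] <= cfg$er_fmax,
            cfg$er_variant %in% c("magnitude", "power"),
            cfg$focus_step > 0, cfg$focus_max_iter >= 1,
            cfg$focus_area_floor > 0, cfg$focus_tol > 0,
            cfg$fs > 0)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %s: %s\n", k,
                if (is.null(v)) "auto" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' @rdname run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

#' Acoustic constants from a run configuration
#' @param cfg A [run_config()].
#' @export
config_constants <- function(cfg) {
  acoustic_constants(c = cfg$c, rho = cfg$rho,
                     wall_resistance = cfg$wall_resistance,
                     wall_mass = cfg$wall_mass,
                     wall_compliance = cfg$wall_compliance,
                     include_walls = cfg$include_walls,
                     include_viscous_thermal = cfg$include_viscous_thermal,
                     include_radiation = cfg$include_radiation)
}
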