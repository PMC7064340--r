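#' Vocal-tract area function
#'
#' An area function describes the vocal tract as a one-dimensional tube:
#' cross-sectional area `A` (cm^2) sampled at positions `x` (cm from the
#' glottis). It is the central object of the package: the transmission-line
#' model, the formant-merging perturbation and the synthesizer all operate on
#' area functions.
#'
#' @param x Numeric vector of sample positions (cm), strictly increasing,
#'   starting at 0 (the glottis). The last position equals the tract length.
#' @param A Numeric vector of cross-sectional areas (cm^2), same length as
#'   `x`, all strictly positive.
#' @return An object of class `area_function` with fields `x`, `A` and `L`
#'   (total length, `max(x)`).
#' @seealso [resample_area_function()], [cross_distance_to_area()],
#'   [compute_frequency_response()]
#' @export
area_function <- function(x, A) {
  x <- as.numeric(x)
  A <- as.numeric(A)
  if (length(x) != length(A))
    stop("`x` and `A` must have the same length")
  if (length(x) < 2)
    stop("an area function needs at least 2 samples")
  if (!all(is.finite(x)) || !all(is.finite(A)))
    stop("`x` and `A` must be finite")
  if (any(diff(x) <= 0))
    stop("`x` must be strictly increasing")
  if (any(A <= 0))
    stop("all areas must be positive (closed tract)")
  structure(list(x = x, A = A, L = max(x)), class = "area_function")
}

#' @export
print.area_function <- function(x, ...) {
  cat(sprintf("<area_function> %d sections, L = %.2f cm, A in [%.3g, %.3g] cm^2\n",
              length(x$x), x$L, min(x$A), max(x$A)))
  invisible(x)
}

#' Check whether an area function is sampled on a uniform grid
#'
#' The transmission-line model requires equal-length tube sections; this
#' predicate is its precondition.
#'
#' @param af An [area_function()].
#' @param tol Relative tolerance on spacing variation.
#' @return Logical scalar.
#' @export
is_uniform_area_function <- function(af, tol = 1e-6) {
  dx <- diff(af$x)
  diff(range(dx)) <= tol * mean(dx)
}

#' Resample an area function onto equal-length sections
#'
#' Areas are interpolated piecewise-linearly in `A` versus `x`; the endpoints
#' (glottis and lips) are preserved exactly.
#'
#' @param af An [area_function()].
#' @param n_sections Number of equally spaced sample points covering
#'   `[0, L]` (>= 2).
#' @return An [area_function()] on the uniform grid.
#' @export
resample_area_function <- function(af, n_sections) {
  stopifnot(inherits(af, "area_function"))
  if (!is.numeric(n_sections) || length(n_sections) != 1 || n_sections < 2)
    stop("`n_sections` must be a single integer >= 2")
  x_new <- seq(min(af$x), af$L, length.out = n_sections)
  A_new <- stats::approx(af$x, af$A, xout = x_new, rule = 2)$y
  area_function(x_new, A_new)
}

#' Interpolate between two area functions
#'
#' Section-wise geometric interpolation, `A = A_a^(1 - w) * A_b^w`, which
#' keeps areas positive for any `w` in `[0, 1]`. Used by the dynamic
#' synthesizer to morph between a normal and a focused tract.
#'
#' @param af_a,af_b [area_function()] objects on the same grid.
#' @param w Interpolation weight in `[0, 1]`; 0 returns `af_a`, 1 `af_b`.
#' @return An [area_function()].
#' @export
interpolate_area_functions <- function(af_a, af_b, w) {
  stopifnot(inherits(af_a, "area_function"), inherits(af_b, "area_function"))
  if (length(af_a$x) != length(af_b$x) ||
      max(abs(af_a$x - af_b$x)) > 1e-8 * af_a$L)
    stop("area functions must share the same section grid")
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1)
    stop("`w` must be a single number in [0, 1]")
  area_function(af_a$x, af_a$A^(1 - w) * af_b$A^w)
}

#' Read / write area-function CSV files
#'
#' The on-disk format is a headered CSV with columns `x_cm` and `A_cm2`,
#' one row per section.
#'
#' @param path File path.
#' @return `read_area_csv` returns an [area_function()];
#'   `write_area_csv` returns `path` invisibly.
#' @export
read_area_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_cm", "A_cm2") %in% names(d)))
    stop("area CSV must have columns x_cm, A_cm2: ", path)
  area_function(d$x_cm, d$A_cm2)
}

#' @rdname read_area_csv
#' @param af An [area_function()].
#' @export
write_area_csv <- function(af, path) {
  stopifnot(inherits(af, "area_function"))
  utils::write.csv(data.frame(x_cm = af$x, A_cm2 = af$A), path,
                   row.names = FALSE)
  invisible(path)
}
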