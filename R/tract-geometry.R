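#' Traced midsagittal vocal-tract profile
#'
#' Holds the two manually traced contours of a midsagittal tract image: the
#' inner profile (tongue/epiglottis side) and the outer profile (palate/rear
#' pharyngeal wall side), both ordered glottis-first, in cm.
#'
#' @param inner,outer Two-column numeric matrices (x, y in cm), >= 3 points
#'   each, ordered from the glottis end to the lip end.
#' @param check_intersection If `TRUE` (default), raise a geometry error when
#'   the two contours cross each other.
#' @return An object of class `sagittal_profile`.
#' @export
sagittal_profile <- function(inner, outer, check_intersection = TRUE) {
  inner <- as_contour(inner, "inner")
  outer <- as_contour(outer, "outer")
  if (check_intersection && polylines_intersect(inner, outer))
    stop("geometry error: inner and outer contours intersect")
  structure(list(inner = inner, outer = outer), class = "sagittal_profile")
}

as_contour <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 2 || nrow(m) < 3)
    stop(sprintf("%s contour must be an n x 2 matrix with n >= 3", what))
  storage.mode(m) <- "double"
  if (!all(is.finite(m)))
    stop(sprintf("%s contour has non-finite coordinates", what))
  unname(m)
}

#' @export
print.sagittal_profile <- function(x, ...) {
  cat(sprintf("<sagittal_profile> inner: %d pts, outer: %d pts\n",
              nrow(x$inner), nrow(x$outer)))
  invisible(x)
}

# segment-segment intersection test for two polylines (proper crossings)
polylines_intersect <- function(P, Q) {
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(nrow(P) - 1)) {
    p1 <- P[i, ]; p2 <- P[i + 1, ]
    r <- p2 - p1
    for (j in seq_len(nrow(Q) - 1)) {
      q1 <- Q[j, ]; q2 <- Q[j + 1, ]
      s <- q2 - q1
      denom <- cross2(r[1], r[2], s[1], s[2])
      if (abs(denom) < 1e-14) next
      t <- cross2(q1[1] - p1[1], q1[2] - p1[2], s[1], s[2]) / denom
      u <- cross2(q1[1] - p1[1], q1[2] - p1[2], r[1], r[2]) / denom
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9)
        return(TRUE)
    }
  }
  FALSE
}

# distance from point p to a polyline (with projection onto segments)
dist_to_polyline <- function(p, P) {
  seg <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  len2 <- rowSums(seg^2)
  dx <- p[1] - P[-nrow(P), 1]
  dy <- p[2] - P[-nrow(P), 2]
  t <- (dx * seg[, 1] + dy * seg[, 2]) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  ex <- dx - t * seg[, 1]
  ey <- dy - t * seg[, 2]
  sqrt(min(ex^2 + ey^2))
}

#' Cross-section series along the tract centerline
#'
#' Stores the extracted centerline, the arc-length coordinate `x` from the
#' glottis, and the cross-distance function `D(x)` (perpendicular
#' inner-to-outer distance at each centerline point).
#'
#' @param centerline n x 2 matrix of centerline points (cm).
#' @param x Arc length from the glottis (cm), strictly increasing, `x[1] = 0`.
#' @param D Cross-distances (cm), all positive.
#' @param low_confidence Optional logical vector flagging end points where the
#'   perpendicular construction is ill-defined.
#' @return An object of class `cross_section_series`.
#' @export
cross_section_series <- function(centerline, x, D, low_confidence = NULL) {
  centerline <- as.matrix(centerline)
  x <- as.numeric(x); D <- as.numeric(D)
  if (nrow(centerline) != length(x) || length(x) != length(D))
    stop("centerline, x and D must have matching lengths")
  if (abs(x[1]) > 1e-9) stop("x must start at 0 (glottis)")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (any(D <= 0)) stop("all cross-distances must be positive")
  if (is.null(low_confidence)) low_confidence <- rep(FALSE, length(x))
  structure(list(centerline = centerline, x = x, D = D,
                 low_confidence = low_confidence),
            class = "cross_section_series")
}

#' @export
print.cross_section_series <- function(x, ...) {
  cat(sprintf("<cross_section_series> %d points, length %.2f cm, D in [%.2f, %.2f] cm\n",
              length(x$x), max(x$x), min(x$D), max(x$D)))
  invisible(x)
}

#' Extract the tract centerline and cross-distance function
#'
#' Iterative bisection: starting from the midpoint of the glottis-end segment,
#' the centerline advances in fixed arc steps; at each step the provisional
#' point (one step along the current tangent) is corrected along the local
#' normal until it is equidistant from the inner and outer contours. The
#' cross-distance `D` at each centerline point is the sum of the distances to
#' the two contours, i.e. the tract width along the local perpendicular.
#'
#' The first and last 0.5 cm are flagged low-confidence: near the ends the
#' perpendicular does not cleanly hit both contours and distances there are
#' dominated by the contour end segments.
#'
#' @param profile A [sagittal_profile()], glottis-first.
#' @param step Arc-length step between centerline points (cm).
#' @param end_margin Length (cm) at each end flagged low-confidence.
#' @return A [cross_section_series()].
#' @export
extract_centerline <- function(profile, step = 0.25, end_margin = 0.5) {
  stopifnot(inherits(profile, "sagittal_profile"))
  if (polylines_intersect(profile$inner, profile$outer))
    stop("geometry error: inner and outer contours intersect")
  Pin <- profile$inner; Pout <- profile$outer

  g <- (Pin[1, ] + Pout[1, ]) / 2                   # glottis-end midpoint
  lip_mid <- (Pin[nrow(Pin), ] + Pout[nrow(Pout), ]) / 2

  # initial tangent: perpendicular to the glottis end segment, oriented
  # toward the interior (i.e. toward the lip end of the tract)
  v <- Pout[1, ] - Pin[1, ]
  tangent <- c(-v[2], v[1])
  tangent <- tangent / sqrt(sum(tangent^2))
  if (sum((g + step * tangent - lip_mid)^2) > sum((g - step * tangent - lip_mid)^2))
    tangent <- -tangent

  balance <- function(p, n_hat, half_width) {
    # move p along n_hat so that dist(inner) == dist(outer)
    f <- function(s) {
      q <- p + s * n_hat
      dist_to_polyline(q, Pin) - dist_to_polyline(q, Pout)
    }
    smax <- max(half_width, step)
    lo <- -smax; hi <- smax
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0) {
      s <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
    } else {
      s <- stats::optimize(function(s) abs(f(s)), c(lo, hi))$minimum
    }
    p + s * n_hat
  }

  pts <- matrix(g, ncol = 2)
  D <- dist_to_polyline(g, Pin) + dist_to_polyline(g, Pout)
  max_steps <- ceiling(4 * (sum(sqrt(rowSums(diff(Pin)^2))) / step)) + 10
  p <- g
  for (i in seq_len(max_steps)) {
    n_hat <- c(-tangent[2], tangent[1])
    half_width <- dist_to_polyline(p, Pin)
    q <- balance(p + step * tangent, n_hat, half_width)
    new_tan <- q - p
    nt <- sqrt(sum(new_tan^2))
    if (nt < 1e-9) break
    new_tan <- new_tan / nt
    # stop at the lip end: provisional point passes the mouth opening
    if (sum((q - lip_mid)^2) <= step^2) {
      pts <- rbind(pts, q)
      D <- c(D, dist_to_polyline(q, Pin) + dist_to_polyline(q, Pout))
      break
    }
    # guard against reversing direction (end of contours reached)
    if (sum(new_tan * tangent) < 0) break
    pts <- rbind(pts, q)
    D <- c(D, dist_to_polyline(q, Pin) + dist_to_polyline(q, Pout))
    tangent <- new_tan
    p <- q
  }
  if (nrow(pts) < 3)
    warning("centerline extraction terminated early; profile ends trimmed")
  x <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  ok <- D > 0
  if (!all(ok)) {
    warning("non-positive cross-distances near the ends were trimmed")
    pts <- pts[ok, , drop = FALSE]; x <- x[ok] - min(x[ok]); D <- D[ok]
  }
  lc <- x < end_margin | x > max(x) - end_margin
  cross_section_series(pts, x, D, low_confidence = lc)
}

#' Convert a cross-distance function to an area function
#'
#' Applies the power law `A(x) = k * D(x)^alpha`. With the circular
#' cross-section approximation the cross-distances are diameters, giving
#' `k = pi/4` and `alpha = 2` (the defaults). Other published (k, alpha)
#' pairs exist for non-circular tract shapes; none is universally agreed, so
#' only the parameters are exposed.
#'
#' @param series A [cross_section_series()].
#' @param k Scale factor (> 0). Default `pi/4`.
#' @param alpha Exponent. Default 2.
#' @return An [area_function()] on the same `x` grid.
#' @export
cross_distance_to_area <- function(series, k = pi / 4, alpha = 2) {
  stopifnot(inherits(series, "cross_section_series"))
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  if (any(series$D <= 0)) stop("closed tract: non-positive cross-distance")
  area_function(series$x, k * series$D^alpha)
}

#' Read / write traced-profile CSV files
#'
#' Format: columns `contour` ("inner" or "outer"), `index`, `x_cm`, `y_cm`.
#'
#' @param path File path.
#' @return `read_profile_csv` returns a [sagittal_profile()].
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("contour", "index", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stop("profile CSV must have columns contour, index, x_cm, y_cm: ", path)
  grab <- function(which) {
    di <- d[d$contour == which, ]
    di <- di[order(di$index), ]
    cbind(di$x_cm, di$y_cm)
  }
  sagittal_profile(grab("inner"), grab("outer"))
}

#' @rdname read_profile_csv
#' @param profile A [sagittal_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "sagittal_profile"))
  d <- rbind(
    data.frame(contour = "inner", index = seq_len(nrow(profile$inner)),
               x_cm = profile$inner[, 1], y_cm = profile$inner[, 2]),
    data.frame(contour = "outer", index = seq_len(nrow(profile$outer)),
               x_cm = profile$outer[, 1], y_cm = profile$outer[, 2]))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a cross-distance series as CSV (columns x_cm, D_cm)
#' @param series A [cross_section_series()].
#' @param path File path.
#' @export
write_cross_distance_csv <- function(series, path) {
  stopifnot(inherits(series, "cross_section_series"))
  utils::write.csv(data.frame(x_cm = series$x, D_cm = series$D), path,
                   row.names = FALSE)
  invisible(path)
}
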