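#' Rate-dependent critical-block calibration
#'
#' The likelihood of block at a given wavefront convexity is rate
#' dependent: at shorter activation cycle lengths, block occurs at smaller
#' curvature, i.e. across a wider critical width w of the conducting
#' medium. The calibration is a set of (cycle length, critical width)
#' pairs; the defaults are the three experimentally established points
#' w = 0.6 mm at 200 ms, w = 1.29 mm at 150 ms, and w = 2.64 mm at 117 ms,
#' with the circular-arc angle beta = 90 degrees (a narrow isthmus opening
#' to an expanse).
#'
#' @param points data.frame with numeric columns \code{cl} (ms) and
#'   \code{w} (mm).
#' @param beta angle (degrees) between propagation direction and the taper
#'   of the conducting medium.
#' @return Object of class \code{rate_block_calibration}.
#' @examples
#' cal <- rate_block_calibration()
#' critical_width(cal, 150)  # 1.29
#' @export
rate_block_calibration <- function(points = data.frame(
                                     cl = c(117, 150, 200),
                                     w = c(2.64, 1.29, 0.6)),
                                   beta = 90) {
  if (!is.data.frame(points) || !all(c("cl", "w") %in% names(points)))
    stop("'points' must be a data.frame with columns 'cl' and 'w'")
  points <- points[order(points$cl), c("cl", "w")]
  if (nrow(points) < 2L) stop("at least two calibration points required")
  if (any(!is.finite(points$cl)) || any(points$cl <= 0))
    stop("cycle lengths must be positive")
  if (anyDuplicated(points$cl)) stop("cycle lengths must be distinct")
  if (any(!is.finite(points$w)) || any(points$w <= 0))
    stop("critical widths must be positive")
  if (any(diff(points$w) >= 0))
    stop("critical width must strictly decrease with cycle length ",
         "(shorter cycles block at larger w)")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single angle in degrees")
  structure(list(points = points, beta = beta),
            class = "rate_block_calibration")
}

#' @export
print.rate_block_calibration <- function(x, ...) {
  cat("Rate-dependent block calibration (beta =", x$beta, "deg):\n")
  for (i in seq_len(nrow(x$points)))
    cat(sprintf("  CL %4g ms -> w = %g mm (rho_crit = %.3f mm^-1)\n",
                x$points$cl[i], x$points$w[i],
                rho_from_width(x$points$w[i], x$beta)))
  invisible(x)
}

#' Circular-arc wavefront curvature from a critical width
#'
#' The circular-arc form of the conduction law models the wavefront leading
#' edge as an arc spanning the conducting medium:
#' \deqn{\rho = 2 \sin(\beta) / w}
#' where w is the distance across the medium at the leading edge and beta
#' the angle between the propagation direction and the taper.
#'
#' @param w width across the conducting medium in mm (vectorized).
#' @param beta angle in degrees (default 90, isthmus opening to an expanse).
#' @return Curvature rho in mm^-1.
#' @examples
#' rho_from_width(0.6)   # 3.33 mm^-1
#' rho_from_width(1.29)  # 1.55 mm^-1
#' @export
rho_from_width <- function(w, beta = 90) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    stop("'w' must be positive (mm)")
  2 * sin(beta * pi / 180) / w
}

#' Critical width at a given cycle length
#'
#' Interpolates the calibration to the requested cycle length. At a
#' calibration cycle length the tabulated width is returned exactly;
#' between points, log(w) is interpolated linearly in CL (the calibration
#' triple is close to exponential in CL). Cycle lengths outside the
#' calibration range raise an error unless extrapolation is enabled:
#' \code{"loglinear"} continues the nearest segment's slope, \code{"clamp"}
#' holds the endpoint value.
#'
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @param cycle_length activation interval in ms (vectorized).
#' @param extrapolate one of \code{"error"}, \code{"loglinear"},
#'   \code{"clamp"}.
#' @return Critical width w in mm.
#' @export
critical_width <- function(calibration, cycle_length,
                           extrapolate = c("error", "loglinear", "clamp")) {
  stopifnot(inherits(calibration, "rate_block_calibration"))
  extrapolate <- match.arg(extrapolate)
  if (!is.numeric(cycle_length) || any(!is.finite(cycle_length)) ||
      any(cycle_length <= 0))
    stop("'cycle_length' must be positive (ms)")
  p <- calibration$points
  lo <- min(p$cl); hi <- max(p$cl)
  out_of_range <- cycle_length < lo | cycle_length > hi
  if (any(out_of_range) && extrapolate == "error")
    stop(sprintf("cycle length %g ms outside calibration range [%g, %g] ms",
                 cycle_length[out_of_range][1L], lo, hi))
  cl <- cycle_length
  if (extrapolate == "clamp") cl <- pmin(pmax(cl, lo), hi)
  # piecewise linear in log(w) vs CL; rule = 2 with manual slope extension
  # for loglinear extrapolation
  logw <- stats::approx(p$cl, log(p$w), xout = pmin(pmax(cl, lo), hi),
                        method = "linear", ties = "ordered")$y
  if (extrapolate == "loglinear") {
    n <- nrow(p)
    s_lo <- (log(p$w[2L]) - log(p$w[1L])) / (p$cl[2L] - p$cl[1L])
    s_hi <- (log(p$w[n]) - log(p$w[n - 1L])) / (p$cl[n] - p$cl[n - 1L])
    below <- cl < lo; above <- cl > hi
    logw[below] <- log(p$w[1L]) + s_lo * (cl[below] - lo)
    logw[above] <- log(p$w[n]) + s_hi * (cl[above] - hi)
  }
  exp(logw)
}

#' Critical space step for block at a given rate
#'
#' The largest spatial interval c over which a thin-to-thick transition of
#' relative size \eqn{\Delta T / T} still produces block at the given cycle
#' length: \eqn{c = (\Delta T / T) / \rho_{crit}(CL)}, where
#' \eqn{\rho_{crit}} is the circular-arc curvature at the calibrated
#' critical width. A transition completed over a distance no larger than
#' this c yields critically convex curvature and halts the wavefront.
#'
#' @param ratio relative thickness change (unitless), positive.
#' @param cycle_length activation interval in ms.
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @param extrapolate passed to \code{\link{critical_width}}.
#' @return Critical space step c in mm.
#' @examples
#' cal <- rate_block_calibration()
#' critical_space_step(5.23, 200, cal)  # ~1.6 mm
#' critical_space_step(5.23, 117, cal)  # ~6.9 mm
#' @export
critical_space_step <- function(ratio, cycle_length,
                                calibration = rate_block_calibration(),
                                extrapolate = "error") {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("'ratio' must be positive")
  w <- critical_width(calibration, cycle_length, extrapolate = extrapolate)
  ratio / rho_from_width(w, calibration$beta)
}

#' Will a thickness transition block at a given rate?
#'
#' TRUE when a thin-to-thick transition of relative size \code{ratio},
#' completed over \code{transition_length} mm, produces critically convex
#' curvature at the given cycle length - i.e. when the local curvature
#' \code{ratio / transition_length} reaches the calibrated critical
#' curvature, equivalently when \code{transition_length} is no larger than
#' the critical space step. A flat medium (\code{ratio <= 0}) never blocks.
#'
#' @param ratio relative thickness change (unitless, vectorized).
#' @param transition_length distance over which the transition occurs (mm).
#' @param cycle_length activation interval in ms.
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @param extrapolate passed to \code{\link{critical_width}}.
#' @return Logical.
#' @examples
#' cal <- rate_block_calibration()
#' will_block(5.23, 2, 200, cal)  # FALSE: 2 mm > 1.6 mm
#' will_block(5.23, 2, 150, cal)  # TRUE:  2 mm <= 3.4 mm
#' @export
will_block <- function(ratio, transition_length, cycle_length,
                       calibration = rate_block_calibration(),
                       extrapolate = "error") {
  if (!is.numeric(transition_length) || any(!is.finite(transition_length)) ||
      any(transition_length <= 0))
    stop("'transition_length' must be positive (mm)")
  n <- max(length(ratio), length(transition_length))
  ratio <- rep_len(ratio, n)
  transition_length <- rep_len(transition_length, n)
  out <- rep(FALSE, n)
  pos <- is.finite(ratio) & ratio > 0
  if (any(pos))
    out[pos] <- transition_length[pos] <=
      critical_space_step(ratio[pos], cycle_length, calibration,
                          extrapolate = extrapolate)
  out
}
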