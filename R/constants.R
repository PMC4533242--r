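#' Model constants for curvature-modified conduction
#'
#' Bundles the three constants of the thickness-curvature conduction model:
#' the rectilinear (plane-wave) conduction velocity \code{theta_o}, the
#' diffusion coefficient \code{D}, and the space step \code{c} over which
#' spatial thickness changes are sampled.
#'
#' Defaults are the values used throughout the model: 0.4 mm/ms for
#' ventricular myocardium, D = 0.1 mm^2/ms, and a 1 mm space step.
#'
#' @param theta_o rectilinear conduction velocity (mm/ms).
#' @param D diffusion coefficient (mm^2/ms).
#' @param c space step (mm) over which the thickness change is measured.
#' @return An object of class \code{model_constants}.
#' @examples
#' k <- model_constants()
#' critical_ratio(k)  # 4.0
#' @export
model_constants <- function(theta_o = 0.4, D = 0.1, c = 1) {
  if (!is.numeric(theta_o) || length(theta_o) != 1L || !is.finite(theta_o) ||
      theta_o <= 0)
    stop("'theta_o' must be a single positive number (mm/ms)")
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("'D' must be a single positive number (mm^2/ms)")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single positive number (mm)")
  structure(list(theta_o = theta_o, D = D, c = c),
            class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Conduction model constants:\n")
  cat(sprintf("  theta_o = %g mm/ms (rectilinear velocity)\n", x$theta_o))
  cat(sprintf("  D       = %g mm^2/ms (diffusion coefficient)\n", x$D))
  cat(sprintf("  c       = %g mm (space step)\n", x$c))
  cat(sprintf("  critical dT/T = %g\n", critical_ratio(x)))
  invisible(x)
}

#' Conduction velocity of a wavefront crossing a thickness transition
#'
#' The convex-curvature conduction law: a wavefront moving from thinner to
#' thicker border zone over a space step c slows as
#' \deqn{\theta = \theta_o - (D/c) \cdot \Delta T / T}
#' where \eqn{\Delta T / T} is the relative thickness change over c. The
#' returned velocity may be zero or negative; non-positive values are
#' interpreted as conduction block (critically convex curvature).
#'
#' @param constants a \code{\link{model_constants}} object.
#' @param ratio relative thickness change \eqn{\Delta T / T} (unitless);
#'   may be a vector.
#' @return Conduction velocity theta in mm/ms, same length as \code{ratio}.
#' @examples
#' conduction_velocity(model_constants(), 4)     # 0: critical point
#' conduction_velocity(model_constants(), 5.23)  # negative: block
#' @export
conduction_velocity <- function(constants, ratio) {
  stopifnot(inherits(constants, "model_constants"))
  if (!is.numeric(ratio) || any(!is.finite(ratio)))
    stop("'ratio' must be finite numeric")
  constants$theta_o - (constants$D / constants$c) * ratio
}

#' Wavefront curvature implied by a relative thickness change
#'
#' Converts a relative thickness change over a space step into the
#' equivalent wavefront curvature, \eqn{\rho = (1/c) \cdot \Delta T / T}
#' (mm^-1), so that the conduction law can equivalently be written
#' \eqn{\theta = \theta_o - D \rho}.
#'
#' @param ratio relative thickness change (unitless); may be a vector.
#' @param c space step in mm.
#' @return Curvature rho in mm^-1.
#' @examples
#' curvature_rho(5.23, 1)  # 5.23 mm^-1
#' @export
curvature_rho <- function(ratio, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single positive number (mm)")
  ratio / c
}

#' Critical relative thickness change for conduction block
#'
#' The value of \eqn{\Delta T / T} at which the conduction velocity reaches
#' zero: \eqn{\theta_o c / D}. With the default constants this is 4.0 - a
#' thickness step exceeding four times the local thickness over one space
#' step halts the wavefront regardless of rate.
#'
#' @param constants a \code{\link{model_constants}} object.
#' @return The critical unitless ratio.
#' @examples
#' critical_ratio(model_constants())  # 4
#' @export
critical_ratio <- function(constants) {
  stopifnot(inherits(constants, "model_constants"))
  constants$theta_o * constants$c / constants$D
}
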