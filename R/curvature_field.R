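# Bilinear interpolation of a matrix at fractional (row, col) positions
# (1-based, in node units). Returns NA outside the grid or where any of the
# four surrounding nodes is masked out / NA.
.interp_bilinear <- function(values, mask, ri, ci) {
  nr <- nrow(values); nc <- ncol(values)
  # snap to the lattice when a sample lands on a node up to rounding error
  snap_r <- abs(ri - round(ri)) < 1e-9
  snap_c <- abs(ci - round(ci)) < 1e-9
  ri[snap_r] <- round(ri[snap_r])
  ci[snap_c] <- round(ci[snap_c])
  out <- rep(NA_real_, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(ok)) return(out)
  r0 <- pmin(floor(ri[ok]), nr - 1L); c0 <- pmin(floor(ci[ok]), nc - 1L)
  fr <- ri[ok] - r0; fc <- ci[ok] - c0
  idx <- function(r, c) (c - 1L) * nr + r
  v00 <- values[idx(r0, c0)];     v10 <- values[idx(r0 + 1L, c0)]
  v01 <- values[idx(r0, c0 + 1L)]; v11 <- values[idx(r0 + 1L, c0 + 1L)]
  m <- mask[idx(r0, c0)] & mask[idx(r0 + 1L, c0)] &
       mask[idx(r0, c0 + 1L)] & mask[idx(r0 + 1L, c0 + 1L)]
  val <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
         (1 - fr) * fc * v01 + fr * fc * v11
  val[!m] <- NA_real_
  out[ok] <- val
  out
}

#' Maximum directional thickness increase per space step
#'
#' For every viable node, samples the thickness at distance \code{c} along
#' each of \code{n_directions} equally spaced compass bearings (bilinear
#' interpolation off the lattice) and returns the largest thin-to-thick
#' increase, \eqn{\Delta T = \max_d T(x + c d) - T(x)}, clamped below at
#' zero. Thick-to-thin transitions therefore contribute nothing here: the
#' conduction law models convex slowing, and facilitation by concave
#' (thick-to-thin) geometry is handled separately by the wavefront
#' simulator. Bearings whose sample point falls off the grid or on
#' masked-out tissue are skipped.
#'
#' @param map a \code{\link{thickness_map}}.
#' @param c sampling distance in mm; must be at least the grid spacing.
#' @param n_directions number of equally spaced bearings (default 8, the
#'   compass directions).
#' @return Matrix of \eqn{\Delta T} in um (NA at masked-out nodes).
#' @export
delta_T_field <- function(map, c = 1, n_directions = 8L) {
  stopifnot(inherits(map, "thickness_map"))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < map$spacing)
    stop("'c' must be a single number >= the grid spacing")
  n_directions <- as.integer(n_directions)
  if (is.na(n_directions) || n_directions < 4L)
    stop("'n_directions' must be at least 4")
  nr <- nrow(map$values); nc <- ncol(map$values)
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  step <- c / map$spacing  # in node units
  ang <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  dT <- matrix(0, nr, nc)
  for (a in ang) {
    samp <- .interp_bilinear(map$values, map$mask,
                             as.vector(ri) + step * sin(a),
                             as.vector(ci) + step * cos(a))
    d <- matrix(samp, nr, nc) - map$values
    d[is.na(d)] <- 0  # off-grid / masked samples are skipped
    dT <- pmax(dT, d)
  }
  dT[dT < 1e-9 * max(abs(map$values), na.rm = TRUE)] <- 0  # rounding dust
  dT[!map$mask] <- NA_real_
  dT
}

#' Curvature field of a thickness map
#'
#' Computes the per-node fields of the conduction model: the maximum
#' directional thickness increase \code{delta_T} (um), the relative change
#' \code{ratio} = \eqn{\Delta T / T} (unitless), the implied wavefront
#' curvature \code{rho} (mm^-1), the curvature-modified conduction velocity
#' \code{theta} (mm/ms), and the \code{blocked} flag marking nodes where
#' the ratio reaches the critical value (theta <= 0). These are the rasters
#' used to estimate functional block line locations from a thickness map.
#'
#' @param map a \code{\link{thickness_map}}.
#' @param constants a \code{\link{model_constants}}; its \code{c} is the
#'   sampling distance unless \code{c} is given explicitly.
#' @param c sampling distance in mm (default \code{constants$c}).
#' @param n_directions bearings for \code{\link{delta_T_field}}.
#' @return An object of class \code{curvature_field}: list of matrices
#'   \code{delta_T}, \code{ratio}, \code{rho}, \code{theta}, \code{blocked},
#'   plus the inputs used.
#' @examples
#' m <- make_isthmus_map(isthmus_spec(), c(31, 46))
#' cf <- curvature_field(m, model_constants())
#' max(cf$ratio, na.rm = TRUE)
#' @export
curvature_field <- function(map, constants = model_constants(),
                            c = constants$c, n_directions = 8L) {
  stopifnot(inherits(map, "thickness_map"),
            inherits(constants, "model_constants"))
  dT <- delta_T_field(map, c = c, n_directions = n_directions)
  ratio <- dT / map$values
  theta <- constants$theta_o - (constants$D / c) * ratio
  structure(list(delta_T = dT,
                 ratio = ratio,
                 rho = ratio / c,
                 theta = theta,
                 blocked = !is.na(theta) & theta <= 0,
                 c = c, constants = constants),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("Curvature field (%d x %d, c = %g mm)\n",
              nrow(x$ratio), ncol(x$ratio), x$c))
  cat(sprintf("  max dT/T = %.3f, min theta = %.3f mm/ms, %d nodes blocked\n",
              max(x$ratio, na.rm = TRUE), min(x$theta, na.rm = TRUE),
              sum(x$blocked)))
  invisible(x)
}
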