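# 8-neighbor direction offsets (row, col)
.dir_offsets <- function() {
  list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
       c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
}

# For one direction, the thin-to-thick transition profile of every rising
# directed edge u -> u+dir: the relative rise and the length of the maximal
# strictly-increasing thickness run containing the edge, measured along the
# direction. This operationalizes "the distance over which a thickness
# transition occurs": from the local minimum behind the edge to the point
# where the thickness stops rising.
.edge_profile_dir <- function(values, mask, dr, dc, spacing) {
  nr <- nrow(values); nc <- ncol(values)
  steplen <- spacing * sqrt(dr^2 + dc^2)
  RATIO <- matrix(NA_real_, nr, nc)
  RLEN <- matrix(NA_real_, nr, nc)
  START <- matrix(FALSE, nr, nc)
  tol <- 1e-9 * max(abs(values), na.rm = TRUE)
  # line starts: nodes with no in-line predecessor
  rs <- matrix(seq_len(nr), nr, nc)
  cs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  pr <- rs - dr; pc <- cs - dc
  is_start <- pr < 1L | pr > nr | pc < 1L | pc > nc
  starts <- which(is_start)
  for (s in starts) {
    r <- rs[s]; c <- cs[s]
    line <- integer(0)
    while (r >= 1L && r <= nr && c >= 1L && c <= nc) {
      line <- c(line, (c - 1L) * nr + r)
      r <- r + dr; c <- c + dc
    }
    # split at masked-out nodes
    ok <- mask[line]
    if (!any(ok)) next
    grp <- cumsum(!ok)
    for (g in unique(grp[ok])) {
      seg <- line[ok & grp == g]
      if (length(seg) < 2L) next
      v <- values[seg]
      rising <- diff(v) > tol
      if (!any(rising)) next
      rl <- rle(rising)
      ends <- cumsum(rl$lengths)
      begs <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        a <- begs[k]; b <- ends[k]  # edges a..b => nodes a..(b+1)
        ratio <- (v[b + 1L] - v[a]) / v[a]
        len <- (b + 1L - a) * steplen
        RATIO[seg[a:b]] <- ratio
        RLEN[seg[a:b]] <- len
        START[seg[a]] <- TRUE  # edge leaving the run's thin end
      }
    }
  }
  list(ratio = RATIO, rlen = RLEN, start = START)
}

#' Propagation graph over a thickness map
#'
#' Precomputes the directed 8-connected edge structure used by the
#' simulator: per-edge conduction velocities from the signed directional
#' thickness change (thin-to-thick slows per the curvature law with the
#' edge length as the local space step; thick-to-thin facilitates, capped
#' at 1.5 theta_o), and per-edge thin-to-thick transition profiles (rise
#' and run length of the maximal increasing thickness run through the
#' edge) used by the rate-dependent block criterion.
#'
#' @param map a \code{\link{thickness_map}}.
#' @param constants a \code{\link{model_constants}}.
#' @return An object of class \code{propagation_graph} (internal structure).
#' @keywords internal
#' @export
propagation_graph <- function(map, constants = model_constants()) {
  stopifnot(inherits(map, "thickness_map"),
            inherits(constants, "model_constants"))
  nr <- nrow(map$values); nc <- ncol(map$values)
  n <- nr * nc
  vals <- map$values
  msk <- map$mask
  rs <- matrix(seq_len(nr), nr, nc)
  cs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dirs <- vector("list", 8L)
  offs <- .dir_offsets()
  for (d in seq_along(offs)) {
    dr <- offs[[d]][1L]; dc <- offs[[d]][2L]
    tr <- rs + dr; tc <- cs + dc
    inb <- tr >= 1L & tr <= nr & tc >= 1L & tc <= nc
    to <- ifelse(inb, (pmin(pmax(tc, 1L), nc) - 1L) * nr +
                        pmin(pmax(tr, 1L), nr), NA_integer_)
    valid <- inb & msk
    valid[inb] <- valid[inb] & msk[to[inb]]
    len <- map$spacing * sqrt(dr^2 + dc^2)
    Tu <- as.vector(vals)
    Tv <- rep(NA_real_, n)
    Tv[valid] <- vals[to[valid]]
    ratio_edge <- (Tv - Tu) / Tu  # signed directional dT/T over the edge
    theta <- constants$theta_o - (constants$D / len) * ratio_edge
    theta <- pmin(theta, 1.5 * constants$theta_o)  # facilitation cap
    cost <- ifelse(!is.na(theta) & theta > 0, len / theta, Inf)
    prof <- .edge_profile_dir(vals, msk, dr, dc, map$spacing)
    dirs[[d]] <- list(dr = dr, dc = dc, len = len,
                      valid = as.vector(valid), to = as.vector(to),
                      theta = theta, cost = cost,
                      trans_ratio = as.vector(prof$ratio),
                      trans_len = as.vector(prof$rlen),
                      trans_start = as.vector(prof$start))
  }
  structure(list(nr = nr, nc = nc, n = n, spacing = map$spacing,
                 mask = as.vector(msk), dirs = dirs,
                 constants = constants),
            class = "propagation_graph")
}

# Per-direction logical vectors of curvature-excluded edges at a cycle
# length: static block (theta_edge <= 0) plus rate-dependent block of the
# local thin-to-thick transition.
.graph_exclusions <- function(graph, calibration, cycle_length,
                              extrapolate = "loglinear") {
  lapply(graph$dirs, function(dd) {
    excl <- dd$valid & !is.na(dd$theta) & dd$theta <= 0
    rising <- dd$valid & !is.na(dd$trans_ratio)
    if (any(rising))
      excl[rising] <- excl[rising] |
        will_block(dd$trans_ratio[rising], dd$trans_len[rising],
                   cycle_length, calibration, extrapolate = extrapolate)
    excl
  })
}

#' Curvature-excluded edge set at a cycle length
#'
#' The set of directed node-pair interfaces over which conduction fails at
#' the given activation cycle length, independent of any particular
#' stimulus: edges whose thin-to-thick transition is critically convex per
#' the rate-dependent criterion, plus edges statically blocked by the
#' conduction law. The set is monotone: shortening the cycle length can
#' only add edges.
#'
#' @param map a \code{\link{thickness_map}}.
#' @param cycle_length activation interval in ms.
#' @param constants a \code{\link{model_constants}}.
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @param extrapolate calibration extrapolation mode (see
#'   \code{\link{critical_width}}); the simulator default extends the
#'   calibration log-linearly.
#' @return data.frame with columns \code{from_row}, \code{from_col},
#'   \code{to_row}, \code{to_col}.
#' @export
blocked_edge_set <- function(map, cycle_length,
                             constants = model_constants(),
                             calibration = rate_block_calibration(),
                             extrapolate = "loglinear") {
  g <- propagation_graph(map, constants)
  excl <- .graph_exclusions(g, calibration, cycle_length, extrapolate)
  out <- list()
  for (d in seq_along(g$dirs)) {
    idx <- which(excl[[d]])
    if (!length(idx)) next
    to <- g$dirs[[d]]$to[idx]
    out[[length(out) + 1L]] <- data.frame(
      from_row = ((idx - 1L) %% g$nr) + 1L,
      from_col = ((idx - 1L) %/% g$nr) + 1L,
      to_row = ((to - 1L) %% g$nr) + 1L,
      to_col = ((to - 1L) %/% g$nr) + 1L)
  }
  if (!length(out))
    return(data.frame(from_row = integer(0), from_col = integer(0),
                      to_row = integer(0), to_col = integer(0)))
  do.call(rbind, out)
}

#' Uniform effective refractory period
#'
#' The model's first approximation treats the effective refractory period
#' (ERP) as spatially uniform across the border zone. Tissue activated at
#' time t cannot be re-excited before t + erp; a wavefront arriving earlier
#' is extinguished at that interface.
#'
#' @param erp effective refractory period in ms (default 100).
#' @return Object of class \code{refractory_model}.
#' @export
refractory_model <- function(erp = 100) {
  if (!is.numeric(erp) || length(erp) != 1L || !is.finite(erp) || erp <= 0)
    stop("'erp' must be a single positive number (ms)")
  structure(list(erp = erp), class = "refractory_model")
}

#' Simulate one activation cycle over a thickness map
#'
#' Discrete wavefront marching: from the given sources, each node's
#' activation time is the minimum over incoming edges of the neighbor's
#' time plus edge length divided by the edge conduction velocity. An edge
#' is impassable when its local thin-to-thick transition blocks at the
#' given cycle length (rate-dependent criterion) or when the edge velocity
#' is non-positive (statically critical curvature). When a refractory model
#' and prior-cycle activation times are supplied, an arrival earlier than
#' prior + erp is extinguished at that interface (the tissue has not
#' recovered); a later wavefront from another direction may still succeed.
#'
#' Activation times are absolute (same clock as \code{sources} and
#' \code{prior_activation}). Unreached nodes are NA.
#'
#' @param map a \code{\link{thickness_map}}.
#' @param constants a \code{\link{model_constants}}.
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @param sources data.frame with columns \code{row}, \code{col},
#'   \code{time}: wavefront origins and their start times (ms).
#' @param cycle_length activation interval (ms) at which rate-dependent
#'   block is evaluated.
#' @param refractory optional \code{\link{refractory_model}}.
#' @param prior_activation optional matrix of the previous cycle's absolute
#'   activation times (NA where not previously activated).
#' @param extrapolate calibration extrapolation mode (default
#'   \code{"loglinear"}).
#' @param graph optional precomputed \code{\link{propagation_graph}}.
#' @param tie_shuffle if TRUE, nodes tied for the earliest tentative time
#'   are settled in random order (activation times are invariant to this;
#'   used by property tests).
#' @return Object of class \code{activation_cycle}: list with
#'   \code{activation_time} (matrix, ms), \code{blocked_edges} (data.frame
#'   of interfaces where an arriving wavefront was halted by the curvature
#'   criterion), \code{refractory_failures} (count), \code{cycle_length},
#'   \code{sources}.
#' @export
simulate_cycle <- function(map, constants = model_constants(),
                           calibration = rate_block_calibration(),
                           sources, cycle_length,
                           refractory = NULL, prior_activation = NULL,
                           extrapolate = "loglinear", graph = NULL,
                           tie_shuffle = FALSE) {
  stopifnot(inherits(map, "thickness_map"))
  if (is.null(graph)) graph <- propagation_graph(map, constants)
  if (!is.data.frame(sources) ||
      !all(c("row", "col", "time") %in% names(sources)) ||
      nrow(sources) == 0L)
    stop("'sources' must be a non-empty data.frame with row, col, time")
  nr <- graph$nr; nc <- graph$nc; n <- graph$n
  src_idx <- (as.integer(sources$col) - 1L) * nr + as.integer(sources$row)
  if (any(sources$row < 1L | sources$row > nr |
          sources$col < 1L | sources$col > nc))
    stop("source outside the grid")
  if (!all(graph$mask[src_idx])) stop("source on masked-out node")
  erp <- if (!is.null(refractory)) {
    stopifnot(inherits(refractory, "refractory_model")); refractory$erp
  } else NULL
  prior <- if (!is.null(prior_activation)) as.vector(prior_activation)
  excl <- .graph_exclusions(graph, calibration, cycle_length, extrapolate)

  dist <- rep(Inf, n)
  dist[src_idx] <- pmin(dist[src_idx], as.numeric(sources$time))
  active <- dist  # settled nodes set to Inf here
  settled <- rep(FALSE, n)
  blk_from <- integer(0); blk_to <- integer(0)
  refr_fail <- 0L
  dirs <- graph$dirs
  repeat {
    mn <- min(active)
    if (!is.finite(mn)) break
    cand <- which(active == mn)
    u <- if (tie_shuffle && length(cand) > 1L)
      cand[sample.int(length(cand), 1L)] else cand[1L]
    settled[u] <- TRUE
    active[u] <- Inf
    tu <- dist[u]
    for (d in 1:8) {
      dd <- dirs[[d]]
      if (!dd$valid[u]) next
      v <- dd$to[u]
      if (settled[v]) next
      if (excl[[d]][u] || !is.finite(dd$cost[u])) {
        # draw the halted interface only at the thin end of the transition
        # run, where the primary (thin-side) wavefront fails; attempts from
        # mid-transition nodes reached sideways are the same block
        if (isTRUE(dd$trans_start[u])) {
          blk_from <- c(blk_from, u); blk_to <- c(blk_to, v)
        }
        next
      }
      tv <- tu + dd$cost[u]
      if (!is.null(erp) && !is.null(prior) && !is.na(prior[v]) &&
          tv < prior[v] + erp - 1e-9) {
        refr_fail <- refr_fail + 1L
        next
      }
      if (tv < dist[v] - 1e-12) {
        dist[v] <- tv
        active[v] <- tv
      }
    }
  }
  times <- matrix(ifelse(is.finite(dist), dist, NA_real_), nr, nc)
  # keep blocked interfaces where the wavefront was actually halted: the
  # target activated later from elsewhere, or never
  keep <- logical(length(blk_from))
  if (length(blk_from)) {
    tf <- dist[blk_from]; tt <- dist[blk_to]
    keep <- is.finite(tf) & (!is.finite(tt) | tt > tf + 1e-9)
  }
  blocked <- data.frame(
    from_row = ((blk_from[keep] - 1L) %% nr) + 1L,
    from_col = ((blk_from[keep] - 1L) %/% nr) + 1L,
    to_row = ((blk_to[keep] - 1L) %% nr) + 1L,
    to_col = ((blk_to[keep] - 1L) %/% nr) + 1L,
    t_from = dist[blk_from[keep]],
    t_to = ifelse(is.finite(dist[blk_to[keep]]), dist[blk_to[keep]],
                  NA_real_))
  structure(list(activation_time = times, blocked_edges = blocked,
                 refractory_failures = refr_fail,
                 cycle_length = cycle_length, sources = sources,
                 spacing = graph$spacing),
            class = "activation_cycle")
}

#' @export
print.activation_cycle <- function(x, ...) {
  tm <- x$activation_time
  cat(sprintf("Activation cycle (CL %g ms): %d/%d nodes activated\n",
              x$cycle_length, sum(!is.na(tm)), length(tm)))
  if (sum(!is.na(tm)))
    cat(sprintf("  times %.1f-%.1f ms; %d blocked interfaces, %d refractory failures\n",
                min(tm, na.rm = TRUE), max(tm, na.rm = TRUE),
                nrow(x$blocked_edges), x$refractory_failures))
  invisible(x)
}
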