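# minimum distance between two segments p1-p2 and q1-q2 (2-D)
.seg_dist <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    L2 <- sum(ab^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
    sqrt(sum((a + t * ab - p)^2))
  }
  segs_cross <- function(a, b, c, d) {
    cr <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) -
      (p[2] - o[2]) * (q[1] - o[1])
    d1 <- cr(c, d, a); d2 <- cr(c, d, b); d3 <- cr(a, b, c); d4 <- cr(a, b, d)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  if (segs_cross(p1, p2, q1, q2)) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2),
      pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

.poly_segments <- function(poly) {
  n <- nrow(poly)
  if (n < 2L) return(NULL)
  list(a = as.matrix(poly[-n, c("x", "y")]),
       b = as.matrix(poly[-1L, c("x", "y")]))
}

.poly_dist <- function(pa, pb) {
  sa <- .poly_segments(pa); sb <- .poly_segments(pb)
  if (is.null(sa) || is.null(sb)) stop("degenerate polyline (< 2 vertices)")
  best <- Inf
  for (i in seq_len(nrow(sa$a)))
    for (j in seq_len(nrow(sb$a)))
      best <- min(best, .seg_dist(sa$a[i, ], sa$b[i, ], sb$a[j, ], sb$b[j, ]))
  best
}

.arc_length <- function(poly) {
  n <- nrow(poly)
  if (n < 2L) return(0)
  sum(sqrt(diff(poly$x)^2 + diff(poly$y)^2))
}

#' Reentry-circuit geometry
#'
#' The spatial objects needed to relate the unidirectional block line of
#' premature stimulation to the reentry isthmus: the stimulus site, the
#' UBL polyline, the two lateral functional block lines bounding the
#' isthmus during reentry, and the isthmus long axis. When the axis is not
#' supplied it is estimated as the principal direction of the lateral
#' polylines' vertices.
#'
#' @param stimulus_site numeric \code{c(x, y)} in mm.
#' @param ubl data.frame polyline (columns x, y, mm).
#' @param lateral_lines list of two data.frame polylines.
#' @param isthmus_axis optional unit vector \code{c(x, y)}.
#' @return Object of class \code{circuit_geometry}.
#' @export
circuit_geometry <- function(stimulus_site, ubl, lateral_lines,
                             isthmus_axis = NULL) {
  if (!is.numeric(stimulus_site) || length(stimulus_site) != 2L)
    stop("'stimulus_site' must be c(x, y) in mm")
  chk <- function(p, nm) {
    if (!is.data.frame(p) || !all(c("x", "y") %in% names(p)) || nrow(p) < 2L)
      stop(sprintf("'%s' must be a polyline data.frame with >= 2 vertices",
                   nm))
    p
  }
  ubl <- chk(ubl, "ubl")
  if (!is.list(lateral_lines) || length(lateral_lines) != 2L)
    stop("'lateral_lines' must be a list of two polylines")
  lateral_lines <- list(chk(lateral_lines[[1L]], "lateral_lines[[1]]"),
                        chk(lateral_lines[[2L]], "lateral_lines[[2]]"))
  if (is.null(isthmus_axis)) {
    pts <- rbind(as.matrix(lateral_lines[[1L]][, c("x", "y")]),
                 as.matrix(lateral_lines[[2L]][, c("x", "y")]))
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    isthmus_axis <- sv$v[, 1L]
  }
  isthmus_axis <- isthmus_axis / sqrt(sum(isthmus_axis^2))
  structure(list(stimulus_site = as.numeric(stimulus_site), ubl = ubl,
                 lateral_lines = lateral_lines,
                 isthmus_axis = as.numeric(isthmus_axis)),
            class = "circuit_geometry")
}

# split the UBL into its axis-aligned ("lateral edge") segments, keyed by
# which side of the isthmus axis they fall on
.ubl_lateral_edges <- function(geometry) {
  u <- geometry$isthmus_axis
  nvec <- c(-u[2L], u[1L])
  pts <- rbind(as.matrix(geometry$lateral_lines[[1L]][, c("x", "y")]),
               as.matrix(geometry$lateral_lines[[2L]][, c("x", "y")]))
  ctr <- colMeans(pts)
  sg <- .poly_segments(geometry$ubl)
  dirs <- sg$b - sg$a
  lens <- sqrt(rowSums(dirs^2))
  keep <- lens > 0
  along <- abs((dirs[, 1L] * u[1L] + dirs[, 2L] * u[2L]) / pmax(lens, 1e-12))
  axis_aligned <- keep & along >= cos(pi / 4)
  mid <- (sg$a + sg$b) / 2
  side <- sign((mid[, 1L] - ctr[1L]) * nvec[1L] +
                 (mid[, 2L] - ctr[2L]) * nvec[2L])
  list(a = sg$a, b = sg$b, lens = lens, axis_aligned = axis_aligned,
       side = side, ctr = ctr, nvec = nvec)
}

.axis_coord <- function(p, geometry) {
  u <- geometry$isthmus_axis
  p[, 1L] * u[1L] + p[, 2L] * u[2L]
}

#' Measure the UBL-isthmus spatial relationship
#'
#' The five lengths quantifying whether the unidirectional block line of
#' premature stimulation coincides with the isthmus entrance boundary:
#' \describe{
#'   \item{a}{distance from the stimulus site to the UBL leading edge
#'     (the UBL vertex nearest the stimulus), mm.}
#'   \item{b}{extent of the UBL lateral edges: mean over the two sides of
#'     the arc length of the UBL's axis-aligned segments, mm.}
#'   \item{c_len}{isthmus length along its long axis: mean of the two
#'     lateral block lines' arc lengths, mm.}
#'   \item{d}{projection of the UBL lateral edges onto the lateral block
#'     lines: mean over sides of the overlap, along the isthmus axis,
#'     between the UBL lateral edges and the lateral lines, mm.}
#'   \item{e}{error function: mean over sides of the minimum distance
#'     between each UBL lateral edge and its nearest lateral line, mm.}
#'   \item{d_over_c}{100 d / c_len: percent of the isthmus length
#'     overlapped by the UBL.}
#' }
#'
#' @param geometry a \code{\link{circuit_geometry}}.
#' @return data.frame with one row: a, b, c_len, d, e, d_over_c.
#' @export
measure_circuit <- function(geometry) {
  stopifnot(inherits(geometry, "circuit_geometry"))
  stim <- geometry$stimulus_site
  dle <- sqrt((geometry$ubl$x - stim[1L])^2 + (geometry$ubl$y - stim[2L])^2)
  a <- min(dle)
  c_len <- mean(vapply(geometry$lateral_lines, .arc_length, 0))
  ed <- .ubl_lateral_edges(geometry)
  lat_sides <- vapply(geometry$lateral_lines, function(p) {
    m <- colMeans(as.matrix(p[, c("x", "y")]))
    sign((m[1L] - ed$ctr[1L]) * ed$nvec[1L] +
           (m[2L] - ed$ctr[2L]) * ed$nvec[2L])
  }, 0)
  b_sides <- d_sides <- e_sides <- numeric(0)
  for (s in c(-1, 1)) {
    segs <- which(ed$axis_aligned & ed$side == s)
    if (!length(segs)) next
    b_sides <- c(b_sides, sum(ed$lens[segs]))
    # axial interval of the UBL lateral edge on this side
    verts <- rbind(ed$a[segs, , drop = FALSE], ed$b[segs, , drop = FALSE])
    ubl_iv <- range(.axis_coord(verts, geometry))
    m <- match(s, lat_sides)
    if (is.na(m)) m <- which.min(abs(lat_sides - s))  # nearest lateral line
    lat <- geometry$lateral_lines[[m]]
    lat_iv <- range(.axis_coord(as.matrix(lat[, c("x", "y")]), geometry))
    ov <- min(ubl_iv[2L], lat_iv[2L]) - max(ubl_iv[1L], lat_iv[1L])
    d_sides <- c(d_sides, max(0, ov))
    sl <- .poly_segments(lat)
    e_side <- Inf
    for (i in segs)
      for (j in seq_len(nrow(sl$a)))
        e_side <- min(e_side, .seg_dist(ed$a[i, ], ed$b[i, ],
                                        sl$a[j, ], sl$b[j, ]))
    e_sides <- c(e_sides, e_side)
  }
  b <- if (length(b_sides)) mean(b_sides) else 0
  d <- if (length(d_sides)) mean(d_sides) else 0
  e <- if (length(e_sides)) mean(e_sides) else NA_real_
  data.frame(a = a, b = b, c_len = c_len, d = d, e = e,
             d_over_c = 100 * d / c_len)
}

#' Position of the UBL leading edge along the isthmus
#'
#' Projects the UBL leading edge (its vertex nearest the stimulus site)
#' onto the isthmus long axis and reports the distance from the distal end
#' of the isthmus - the end farther from the stimulus - as a percent of
#' the isthmus length.
#'
#' @param geometry a \code{\link{circuit_geometry}}.
#' @return Percent (0 at the distal end).
#' @export
leading_edge_position <- function(geometry) {
  stopifnot(inherits(geometry, "circuit_geometry"))
  stim <- geometry$stimulus_site
  dle <- sqrt((geometry$ubl$x - stim[1L])^2 + (geometry$ubl$y - stim[2L])^2)
  le <- as.matrix(geometry$ubl[which.min(dle), c("x", "y")])
  c_len <- mean(vapply(geometry$lateral_lines, .arc_length, 0))
  lat_pts <- rbind(as.matrix(geometry$lateral_lines[[1L]][, c("x", "y")]),
                   as.matrix(geometry$lateral_lines[[2L]][, c("x", "y")]))
  iv <- range(.axis_coord(lat_pts, geometry))
  stim_s <- .axis_coord(matrix(stim, 1L), geometry)
  distal <- if (abs(iv[1L] - stim_s) > abs(iv[2L] - stim_s)) iv[1L] else iv[2L]
  100 * abs(.axis_coord(le, geometry) - distal) / c_len
}

#' Summary statistics over experiment records
#'
#' Arithmetic mean and sample standard deviation (n - 1) of every numeric
#' column, matching the MN and SD rows of the per-experiment measurement
#' tables.
#'
#' @param records data.frame of per-experiment values (>= 2 rows).
#' @return data.frame with rows \code{mean} and \code{sd}.
#' @export
summarize_experiments <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2L)
    stop("'records' must be a data.frame with at least 2 rows")
  num <- vapply(records, is.numeric, TRUE)
  num["expt"] <- FALSE
  cols <- records[, num, drop = FALSE]
  out <- rbind(mean = vapply(cols, mean, 0),
               sd = vapply(cols, stats::sd, 0))
  as.data.frame(out)
}

#' Count experiments with reexcitation shorter than the coupling interval
#'
#' @param records data.frame with columns \code{reexcitation} and
#'   \code{ps} (premature coupling interval), ms.
#' @return Integer count (strict inequality).
#' @export
count_reexcitation_shorter <- function(records) {
  if (!all(c("reexcitation", "ps") %in% names(records)))
    stop("'records' needs columns 'reexcitation' and 'ps'")
  sum(records$reexcitation < records$ps)
}

#' Per-experiment measurement tables
#'
#' The per-experiment measurements of the 12 mapped postinfarction canine
#' experiments, shipped as plain-text fixtures: the UBL/isthmus length
#' measurements (a, b, c, d in mm and d/c in percent) and the cycle-length
#' records (premature coupling interval ps, first-VT-cycle length vt, and
#' reexcitation interval, ms).
#'
#' @return List with data.frames \code{measurements} and
#'   \code{cycle_lengths}.
#' @examples
#' tabs <- experiment_tables()
#' summarize_experiments(tabs$measurements)
#' count_reexcitation_shorter(tabs$cycle_lengths)
#' @export
experiment_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "bzblock",
                                  mustWork = TRUE)
  list(measurements = utils::read.delim(path("ubl_isthmus_measurements.tsv")),
       cycle_lengths = utils::read.delim(path("cycle_lengths.tsv")))
}
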