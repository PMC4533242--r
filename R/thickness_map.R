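#' Border-zone thickness map
#'
#' Constructs a regular 2-D grid of infarct border-zone thickness. Rows and
#' columns are node-centered with 0-based physical coordinates: node (i, j)
#' (1-based R indices) sits at x = (j-1)*spacing, y = (i-1)*spacing, the
#' origin at the top-left node. Thickness is stored in micrometres; the grid
#' spacing is in millimetres.
#'
#' @param values numeric matrix of thickness in um; NA marks non-viable
#'   (masked-out) nodes when \code{mask} is not given.
#' @param spacing grid step in mm (square grid).
#' @param mask logical matrix, TRUE = viable border zone. Defaults to
#'   \code{!is.na(values)}.
#' @return An object of class \code{thickness_map} with fields
#'   \code{values}, \code{spacing}, \code{mask}.
#' @export
thickness_map <- function(values, spacing = 1, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 3L || ncol(values) < 3L)
    stop("thickness map needs at least 3x3 nodes")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("'spacing' must be a single positive number (mm)")
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(values)))
    stop("'mask' must be a logical matrix with the dimensions of 'values'")
  if (any(is.na(mask))) stop("'mask' must not contain NA")
  vin <- values[mask]
  if (any(is.na(vin)) || any(vin <= 0))
    stop("all masked-in thickness values must be positive and non-missing")
  structure(list(values = values, spacing = spacing, mask = mask),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("Border-zone thickness map: %d x %d nodes, spacing %g mm\n",
              nrow(x$values), ncol(x$values), x$spacing))
  cat(sprintf("  thickness range %.0f-%.0f um, %d/%d nodes viable\n",
              min(v), max(v), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.thickness_map <- function(x) dim(x$values)

#' Uniform thickness map
#'
#' The control geometry: every node has the same thickness, so the spatial
#' thickness-change field is identically zero and conduction over the map is
#' rectilinear at theta_o everywhere.
#'
#' @param T thickness in um.
#' @param shape integer vector \code{c(rows, cols)}.
#' @param spacing grid step in mm.
#' @return A \code{\link{thickness_map}}.
#' @examples
#' m <- make_uniform_map(1440, c(40, 40), 1)
#' @export
make_uniform_map <- function(T, shape, spacing = 1) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("'T' must be a single positive thickness in um")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(is.na(shape)) || any(shape < 3L))
    stop("'shape' must be two integers >= 3")
  thickness_map(matrix(T, shape[1L], shape[2L]), spacing = spacing)
}

#' Isthmus channel specification
#'
#' Parameterizes the synthetic border-zone geometry: a thin channel (the
#' reentry isthmus, coincident with the thinnest border zone) inside a
#' thicker outer pathway, with a steep thickness ramp at one end (the
#' entrance, where unidirectional block forms), a more gradual ramp at the
#' other end (the exit), and steep lateral ramps flanking the channel.
#'
#' Default thicknesses are the mean values measured in postinfarction canine
#' border zone: 231 um at the isthmus, 1440 um along the outer pathway.
#' Channel width (10 mm) and length (23 mm, the mean measured isthmus
#' length) are package choices for a realistic mapped circuit.
#'
#' @param channel_start,channel_end numeric length-2 points \code{c(x, y)}
#'   in mm: the channel axis runs from \code{channel_start} (the entrance,
#'   steep end) to \code{channel_end} (the exit, gradual end).
#' @param channel_width width of the thin channel in mm.
#' @param T_isthmus,T_outer thickness (um) of the channel and the far field.
#' @param entrance_transition_length axial ramp length (mm) at the steep
#'   (entrance) end; must not exceed \code{exit_transition_length}.
#' @param exit_transition_length axial ramp length (mm) at the gradual
#'   (exit) end.
#' @param lateral_transition_length ramp length (mm) across the lateral
#'   channel boundaries.
#' @return An object of class \code{isthmus_spec}.
#' @export
isthmus_spec <- function(channel_start = c(8, 15),
                         channel_end = c(31, 15),
                         channel_width = 10,
                         T_isthmus = 231, T_outer = 1440,
                         entrance_transition_length = 2,
                         exit_transition_length = 6,
                         lateral_transition_length = 1.5) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
    x
  }
  if (!is.numeric(channel_start) || length(channel_start) != 2L ||
      !is.numeric(channel_end) || length(channel_end) != 2L)
    stop("'channel_start' and 'channel_end' must be length-2 points (mm)")
  if (sqrt(sum((channel_end - channel_start)^2)) <= 0)
    stop("channel axis is degenerate")
  T_isthmus <- num1(T_isthmus, "T_isthmus")
  T_outer <- num1(T_outer, "T_outer")
  if (T_isthmus >= T_outer) stop("'T_isthmus' must be less than 'T_outer'")
  ent <- num1(entrance_transition_length, "entrance_transition_length")
  ext <- num1(exit_transition_length, "exit_transition_length")
  lat <- num1(lateral_transition_length, "lateral_transition_length")
  if (ent > ext)
    stop("the entrance is the steep end: entrance_transition_length must ",
         "not exceed exit_transition_length")
  structure(list(channel_start = as.numeric(channel_start),
                 channel_end = as.numeric(channel_end),
                 channel_width = num1(channel_width, "channel_width"),
                 T_isthmus = T_isthmus, T_outer = T_outer,
                 entrance_transition_length = ent,
                 exit_transition_length = ext,
                 lateral_transition_length = lat),
            class = "isthmus_spec")
}

#' Synthetic isthmus thickness map
#'
#' Generates a thickness map containing a thin channel per an
#' \code{\link{isthmus_spec}}. Thickness ramps linearly (in thickness) from
#' \code{T_isthmus} to \code{T_outer} over each transition zone: axially
#' beyond the channel ends (over the entrance/exit transition lengths) and
#' laterally beyond the channel half-width (over the lateral transition
#' length). Where an axial and a lateral ramp overlap, the larger of the
#' two ramp fractions applies, so the generated field is bounded by
#' [T_isthmus, T_outer] and non-decreasing outward from the channel.
#'
#' @param spec an \code{\link{isthmus_spec}}.
#' @param shape integer \code{c(rows, cols)}.
#' @param spacing grid step in mm.
#' @return A \code{\link{thickness_map}}.
#' @examples
#' m <- make_isthmus_map(isthmus_spec(), c(31, 46), 1)
#' @export
make_isthmus_map <- function(spec, shape = c(31, 46), spacing = 1) {
  stopifnot(inherits(spec, "isthmus_spec"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(is.na(shape)) || any(shape < 3L))
    stop("'shape' must be two integers >= 3")
  xmax <- (shape[2L] - 1L) * spacing
  ymax <- (shape[1L] - 1L) * spacing
  p0 <- spec$channel_start
  p1 <- spec$channel_end
  margin <- 2 * spacing
  for (p in list(p0, p1))
    if (p[1] < margin || p[1] > xmax - margin ||
        p[2] < margin || p[2] > ymax - margin)
      stop("channel axis must lie inside the grid with >= 2 nodes margin")

  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  u <- axis / L
  x <- (seq_len(shape[2L]) - 1) * spacing
  y <- (seq_len(shape[1L]) - 1) * spacing
  X <- matrix(x, shape[1L], shape[2L], byrow = TRUE)
  Y <- matrix(y, shape[1L], shape[2L])
  # axial coordinate s (0 at entrance, L at exit) and lateral offset l
  dx <- X - p0[1]; dy <- Y - p0[2]
  s <- dx * u[1] + dy * u[2]
  l <- abs(-dx * u[2] + dy * u[1])
  f_ax <- matrix(0, shape[1L], shape[2L])
  f_ax[s < 0] <- pmin(1, -s[s < 0] / spec$entrance_transition_length)
  f_ax[s > L] <- pmin(1, (s[s > L] - L) / spec$exit_transition_length)
  f_lat <- pmin(1, pmax(0, (l - spec$channel_width / 2) /
                             spec$lateral_transition_length))
  f <- pmax(f_ax, f_lat)
  vals <- spec$T_isthmus + f * (spec$T_outer - spec$T_isthmus)
  m <- thickness_map(vals, spacing = spacing)
  m$isthmus <- spec
  m
}

#' Write a thickness map as a delimited-text raster
#'
#' One number per node in um, tab-delimited, preceded by a header line
#' \code{# spacing_mm=<spacing>}. Masked-out nodes are written as NA.
#'
#' @param map a \code{\link{thickness_map}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  vals <- map$values
  vals[!map$mask] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_mm=%.17g", map$spacing), con)
  utils::write.table(vals, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a thickness map from a delimited-text raster
#'
#' Accepts tab- or comma-delimited rasters, optionally starting with a
#' \code{# spacing_mm=<float>} header. Without the header the spacing
#' defaults to 1 mm and a warning is issued. NA cells become masked-out
#' nodes (e.g. infarct holes); any other non-numeric cell is a parse error
#' reported with its row and column.
#'
#' @param path input file path.
#' @return A \code{\link{thickness_map}}.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty raster file: ", path)
  spacing <- NA_real_
  if (grepl("^#", lines[1L])) {
    hm <- regmatches(lines[1L],
                     regexec("spacing_mm\\s*=\\s*([0-9eE.+-]+)", lines[1L]))[[1L]]
    if (length(hm) == 2L) spacing <- as.numeric(hm[2L])
    lines <- lines[-1L]
  }
  if (is.na(spacing)) {
    warning("no spacing header in ", path, "; assuming 1 mm")
    spacing <- 1
  }
  sep <- if (grepl(",", lines[1L], fixed = TRUE)) "," else "\t"
  rows <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged raster: row %d has %d cells, row 1 has %d",
                 which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L]))
  parse_row <- function(i) {
    cells <- trimws(rows[[i]])
    out <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(out) & !(cells %in% c("NA", "nan", "NaN", "")))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                   cells[bad[1L]], i, bad[1L]))
    out
  }
  vals <- do.call(rbind, lapply(seq_along(rows), parse_row))
  thickness_map(vals, spacing = spacing)
}
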