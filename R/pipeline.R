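#' Worked examples of the conduction-block model
#'
#' Recomputes, from the model constants and the block calibration, the
#' chain of quantities linking border-zone thickness to rate-dependent
#' conduction block: the relative thickness change between the isthmus
#' (231 um) and the outer pathway (1440 um); the critical circular-arc
#' curvatures at the calibrated widths for 200, 150 and 117 ms; and the
#' corresponding critical space steps - the largest transition distances
#' that still block at each rate. The \code{printed} column rounds each
#' value to its conventional reported precision.
#'
#' @param T_isthmus,T_outer thickness in um.
#' @param constants a \code{\link{model_constants}}.
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @return data.frame with columns quantity, cycle_length, value, printed,
#'   units.
#' @examples
#' worked_examples()
#' @export
worked_examples <- function(T_isthmus = 231, T_outer = 1440,
                            constants = model_constants(),
                            calibration = rate_block_calibration()) {
  ratio <- (T_outer - T_isthmus) / T_isthmus
  cal <- calibration$points[order(-calibration$points$cl), ]
  rho <- rho_from_width(cal$w, calibration$beta)
  cstep <- critical_space_step(ratio, cal$cl, calibration)
  data.frame(
    quantity = c("dT/T", rep("rho_crit", nrow(cal)),
                 rep("c_crit", nrow(cal))),
    cycle_length = c(NA, cal$cl, cal$cl),
    value = c(ratio, rho, cstep),
    printed = c(round(ratio, 2), signif(rho, 3), round(cstep, 1)),
    units = c("unitless", rep("mm^-1", nrow(cal)), rep("mm", nrow(cal))))
}

.write_raster <- function(m, path, spacing) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_mm=%.17g", spacing), con)
  utils::write.table(round(m, 6), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects everything a full model run needs: the thickness map (an
#' \code{\link{isthmus_spec}} plus shape, or a raster path), the model
#' constants, the block calibration, the stimulus protocol, and the
#' refractory period. Can also be loaded from a YAML file whose keys
#' mirror the argument names.
#'
#' @param map a \code{\link{thickness_map}}, or a path to a raster file.
#' @param constants a \code{\link{model_constants}}.
#' @param calibration a \code{\link{rate_block_calibration}}.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param refractory a \code{\link{refractory_model}}.
#' @param pivot_delay see \code{\link{run_premature_protocol}}.
#' @param vt_cycle_length cycle length (ms) for the VT-rate block
#'   prediction raster.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(map, constants = model_constants(),
                       calibration = rate_block_calibration(),
                       protocol, refractory = refractory_model(100),
                       pivot_delay = 100, vt_cycle_length = 200) {
  if (is.character(map)) map <- read_map(map)
  stopifnot(inherits(map, "thickness_map"),
            inherits(protocol, "stimulus_protocol"))
  structure(list(map = map, constants = constants,
                 calibration = calibration, protocol = protocol,
                 refractory = refractory, pivot_delay = pivot_delay,
                 vt_cycle_length = vt_cycle_length),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys: \code{map} (path to a thickness raster) or
#' \code{isthmus} (fields of \code{\link{isthmus_spec}} plus \code{shape},
#' \code{spacing}); \code{constants} (theta_o, D, c); \code{calibration}
#' (cl and w lists, beta); \code{protocol} (site, s1_interval,
#' s2_interval, s1_count); \code{erp}; \code{pivot_delay};
#' \code{vt_cycle_length}.
#'
#' @param path YAML file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  map <- if (!is.null(y$map)) {
    read_map(if (file.exists(y$map)) y$map
             else file.path(dirname(path), y$map))
  } else if (!is.null(y$isthmus)) {
    iy <- y$isthmus
    shape <- if (is.null(iy$shape)) c(31, 46) else unlist(iy$shape)
    spacing <- if (is.null(iy$spacing)) 1 else iy$spacing
    iy$shape <- NULL; iy$spacing <- NULL
    make_isthmus_map(do.call(isthmus_spec, iy), shape, spacing)
  } else stop("config needs 'map' or 'isthmus'")
  constants <- do.call(model_constants, as.list(y$constants))
  calibration <- if (is.null(y$calibration)) rate_block_calibration() else
    rate_block_calibration(data.frame(cl = unlist(y$calibration$cl),
                                      w = unlist(y$calibration$w)),
                           beta = if (is.null(y$calibration$beta)) 90
                                  else y$calibration$beta)
  protocol <- do.call(stimulus_protocol, as.list(y$protocol))
  run_config(map, constants, calibration, protocol,
             refractory_model(if (is.null(y$erp)) 100 else y$erp),
             pivot_delay = if (is.null(y$pivot_delay)) 100 else y$pivot_delay,
             vt_cycle_length = if (is.null(y$vt_cycle_length)) 200
                               else y$vt_cycle_length)
}

#' Run the full model pipeline
#'
#' End-to-end run: thickness map -> curvature (dT/T) rasters ->
#' rate-dependent block-prediction rasters at the premature and VT cycle
#' lengths -> activation simulation of the S1/S2/V1 cycles -> block-line
#' polylines -> circuit measurements -> summary report. All artifacts are
#' plain text; identical configurations produce identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return List with the pipeline products: \code{curvature}
#'   (\code{\link{curvature_field}}), \code{run}
#'   (\code{\link{run_premature_protocol}} result), \code{geometry}
#'   (\code{\link{circuit_geometry}} or NULL), \code{measurements}
#'   (data.frame or NULL), \code{report} (character vector).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  map <- config$map
  cf <- curvature_field(map, config$constants)
  ps_cl <- config$protocol$s2_interval
  node_block <- function(cl) {
    be <- blocked_edge_set(map, cl, config$constants, config$calibration)
    m <- matrix(0L, nrow(map$values), ncol(map$values))
    if (nrow(be)) m[cbind(be$from_row, be$from_col)] <- 1L
    m
  }
  blk_ps <- node_block(ps_cl)
  blk_vt <- node_block(config$vt_cycle_length)
  run <- run_premature_protocol(map, config$constants, config$calibration,
                                config$protocol, config$refractory,
                                pivot_delay = config$pivot_delay)
  geometry <- NULL
  measurements <- NULL
  if (isTRUE(run$induced)) {
    labs <- vapply(run$block_lines, function(p) attr(p, "label"), "")
    ubls <- run$block_lines[labs == "UBL"]
    lats <- run$block_lines[labs == "lateral"]
    if (length(ubls) >= 1L && length(lats) >= 2L) {
      lat_len <- vapply(lats, .arc_length, 0)
      lats <- lats[order(-lat_len)][1:2]
      ubl <- ubls[[which.max(vapply(ubls, .arc_length, 0))]]
      geometry <- circuit_geometry(run$stimulus_mm, ubl, lats)
      measurements <- measure_circuit(geometry)
      measurements$leading_edge_position <- leading_edge_position(geometry)
    }
  }
  report <- c(
    sprintf("map: %d x %d nodes, spacing %g mm, thickness %.0f-%.0f um",
            nrow(map$values), ncol(map$values), map$spacing,
            min(map$values[map$mask]), max(map$values[map$mask])),
    sprintf("constants: theta_o=%g mm/ms, D=%g mm^2/ms, c=%g mm (critical dT/T=%g)",
            config$constants$theta_o, config$constants$D,
            config$constants$c, critical_ratio(config$constants)),
    sprintf("max dT/T = %.3f; %d statically blocked nodes",
            max(cf$ratio, na.rm = TRUE), sum(cf$blocked)),
    sprintf("block-prediction nodes: %d at PS CL %g ms, %d at VT CL %g ms",
            sum(blk_ps), ps_cl, sum(blk_vt), config$vt_cycle_length),
    sprintf("protocol: S1 %g ms x%d, S2 %g ms at node (%d, %d); ERP %g ms",
            config$protocol$s1_interval, config$protocol$s1_count,
            config$protocol$s2_interval, config$protocol$site[1L],
            config$protocol$site[2L], config$refractory$erp),
    paste0("outcome: ", run$diagnostic))
  if (isTRUE(run$induced))
    report <- c(report,
      sprintf("reexcitation interval %.1f ms (coupling interval %g ms)",
              run$reexcitation_interval, ps_cl))
  if (!is.null(measurements))
    report <- c(report, sprintf(
      "circuit: a=%.1f b=%.1f c=%.1f d=%.1f e=%.1f mm, d/c=%.1f%%, leading edge at %.1f%%",
      measurements$a, measurements$b, measurements$c_len, measurements$d,
      measurements$e, measurements$d_over_c,
      measurements$leading_edge_position))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map(map, file.path(out_dir, "thickness.tsv"))
    .write_raster(cf$ratio, file.path(out_dir, "ratio.tsv"), map$spacing)
    .write_raster(cf$theta, file.path(out_dir, "theta.tsv"), map$spacing)
    .write_raster(blk_ps, file.path(out_dir, "block_prediction_ps.tsv"),
                  map$spacing)
    .write_raster(blk_vt, file.path(out_dir, "block_prediction_vt.tsv"),
                  map$spacing)
    for (nm in names(run$cycles))
      .write_raster(run$cycles[[nm]]$activation_time,
                    file.path(out_dir, paste0("activation_", nm, ".tsv")),
                    map$spacing)
    if (nrow(run$blocked_edges))
      utils::write.table(run$blocked_edges,
                         file.path(out_dir, "blocked_edges.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (length(run$block_lines)) {
      lines <- unlist(lapply(seq_along(run$block_lines), function(i) {
        p <- run$block_lines[[i]]
        c(sprintf("> line %d label=%s", i, attr(p, "label")),
          sprintf("%.3f\t%.3f", p$x, p$y))
      }))
      writeLines(lines, file.path(out_dir, "block_lines.txt"))
    }
    if (!is.null(measurements))
      utils::write.table(measurements,
                         file.path(out_dir, "measurements.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  list(curvature = cf, block_prediction = list(ps = blk_ps, vt = blk_vt),
       run = run, geometry = geometry, measurements = measurements,
       report = report)
}
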