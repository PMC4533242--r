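# Independent oracles and shared fixtures for the test suite.

# Scalar bilinear interpolation, written independently of the package
# internals: value of the thickness surface at fractional (row, col).
oracle_interp <- function(values, r, c) {
  nr <- nrow(values); nc <- ncol(values)
  if (abs(r - round(r)) < 1e-9) r <- round(r)
  if (abs(c - round(c)) < 1e-9) c <- round(c)
  if (r < 1 || r > nr || c < 1 || c > nc) return(NA_real_)
  r0 <- min(floor(r), nr - 1); c0 <- min(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * values[r0, c0] +
    fr * (1 - fc) * values[r0 + 1, c0] +
    (1 - fr) * fc * values[r0, c0 + 1] +
    fr * fc * values[r0 + 1, c0 + 1]
}

# Brute-force maximum thin-to-thick thickness change: explicit loop over
# nodes and the 8 compass bearings.
oracle_delta_T <- function(map, c = 1) {
  vals <- map$values
  nr <- nrow(vals); nc <- ncol(vals)
  step <- c / map$spacing
  out <- matrix(0, nr, nc)
  angles <- 2 * pi * (0:7) / 8
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- 0
    for (a in angles) {
      v <- oracle_interp(vals, i + step * sin(a), j + step * cos(a))
      if (!is.na(v)) best <- max(best, v - vals[i, j])
    }
    out[i, j] <- best
  }
  out
}

# Exhaustive relaxation (Bellman-Ford style) of single-cycle activation
# times over the package's edge-speed graph: iterate over every directed
# edge until no activation time improves. Independent of the marching
# order used by simulate_cycle.
oracle_activation <- function(map, sources, cycle_length,
                              constants = model_constants(),
                              calibration = rate_block_calibration()) {
  g <- propagation_graph(map, constants)
  excl_df <- blocked_edge_set(map, cycle_length, constants, calibration)
  excl_key <- sprintf("%d_%d_%d_%d", excl_df$from_row, excl_df$from_col,
                      excl_df$to_row, excl_df$to_col)
  nr <- g$nr; nc <- g$nc
  dist <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(sources)))
    dist[sources$row[k], sources$col[k]] <-
      min(dist[sources$row[k], sources$col[k]], sources$time[k])
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!is.finite(dist[i, j])) next
      for (d in seq_along(offs)) {
        ii <- i + offs[[d]][1]; jj <- j + offs[[d]][2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!map$mask[i, j] || !map$mask[ii, jj]) next
        if (sprintf("%d_%d_%d_%d", i, j, ii, jj) %in% excl_key) next
        dd <- g$dirs[[d]]
        cost <- dd$cost[(j - 1) * nr + i]
        if (!is.finite(cost)) next
        t <- dist[i, j] + cost
        if (t < dist[ii, jj] - 1e-12) {
          dist[ii, jj] <- t
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist[!is.finite(dist)] <- NA_real_
  dist
}

# random small thickness map for property tests
random_map <- function(n = 7, spacing = 1, tmin = 200, tmax = 1500) {
  thickness_map(matrix(stats::runif(n * n, tmin, tmax), n, n),
                spacing = spacing)
}

# The study geometry: the thin-channel border zone resolved at 0.5 mm so
# the 1.5 mm lateral ramps are represented at their true length, with the
# stimulus in the thick field beyond the gradual (exit) end.
study_map <- function() make_isthmus_map(isthmus_spec(), c(61, 91), 0.5)
study_site <- function() c(31L, 85L)  # x = 42 mm, y = 15 mm

edge_key <- function(df)
  sprintf("%d_%d_%d_%d", df$from_row, df$from_col, df$to_row, df$to_col)
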