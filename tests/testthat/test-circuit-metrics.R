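# A hand-constructable rectangular circuit: isthmus along the x axis from
# x = 0 (distal end) to x = 20, half-width 5, stimulus beyond the distal...
# the proximal (exit) end at x = 35. The UBL caps the distal fraction
# `frac` of the isthmus on three sides, offset laterally by `off`.
rect_geometry <- function(frac = 0.4, off = 0, stim = c(35, 0)) {
  lat1 <- data.frame(x = c(0, 20), y = c(5, 5))
  lat2 <- data.frame(x = c(0, 20), y = c(-5, -5))
  xe <- 20 * frac
  ubl <- data.frame(
    x = c(xe, 0, 0, xe),
    y = c(5 + off, 5 + off, -5 - off, -5 - off))
  circuit_geometry(stim, ubl, list(lat1, lat2))
}

test_that("a UBL capping the distal 40 percent and touching both lateral
           lines gives zero error and 40 percent overlap", {
  g <- rect_geometry(frac = 0.4, off = 0)
  meas <- measure_circuit(g)
  expect_equal(meas$e, 0)
  expect_equal(meas$d_over_c, 40)
  expect_equal(meas$c_len, 20)
  expect_equal(meas$b, 8)
  expect_equal(meas$d, 8)
  expect_equal(meas$a, sqrt((35 - 8)^2 + 25))
})

test_that("a UBL displaced 3 mm laterally from both isthmus boundaries
           measures e = 3 mm", {
  g <- rect_geometry(frac = 0.4, off = 3)
  expect_equal(measure_circuit(g)$e, 3)
})

test_that("the leading edge of a UBL capping the distal half projects to
           50 percent of the isthmus length", {
  g <- rect_geometry(frac = 0.5)
  expect_equal(leading_edge_position(g), 50)
  expect_equal(leading_edge_position(rect_geometry(frac = 0.25)), 25)
})

test_that("all circuit measurements are invariant under rigid motion", {
  g0 <- rect_geometry(frac = 0.35, off = 1.5)
  m0 <- measure_circuit(g0)
  p0 <- leading_edge_position(g0)
  set.seed(5)
  for (rep in 1:10) {
    ang <- runif(1, 0, 2 * pi)
    tr <- runif(2, -40, 40)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    move_poly <- function(p) {
      q <- as.matrix(p[, c("x", "y")]) %*% t(R)
      data.frame(x = q[, 1] + tr[1], y = q[, 2] + tr[2])
    }
    g1 <- circuit_geometry(as.numeric(R %*% g0$stimulus_site + tr),
                           move_poly(g0$ubl),
                           lapply(g0$lateral_lines, move_poly))
    expect_equal(measure_circuit(g1), m0, tolerance = 1e-9)
    expect_equal(leading_edge_position(g1), p0, tolerance = 1e-9)
  }
})

test_that("degenerate polylines are rejected", {
  expect_error(circuit_geometry(c(0, 0), data.frame(x = 1, y = 1),
                                list(data.frame(x = c(0, 1), y = c(0, 0)),
                                     data.frame(x = c(0, 1), y = c(2, 2)))),
               "polyline")
})

test_that("the shipped per-experiment tables reproduce the pooled
           measurement statistics", {
  tabs <- experiment_tables()
  expect_identical(nrow(tabs$measurements), 12L)
  expect_identical(nrow(tabs$cycle_lengths), 12L)
  s1 <- summarize_experiments(tabs$measurements)
  expect_equal(round(as.numeric(s1["mean", c("a", "b", "c", "d", "d_over_c")]), 2),
               c(31.36, 10.70, 23.12, 8.92, 38.45))
  expect_equal(round(as.numeric(s1["sd", c("a", "b", "c", "d", "d_over_c")]), 2),
               c(14.18, 5.73, 9.34, 4.49, 9.69))
  s2 <- summarize_experiments(tabs$cycle_lengths)
  expect_equal(round(as.numeric(s2["mean", c("ps", "vt", "reexcitation")]), 1),
               c(164.6, 190.7, 150.9))
  expect_equal(round(as.numeric(s2["sd", c("ps", "vt", "reexcitation")]), 1),
               c(11.0, 20.4, 26.7))
})

test_that("reexcitation-shorter counting uses a strict inequality", {
  tabs <- experiment_tables()
  expect_identical(count_reexcitation_shorter(tabs$cycle_lengths), 8L)
  expect_identical(
    count_reexcitation_shorter(data.frame(ps = c(170, 150),
                                          reexcitation = c(170, 150))), 0L)
  expect_identical(
    count_reexcitation_shorter(data.frame(ps = 170, reexcitation = 103)), 1L)
})

test_that("summaries of constant columns have zero dispersion and small
           inputs are rejected", {
  s <- summarize_experiments(data.frame(v = c(5, 5, 5)))
  expect_equal(s["mean", "v"], 5)
  expect_equal(s["sd", "v"], 0)
  expect_error(summarize_experiments(data.frame(v = 1)), "at least 2")
})
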