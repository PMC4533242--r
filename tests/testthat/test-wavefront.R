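test_that("activation on a uniform map matches the closed form r/theta_o
           within the 8-connectivity metric bound", {
  m <- make_uniform_map(1440, c(21, 21), 1)
  src <- data.frame(row = 11, col = 11, time = 0)
  res <- simulate_cycle(m, sources = src, cycle_length = 300)
  tm <- res$activation_time
  expect_true(all(!is.na(tm)))
  expect_equal(nrow(res$blocked_edges), 0L)
  theta_o <- 0.4
  for (i in seq_len(21)) for (j in seq_len(21)) {
    dx <- abs(j - 11); dy <- abs(i - 11)
    eucl <- sqrt(dx^2 + dy^2)
    octile <- max(dx, dy) + (sqrt(2) - 1) * min(dx, dy)
    expect_gte(tm[i, j], eucl / theta_o - 1e-9)
    expect_lte(tm[i, j], octile / theta_o + 1e-9)
  }
})

test_that("marching activation times equal exhaustive relaxation over the
           same edge-speed graph on random small maps", {
  set.seed(11)
  for (rep in 1:25) {
    m <- random_map(sample(4:7, 1))
    src <- data.frame(row = sample(nrow(m$values), 1),
                      col = sample(ncol(m$values), 1), time = 0)
    got <- simulate_cycle(m, sources = src, cycle_length = 150)
    want <- oracle_activation(m, src, 150)
    expect_equal(got$activation_time, want, tolerance = 1e-9)
  }
})

test_that("activation times are invariant to the order in which tied
           queue entries are settled", {
  m <- make_uniform_map(800, c(9, 9), 1)
  src <- data.frame(row = 5, col = 5, time = 0)
  base <- simulate_cycle(m, sources = src, cycle_length = 200)
  set.seed(3)
  for (rep in 1:5) {
    shuf <- simulate_cycle(m, sources = src, cycle_length = 200,
                           tie_shuffle = TRUE)
    expect_equal(shuf$activation_time, base$activation_time,
                 tolerance = 1e-12)
  }
})

test_that("activation is causal: every non-source node is later than some
           neighbor it could have been activated from", {
  set.seed(19)
  m <- random_map(7)
  src <- data.frame(row = 2, col = 3, time = 0)
  tm <- simulate_cycle(m, sources = src, cycle_length = 150)$activation_time
  for (i in 1:7) for (j in 1:7) {
    if (is.na(tm[i, j]) || (i == 2 && j == 3)) next
    nb <- expand.grid(r = i + (-1:1), c = j + (-1:1))
    nb <- nb[(nb$r != i | nb$c != j) &
               nb$r >= 1 & nb$r <= 7 & nb$c >= 1 & nb$c <= 7, ]
    expect_true(any(tm[cbind(nb$r, nb$c)] < tm[i, j], na.rm = TRUE))
  }
})

test_that("block across a steep thin-to-thick step is one-directional:
           the reverse thick-to-thin traversal conducts", {
  vals <- matrix(231, 5, 12)
  vals[, 7] <- 835.5
  vals[, 8:12] <- 1440
  m <- thickness_map(vals, spacing = 1)
  thin_src <- data.frame(row = 3, col = 1, time = 0)
  fwd <- simulate_cycle(m, sources = thin_src, cycle_length = 150)
  expect_true(all(is.na(fwd$activation_time[, 8:12])))
  expect_gt(nrow(fwd$blocked_edges), 0L)
  thick_src <- data.frame(row = 3, col = 12, time = 0)
  rev <- simulate_cycle(m, sources = thick_src, cycle_length = 150)
  expect_true(all(!is.na(rev$activation_time)))
})

test_that("the curvature-excluded edge set only grows as the cycle length
           shortens", {
  m <- study_map()
  sets <- lapply(c(300, 200, 150, 117),
                 function(cl) edge_key(blocked_edge_set(m, cl)))
  for (k in 1:3)
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  expect_length(sets[[1]], 0L)
})

test_that("a premature stimulus from the gradual end induces
           figure-of-eight reentry with a reversed isthmus wavefront,
           while a non-premature one does not", {
  m <- study_map()
  prot <- stimulus_protocol(site = study_site(), s1_interval = 300,
                            s2_interval = 150)
  res <- run_premature_protocol(m, protocol = prot)
  expect_true(res$induced)
  labs <- vapply(res$block_lines, function(p) attr(p, "label"), "")
  expect_identical(sum(labs == "UBL"), 1L)
  expect_identical(sum(labs == "lateral"), 2L)
  # S2 travels exit -> entrance (decreasing x), V1 the reverse
  s2 <- res$cycles$s2$activation_time
  v1 <- res$cycles$v1$activation_time
  ch_cols <- seq(21, 61, by = 2)  # x in [10, 30], inside the channel
  expect_lt(cor(ch_cols, s2[31, ch_cols]), -0.99)
  expect_gt(cor(ch_cols, v1[31, ch_cols]), 0.99)
  expect_lt(res$reexcitation_interval, prot$s2_interval)
  expect_gte(res$reexcitation_interval, res$refractory$erp)
  # non-premature control: long S2 produces no block, no reentry
  ctrl <- run_premature_protocol(
    m, protocol = stimulus_protocol(site = study_site(),
                                    s1_interval = 320, s2_interval = 300))
  expect_false(ctrl$induced)
  expect_identical(nrow(ctrl$blocked_edges), 0L)
})

test_that("the UBL polyline caps the steep entrance end on three sides", {
  m <- study_map()
  res <- run_premature_protocol(
    m, protocol = stimulus_protocol(site = study_site(), s1_interval = 300,
                                    s2_interval = 150))
  labs <- vapply(res$block_lines, function(p) attr(p, "label"), "")
  ubl <- res$block_lines[[which(labs == "UBL")]]
  # distal edge: vertices spanning the channel width just before x = 8
  cap <- ubl[abs(ubl$x - 7.75) < 1e-6, ]
  expect_gte(nrow(cap), 2L)
  expect_lt(min(cap$y), 11)
  expect_gt(max(cap$y), 19)
  # lateral margins on both sides near the entrance
  for (yb in c(9.75, 20.25)) {
    marg <- ubl[abs(ubl$y - yb) < 1e-6 & ubl$x < 15, ]
    expect_gte(nrow(marg), 2L)
  }
  # leading edge faces the stimulus
  le <- attr(ubl, "leading_edge")
  expect_true(le[1] >= max(ubl$x) - 1e-6)
})

test_that("an unreachable source region reports an empty map rather than
           an error", {
  vals <- matrix(1440, 5, 5)
  vals[3, 3] <- 100  # dT/T = 13.4 in every direction: statically blocked
  m <- thickness_map(vals)
  res <- simulate_cycle(m, sources = data.frame(row = 3, col = 3, time = 0),
                        cycle_length = 150)
  expect_identical(sum(!is.na(res$activation_time)), 1L)
  expect_gt(nrow(res$blocked_edges), 0L)
})

test_that("block lines from a uniform run are empty", {
  m <- make_uniform_map(1000, c(9, 9), 1)
  res <- run_premature_protocol(
    m, protocol = stimulus_protocol(site = c(5, 5), s1_interval = 300,
                                    s2_interval = 150))
  expect_false(res$induced)
  expect_length(res$block_lines, 0L)
})
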