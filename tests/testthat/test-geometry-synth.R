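test_that("uniform maps are constant with an identically zero dT field", {
  m <- make_uniform_map(1440, c(40, 40), 1)
  expect_true(all(m$values == 1440))
  expect_true(all(m$mask))
  expect_true(all(delta_T_field(m, 1) == 0))
  expect_error(make_uniform_map(-5, c(10, 10)), "positive")
  expect_error(make_uniform_map(100, c(2, 10)), ">= 3")
})

test_that("isthmus maps are bounded, ramp monotonically, and honor the
           entrance/exit steepness ordering", {
  spec <- isthmus_spec()
  m <- make_isthmus_map(spec, c(31, 46), 1)
  expect_gte(min(m$values), spec$T_isthmus)
  expect_lte(max(m$values), spec$T_outer)
  # along the channel axis (row y = 15) thickness is non-decreasing
  # outward from the thinnest node through each end
  prof <- m$values[16, ]
  thin <- which(prof == min(prof))
  expect_true(all(diff(prof[min(thin):1]) >= 0))
  expect_true(all(diff(prof[max(thin):length(prof)]) >= 0))
  # steeper entrance: max |gradient| at the entrance end >= exit end
  grad <- abs(diff(prof))
  expect_gte(max(grad[1:min(thin)]), max(grad[max(thin):(length(prof) - 1)]))
})

test_that("a 1 mm entrance ramp reproduces the border-zone thickness ratio
           when sampled one space step from the thinnest node", {
  spec <- isthmus_spec(entrance_transition_length = 1,
                       exit_transition_length = 6)
  m <- make_isthmus_map(spec, c(31, 46), 1)
  dT <- delta_T_field(m, c = 1)
  ratio <- dT / m$values
  # entrance axis: channel starts at x = 8 (col 9)
  expect_equal(ratio[16, 9], (1440 - 231) / 231, tolerance = 1e-12)
  expect_equal(round(max(ratio, na.rm = TRUE), 2), 5.23)
})

test_that("a 2 mm entrance ramp rises from 231 to 1440 um within a 2 mm
           band, read off the generated profile", {
  m <- make_isthmus_map(isthmus_spec(entrance_transition_length = 2),
                        c(31, 46), 1)
  prof <- m$values[16, ]
  expect_equal(prof[9], 231)           # channel start x = 8
  expect_equal(prof[7], 1440)          # 2 mm before the entrance
  expect_true(all(diff(prof[7:9]) < 0))
})

test_that("symmetric channel specs generate maps symmetric under 180-degree
           rotation about the channel center", {
  spec <- isthmus_spec(channel_start = c(12, 15), channel_end = c(33, 15),
                       entrance_transition_length = 3,
                       exit_transition_length = 3)
  m <- make_isthmus_map(spec, c(31, 46), 1)
  rot <- m$values[nrow(m$values):1, ncol(m$values):1]
  expect_equal(m$values, rot, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("isthmus spec enforces its invariants", {
  expect_error(isthmus_spec(T_isthmus = 1500), "less than")
  expect_error(isthmus_spec(entrance_transition_length = 7,
                            exit_transition_length = 3), "steep end")
  expect_error(make_isthmus_map(isthmus_spec(channel_start = c(0.5, 15)),
                                c(31, 46), 1), "margin")
})

test_that("raster round trip preserves values, spacing, and mask", {
  spec <- isthmus_spec()
  m <- make_isthmus_map(spec, c(61, 91), 0.5)
  m$values[5, 5] <- NA
  m$mask[5, 5] <- FALSE
  f <- withr::local_tempfile(fileext = ".tsv")
  write_map(m, f)
  m2 <- read_map(f)
  expect_equal(m2$values[m2$mask], m$values[m$mask])
  expect_identical(m2$mask, m$mask)
  expect_identical(m2$spacing, 0.5)
})

test_that("malformed rasters are rejected with cell coordinates and a
           missing header falls back to 1 mm with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# spacing_mm=1", "100\t200", "100\tzap"), f)
  expect_error(read_map(f), "row 2, column 2")
  writeLines(c("# spacing_mm=1", "100\t200\t300", "100\t200"), f)
  expect_error(read_map(f), "ragged")
  writeLines(c("100\t200\t300", "100\t200\t300", "100\t200\t300"), f)
  expect_warning(m <- read_map(f), "assuming 1 mm")
  expect_identical(m$spacing, 1)
})
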