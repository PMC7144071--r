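test_that("melt_curve validates its series", {
  tt <- seq(70, 90, by = 0.1)
  expect_s3_class(melt_curve("A1", tt, rev(seq_along(tt))), "melt_curve")
  expect_error(melt_curve("A1", c(tt, 75), c(rev(seq_along(tt)), 1)),
               "strictly increasing")
  expect_error(melt_curve("A1", tt[1:5], 1:5), "fewer than 10")
  expect_error(melt_curve("A1", tt, seq_along(tt)[-1]), "same length")
})

test_that("normalization is an exact min-max affine map", {
  tt <- seq(70, 79, by = 1)
  cu <- melt_curve("A1", tt, c(100, 600, 1100, rep(100, 7)))
  nn <- normalize_curve(cu)
  expect_equal(nn$rfu[1:3], c(0, 0.5, 1))
  expect_equal(min(nn$rfu), 0)
  expect_equal(max(nn$rfu), 1)
  expect_identical(nn$temperature, cu$temperature)
  # guard against double normalization and degenerate (NTC-like) traces
  expect_error(normalize_curve(nn), "already normalized")
  expect_error(normalize_curve(melt_curve("H12", tt, rep(3, 10))),
               "degenerate")
})

test_that("Tm is the sigmoid centre on analytic curves", {
  for (centre in c(75, 81.5, 88)) {
    cu <- sigmoid_curve("A1", centre)
    expect_lt(abs(melting_temperature(cu) - centre), 0.01 + 1e-9)
  }
  expect_error(melting_temperature(sigmoid_curve("A1", 81, normalized = FALSE)),
               "normalized")
})

test_that("Tm is invariant to affine rescaling of the raw fluorescence", {
  tt <- seq(70, 90, by = 0.1)
  base <- 1 / (1 + exp((tt - 81.3) / 0.4))
  tm1 <- melting_temperature(normalize_curve(melt_curve("A1", tt, 900 * base + 120)))
  tm2 <- melting_temperature(normalize_curve(melt_curve("A1", tt, 55 * base + 3)))
  expect_equal(tm1, tm2)
})

test_that("a two-allele mixture melts between the pure-allele Tms", {
  tt <- seq(70, 90, by = 0.1)
  mix <- 0.5 / (1 + exp((tt - 81.0) / 0.4)) + 0.5 / (1 + exp((tt - 82.1) / 0.4))
  cu <- normalize_curve(melt_curve("A1", tt, mix))
  tm <- melting_temperature(cu)
  expect_gte(tm, 81.0)
  expect_lte(tm, 82.1)
})

test_that("difference curves subtract pointwise and are antisymmetric", {
  ctrl <- sigmoid_curve("C1", 81)
  self <- difference_curve(ctrl, ctrl)
  expect_equal(self$diff, rep(0, length(ctrl$temperature)))

  other <- sigmoid_curve("B1", 82.1)
  d_ab <- difference_curve(ctrl, other)
  d_ba <- difference_curve(other, ctrl)
  expect_equal(d_ab$diff, -d_ba$diff)

  short <- sigmoid_curve("E1", 81, grid = seq(70, 90, by = 0.2))
  expect_error(difference_curve(short, ctrl), "grids")
})

test_that("one-point difference propagates exactly", {
  grid <- seq(70, 79, by = 1)
  a <- melt_curve("A1", grid, c(0, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1),
                  normalized = TRUE)
  b_r <- a$rfu; b_r[4] <- b_r[4] + 0.1
  b <- melt_curve("B1", grid, b_r)
  b$normalized <- TRUE
  d <- difference_curve(b, a)
  expect_equal(d$diff[4], 0.1)
  expect_equal(d$diff[-4], rep(0, 9))
})

test_that("discriminating temperature maximizes the 0-vs-1 separation", {
  grid <- seq(70, 90, by = 0.1)
  sep <- exp(-(grid - 81.6)^2 / 0.5)          # peaked exactly at 81.6
  d1 <- flat_diff(rep(0, length(grid)), grid, "S1")
  d0 <- flat_diff(sep, grid, "S0")
  dmid <- flat_diff(sep / 2, grid, "S5")
  expect_equal(select_discriminating_temperature(list(d0, dmid, d1),
                                                 c(0, 0.5, 1)), 81.6)
  # oracle: exhaustive scan over the grid
  expect_equal(grid[which.max(abs(sep - 0))], 81.6)
  # invariant to the order of the standards
  expect_equal(select_discriminating_temperature(list(d1, d0, dmid),
                                                 c(1, 0, 0.5)), 81.6)
  expect_error(select_discriminating_temperature(list(d0, dmid), c(0, 0.5)),
               "0 and 1")
  # degenerate: identical endpoint series -> warning, lowest grid temperature
  expect_warning(
    tie <- select_discriminating_temperature(list(d0, d0), c(0, 1)),
    "identical")
  expect_equal(tie, grid[1])
})

test_that("signal_at interpolates linearly and checks bounds", {
  grid <- seq(70, 90, by = 0.1)
  vals <- rep(0, length(grid))
  vals[grid == 81.6] <- 0.30
  d <- flat_diff(vals, grid)
  expect_equal(signal_at(d, 81.6), 0.30)
  d2 <- flat_diff(seq(0.2, 0.4, length.out = length(grid)), grid)
  expect_equal(signal_at(d2, 80), (0.2 + 0.4) / 2)
  expect_error(signal_at(d, 69.0), "outside")
})

test_that("curves interpolate onto a reference grid", {
  cu <- sigmoid_curve("A1", 81, grid = seq(70, 90, by = 0.1))
  g2 <- seq(70.05, 89.95, by = 0.1)
  al <- align_to_grid(cu, g2)
  expect_equal(al$temperature, g2)
  expect_lt(max(abs(al$rfu - 1 / (1 + exp((g2 - 81) / 0.4)))), 2e-3)
  expect_error(align_to_grid(cu, seq(69, 90, by = 0.1)), "beyond")
})
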