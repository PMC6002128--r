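test_that("front position interpolates the outermost threshold crossing", {
  x <- seq(0, 20, by = 0.1)
  step_at <- function(x0) ifelse(x <= x0, 1, 0)
  # translating step recovered to interpolation accuracy
  pos <- vapply(c(5, 8.24, 13.57), function(x0)
    front_position(x, step_at(x0), 0.1), numeric(1))
  expect_equal(pos, c(5, 8.24, 13.57) + 0.1 * 0.9, tolerance = 0.11)
  expect_true(is.na(front_position(x, rep(0, length(x)))))
  # smooth ramp: exact linear interpolation
  rho <- pmax(1 - x / 10, 0)
  expect_equal(front_position(x, rho, 0.25), 7.5, tolerance = 1e-10)
})

test_that("front speed of a translating profile is exact", {
  x <- seq(0, 100, by = 0.1)
  v <- 2.5 / 3600  # mm/s
  snaps <- lapply(seq(0, 20 * 3600, by = 3600), function(t)
    list(t = t, rho = pmax(1 - (x - v * t) / 5, 0)))
  run <- list(x = x, snapshots = snaps)
  expect_equal(front_speed(run, c(10, 20) * 3600), 2.5, tolerance = 1e-6)
  expect_error(front_speed(run, c(1e7, 2e7)), "fewer than 2")
})

test_that("wavelength is exact on synthetic periodic profiles", {
  x <- seq(0, 20, by = 0.01)
  rho <- 1 + cos(2 * pi * x / 5)
  expect_equal(wavelength(x, rho, exclude_front = FALSE), 5, tolerance = 1e-6)
  # two narrow peaks at 3 and 8 mm
  rho2 <- exp(-(x - 3)^2 / 0.02) + exp(-(x - 8)^2 / 0.02)
  expect_equal(wavelength(x, rho2, exclude_front = FALSE), 5, tolerance = 0.01)
  # fewer than two stripes -> undefined
  expect_true(is.na(wavelength(x, exp(-(x - 3)^2 / 0.02),
                               exclude_front = FALSE)))
})

test_that("peak detection honours prominence and front exclusion", {
  x <- seq(0, 30, by = 0.05)
  # three stripes plus a taller moving front at x = 25
  rho <- exp(-(x - 8)^2 / 2) + exp(-(x - 13)^2 / 2) + exp(-(x - 18)^2 / 2) +
    1.2 * exp(-(x - 25)^2 / 2) + 0.02 * sin(40 * x)
  pk <- find_stripe_peaks(x, rho, prominence_frac = 0.1)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$x, c(8, 13, 18), tolerance = 0.1)
  pk_all <- find_stripe_peaks(x, rho, prominence_frac = 0.1,
                              exclude_front = FALSE)
  expect_equal(nrow(pk_all), 4)
  # low-prominence ripples alone are not stripes
  expect_equal(nrow(find_stripe_peaks(x, 1 + 0.02 * sin(40 * x))), 0)
})

test_that("stripe ratios behave on flat and square-wave windows", {
  x <- seq(10, 15, by = 0.001)
  flat <- stripe_window_ratios(x, rep(2, length(x)), c(10, 15))
  expect_equal(flat$height_ratio, 1)
  expect_equal(flat$density_ratio, 1)
  # square wave occupying fraction phi of a narrow annulus (xi-weighting
  # nearly uniform far from the origin)
  phi <- 0.3
  xa <- seq(100, 105, by = 0.001)
  rho <- ifelse(xa >= 102 & xa <= 102 + phi * 5, 1, 0)
  sq <- stripe_window_ratios(xa, rho, c(100, 105), radial = TRUE)
  expect_equal(sq$height_ratio, 0)
  expect_equal(sq$density_ratio, phi, tolerance = 0.01)
})

test_that("stripe structure extracts height and density ratios per stripe", {
  x <- seq(0.5, 30, by = 0.02)
  rho <- 0.6 + 0.4 * cos(2 * pi * x / 6)
  ss <- stripe_structure(x, rho, radial = FALSE)
  expect_gte(ss$n_stripes, 2)
  expect_equal(ss$height_ratio, 0.2 / 1.0, tolerance = 0.01)
  # cosine mean over a period relative to the peak
  expect_equal(ss$density_ratio, 0.6, tolerance = 0.01)
  expect_true(all(ss$stripes$h2 <= ss$stripes$h1))
})

test_that("metrics are stable under grid refinement", {
  for (dx in c(0.05, 0.025)) {
    x <- seq(0, 30, by = dx)
    rho <- 1 + cos(2 * pi * x / 5)
    expect_equal(wavelength(x, rho, exclude_front = FALSE), 5,
                 tolerance = 0.02)
    expect_equal(front_position(x, pmax(1 - x / 20, 0), 0.25), 15,
                 tolerance = 1e-8)
  }
})

test_that("density ratio lies in (0, 1] for nonnegative profiles", {
  set.seed(3)
  x <- seq(1, 25, by = 0.05)
  for (k in 1:5) {
    rho <- abs(stats::filter(rexp(length(x)), rep(1 / 40, 40),
                             circular = TRUE))
    ss <- stripe_structure(x, as.numeric(rho))
    if (ss$n_stripes > 0) {
      expect_gt(ss$density_ratio, 0)
      expect_lte(ss$density_ratio, 1 + 1e-12)
    }
  }
})
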