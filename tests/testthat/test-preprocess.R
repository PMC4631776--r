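test_that("offset subtraction removes the window mean and is idempotent", {
  grid <- seq(1800, 2100, by = 2)
  const <- single_spectrum(grid, rep(3.7, length(grid)))
  out <- subtract_offset(const, c(1900, 1950))
  expect_equal(out$absorbance, rep(0, length(grid)))

  # A(v) = v: subtracted value equals the window's grid-point mean
  ramp <- single_spectrum(grid, grid)
  out2 <- subtract_offset(ramp, c(1900, 1950))
  expected_mean <- mean(grid[grid >= 1900 & grid <= 1950])
  expect_equal(out2$absorbance, grid - expected_mean)

  # idempotence
  wide <- seq(800, 2100, by = 2)
  sp <- single_spectrum(wide, random_smooth_spectrum(wide, 3))
  once <- subtract_offset(sp, c(1900, 1950))
  expect_equal(subtract_offset(once, c(1900, 1950))$absorbance, once$absorbance)

  expect_error(subtract_offset(sp, c(2090.5, 2091)), "no grid points")
})

test_that("integrate_area is an exact trapezoid with interpolated endpoints", {
  grid <- seq(700, 1200, by = 2.5)
  one <- single_spectrum(grid, rep(1, length(grid)))
  expect_equal(integrate_area(one, c(800, 950))$area, 150)
  # window limits off the grid
  expect_equal(integrate_area(one, c(801.3, 949.1))$area, 949.1 - 801.3)

  ramp <- single_spectrum(grid, grid)
  expect_equal(integrate_area(ramp, c(800, 1000))$area, (1000^2 - 800^2) / 2)

  # random smooth spectrum vs an oversampled oracle of the same piecewise
  # linear interpolant
  y <- random_smooth_spectrum(grid, 11)
  sp <- single_spectrum(grid, y)
  fine <- seq(803.7, 1104.2, length.out = 300001)
  yf <- stats::approx(grid, y, xout = fine)$y
  oracle <- sum(diff(fine) * (yf[-1] + yf[-length(yf)]) / 2)
  got <- integrate_area(sp, c(803.7, 1104.2))$area
  expect_equal(got, oracle, tolerance = 1e-6)

  expect_error(integrate_area(sp, c(900, 900)), "lo < hi")
})

test_that("area normalization hits its target, is gain-invariant and idempotent", {
  grid <- seq(700, 2000, by = 2)
  for (s in 1:5) {
    sp <- single_spectrum(grid, random_smooth_spectrum(grid, s))
    norm <- normalize_area(sp, c(800, 1900), target = 1)
    expect_equal(integrate_area(norm, c(800, 1900))$area, 1, tolerance = 1e-10)
    # gain invariance
    gained <- dplyr::mutate(sp, absorbance = absorbance * (1 + s))
    expect_equal(normalize_area(gained, c(800, 1900))$absorbance,
                 norm$absorbance, tolerance = 1e-12)
    # idempotence
    expect_equal(normalize_area(norm, c(800, 1900))$absorbance,
                 norm$absorbance, tolerance = 1e-12)
  }
  flat0 <- single_spectrum(grid, rep(0, length(grid)))
  expect_error(normalize_area(flat0, c(800, 1900)), "non-positive window area")
})

test_that("band_area vanishes on straight lines and matches the erf closed form", {
  grid <- seq(600, 1000, by = 0.1)
  line <- single_spectrum(grid, 0.3 * grid - 12)
  expect_equal(band_area(line, c(740, 800))$area, 0, tolerance = 1e-9)
  const <- single_spectrum(grid, rep(2, length(grid)))
  expect_equal(band_area(const, c(740, 800))$area, 0, tolerance = 1e-12)

  # Gaussian on a sloped baseline: area equals the truncated-Gaussian
  # integral minus the chord correction for the Gaussian's own tails
  amp <- 0.8; ctr <- 800; sig <- 12; lo <- 740; hi <- 860
  y <- amp * exp(-(grid - ctr)^2 / (2 * sig^2)) + 0.002 * grid + 1
  sp <- single_spectrum(grid, y)
  gauss_cdf <- function(x) stats::pnorm((x - ctr) / sig)
  gauss_int <- amp * sig * sqrt(2 * pi) * (gauss_cdf(hi) - gauss_cdf(lo))
  g <- function(x) amp * exp(-(x - ctr)^2 / (2 * sig^2))
  chord <- (hi - lo) * (g(lo) + g(hi)) / 2  # baseline picks up the tails
  expect_equal(band_area(sp, c(lo, hi))$area, gauss_int - chord,
               tolerance = 1e-4)

  # invariance to adding any global straight line
  for (s in 1:5) {
    y0 <- random_smooth_spectrum(grid, s)
    a <- stats::rnorm(1); b <- stats::rnorm(1, sd = 0.01)
    base <- band_area(single_spectrum(grid, y0), c(700, 950))$area
    shifted <- band_area(single_spectrum(grid, y0 + a + b * grid), c(700, 950))$area
    expect_equal(shifted, base, tolerance = 1e-8)
  }
})

test_that("Savitzky-Golay derivative reproduces polynomials and is linear", {
  grid <- seq(1000, 1500, by = 2)
  const <- single_spectrum(grid, rep(5, length(grid)))
  expect_equal(first_derivative(const)$absorbance, rep(0, length(grid)))

  lin <- single_spectrum(grid, 0.37 * grid - 4)
  expect_equal(first_derivative(lin)$absorbance, rep(0.37, length(grid)),
               tolerance = 1e-10)

  # low-frequency sine: interior points track the analytic cosine
  f <- 2 * pi / 300
  sine <- single_spectrum(grid, sin(f * grid))
  d <- first_derivative(sine)$absorbance
  interior <- 10:(length(grid) - 10)
  expect_lt(max(abs(d[interior] - f * cos(f * grid[interior]))), 0.01 * f)

  # linearity: D(aX + bY) = aD(X) + bD(Y)
  x <- random_smooth_spectrum(grid, 21); y <- random_smooth_spectrum(grid, 22)
  dx <- first_derivative(single_spectrum(grid, x))$absorbance
  dy <- first_derivative(single_spectrum(grid, y))$absorbance
  dxy <- first_derivative(single_spectrum(grid, 2 * x - 0.5 * y))$absorbance
  expect_equal(dxy, 2 * dx - 0.5 * dy, tolerance = 1e-10)

  expect_error(first_derivative(sine, window_pts = 8), "odd")
  expect_error(first_derivative(single_spectrum(grid[1:5], rep(1, 5)),
                                window_pts = 9), "exceeds")
})

test_that("offset + normalization exactly cancel gain and offset artefacts", {
  grid <- reduced_grid()
  cfg <- preprocess_config()
  for (s in 1:8) {
    y <- random_smooth_spectrum(grid, s)
    clean <- normalize_area(subtract_offset(single_spectrum(grid, y),
                                            cfg$offset_window),
                            cfg$norm_window)
    g <- exp(stats::rnorm(1, 0, 0.3)); c0 <- stats::rnorm(1, 0, 0.5)
    messy <- normalize_area(subtract_offset(single_spectrum(grid, g * y + c0),
                                            cfg$offset_window),
                            cfg$norm_window)
    expect_equal(messy$absorbance, clean$absorbance, tolerance = 1e-10)
  }
})

test_that("ir_dataset and long-tibble pre-processing agree", {
  grid <- seq(700, 2000, by = 2)
  sp <- dplyr::bind_rows(
    single_spectrum(grid, random_smooth_spectrum(grid, 31), "a"),
    single_spectrum(grid, random_smooth_spectrum(grid, 32), "b"))
  ds <- build_dataset(sp, toy_manifest(c("a", "b")), grid = grid)
  ds_out <- preprocess(ds, derivative = TRUE)
  tb_out <- sp |>
    subtract_offset(c(1900, 1950)) |>
    normalize_area(c(800, 1900)) |>
    first_derivative()
  expect_equal(as.vector(t(ds_out$absorbance)), tb_out$absorbance,
               tolerance = 1e-12)
  ba_ds <- band_area(normalize_area(subtract_offset(ds), c(800, 1900)),
                     marker_panel())
  ba_tb <- band_area(normalize_area(subtract_offset(sp), c(800, 1900)),
                     marker_panel())
  expect_equal(dplyr::arrange(ba_ds, spectrum_id, band),
               dplyr::arrange(ba_tb, spectrum_id, band), tolerance = 1e-12)
})
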