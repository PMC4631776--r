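test_that("pseudo-Voigt rendering honours amplitude and FWHM definitions", {
  grid <- seq(900, 1100, by = 0.25)
  g <- render_component(tibble::tibble(center = 1000, fwhm = 20, amplitude = 0.8,
                                       gauss_fraction = 1), grid)
  expect_equal(g[grid == 1000], 0.8)
  expect_equal(g[grid == 990], 0.4)   # center - FWHM/2
  expect_equal(g[grid == 1010], 0.4)  # center + FWHM/2
  l <- render_component(tibble::tibble(center = 1000, fwhm = 20, amplitude = 0.8,
                                       gauss_fraction = 0), grid)
  expect_equal(l[grid == 1000], 0.8)
  expect_equal(l[grid == 990], 0.4)
  expect_equal(l[grid == 1010], 0.4)
})

test_that("pseudo-Voigt numerical area matches the closed form", {
  # wide grid so Lorentzian tails are captured
  grid <- seq(-4000, 6000, by = 0.5)
  amp <- 0.6; fwhm <- 24; gf <- 0.7
  y <- render_component(tibble::tibble(center = 1000, fwhm = fwhm,
                                       amplitude = amp, gauss_fraction = gf),
                        grid)
  num <- sum(0.5 * (y[-1] + y[-length(y)])) * 0.5
  gauss_area <- amp * (fwhm / 2) * sqrt(pi / log(2))
  lorentz_area <- amp * pi * (fwhm / 2)
  expect_equal(num, gf * gauss_area + (1 - gf) * lorentz_area,
               tolerance = 1e-3)
})

test_that("simulation is deterministic and noiseless limits are exact", {
  cc <- tibble::tibble(species = rep(c("X", "Y"), each = 2),
                       genus = rep(c("X", "Y"), each = 2), family = "F",
                       sample_type = "cocoon_inner",
                       component = rep(c("fibroin_An", "sericin"), 2),
                       concentration = c(1, 0.3, 0.5, 0.8))
  noiseless <- scenario(cc, n_per = 3, grid = seq(700, 2000, by = 5),
                        within_species_cv = 0, gain_log_sd = 0,
                        baseline_offset_sd = 0, baseline_slope_sd = 0,
                        noise_sd = 0)
  sim <- simulate_spectra(noiseless, seed = 5)
  m <- sim$dataset$absorbance
  expect_equal(m[1, ], m[2, ])  # replicates identical
  expect_equal(m[2, ], m[3, ])
  expect_false(isTRUE(all.equal(m[1, ], m[4, ])))  # species differ

  noisy <- scenario(cc, n_per = 3, grid = seq(700, 2000, by = 5))
  s1 <- simulate_spectra(noisy, seed = 11)
  s2 <- simulate_spectra(noisy, seed = 11)
  expect_identical(s1$dataset$absorbance, s2$dataset$absorbance)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_spectra(noisy, seed = 12)
  expect_false(identical(s1$dataset$absorbance, s3$dataset$absorbance))
})

test_that("empirical white-noise level matches the scenario noise_sd", {
  cc <- tibble::tibble(species = c("X", "Y"), genus = c("X", "Y"), family = "F",
                       sample_type = "cocoon_inner", component = "fibroin_An",
                       concentration = 1)
  sc <- scenario(cc, n_per = 500, grid = seq(940, 990, by = 1),
                 within_species_cv = 0, gain_log_sd = 0,
                 baseline_offset_sd = 0, baseline_slope_sd = 0,
                 noise_sd = 0.01)
  sim <- simulate_spectra(sc, seed = 21)
  # replicates of one species share the exact signal, so the per-point
  # spread across 500 replicates is the noise alone
  eps <- sim$dataset$absorbance[1:500, ]
  per_point_sd <- apply(eps, 2, stats::sd)
  expect_equal(mean(per_point_sd), 0.01, tolerance = 0.05)
})

test_that("marker band areas are linear in the generating concentration", {
  levels <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  cc <- dplyr::bind_rows(lapply(seq_along(levels), function(i) {
    tibble::tibble(species = sprintf("L%d", i), genus = "G", family = "F",
                   sample_type = "cocoon_inner",
                   component = c("fibroin_An", "sericin"),
                   concentration = c(1, levels[i]))
  }))
  sc <- scenario(cc, n_per = 1, grid = reduced_grid(), within_species_cv = 0,
                 gain_log_sd = 0, baseline_offset_sd = 0,
                 baseline_slope_sd = 0, noise_sd = 0)
  sim <- simulate_spectra(sc, seed = 1)
  areas <- quantify_markers(sim$dataset)
  ser <- areas[areas$marker == "sericin", ]
  fit <- stats::lm(ser$area ~ levels)
  # the least-squares slope recovers the unit-concentration band area
  unit <- render_component(
    peak_library()[peak_library()$component == "sericin", ], reduced_grid())
  unit_area <- band_area(single_spectrum(reduced_grid(), unit),
                         c(1384, 1403))$area
  expect_equal(unname(stats::coef(fit)[2]), unit_area, tolerance = 0.01)
  expect_lt(abs(stats::coef(fit)[1]) / max(ser$area), 0.01)
})

test_that("scenario validation rejects malformed inputs before sampling", {
  cc <- tibble::tibble(species = c("X", "Y"), genus = c("X", "Y"), family = "F",
                       sample_type = "cocoon_inner", component = "fibroin_An",
                       concentration = 1)
  expect_error(scenario(dplyr::mutate(cc, sample_type = "inner")),
               "invalid sample_type")
  expect_error(scenario(dplyr::mutate(cc, concentration = -1)), ">= 0")
  expect_error(scenario(dplyr::mutate(cc, component = "mystery_goo")),
               "mystery_goo")
  expect_error(scenario(cc[1, ]), ">= 2 species")
  expect_error(scenario(cc, noise_sd = -1), ">= 0")
  expect_error(scale_noise(scenario(cc), -2), "multiplier")
})

test_that("the default cocoon scenario has the documented design", {
  sc <- paperlike_scenario()
  cc <- sc$concentrations
  expect_equal(length(unique(cc$species)), 35)
  expect_equal(length(unique(cc$genus)), 5)
  expect_equal(sort(unique(cc$sample_type)), c("cocoon_inner", "cocoon_outer"))
  # 35 species x 2 layers x 18 replicates
  sim <- simulate_spectra(paperlike_scenario(grid = reduced_grid(500, 2000)),
                          seed = 3)
  expect_equal(nrow(sim$dataset$absorbance), 35 * 2 * 18)
  expect_equal(nrow(sim$dataset$manifest), 1260)
  # scenario construction itself is deterministic
  expect_identical(paperlike_scenario()$concentrations, cc)
})

test_that("the latent mixture controls its rank and noise share", {
  lm10 <- simulate_latent_mixture(n_spectra = 30, seed = 4)
  expect_equal(dim(lm10$weights), c(30L, 10L))
  # noiseless version has matrix rank exactly n_components
  lm0 <- simulate_latent_mixture(n_spectra = 30, noise_frac = 0, seed = 4)
  sv <- svd(scale(lm0$dataset$absorbance, scale = FALSE))$d
  expect_lt(sv[11] / sv[1], 1e-10)
  expect_gt(sv[10] / sv[1], 1e-10)
  expect_identical(simulate_latent_mixture(seed = 9)$dataset$absorbance,
                   simulate_latent_mixture(seed = 9)$dataset$absorbance)
})
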