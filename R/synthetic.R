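#' Default pseudo-Voigt peak library for silk spectral components
#'
#' Peak positions follow the standard silk band assignments: the
#' poly-alanine (A)n beta-sheet marker at 961 cm^-1 with its amide I/II/III
#' envelope (1620, 1699, 1508, 1230 cm^-1); the weaker poly(alanine-glycine)
#' (AG)n pair at 975 and 998 cm^-1; the helix/random-coil feedstock
#' envelope (1642, 1547, 1308, 1270, 1245 cm^-1) that vanishes on spinning;
#' sericin serine/C-O modes (1395, 1058, 1075 cm^-1); calcium oxalate at
#' 1315 and 779 cm^-1; phenolic/tannin modes near 1103 and 1733 cm^-1; and
#' broad water bands. Widths (FWHM 10-40 cm^-1 in the fingerprint, broad
#' for water) and relative amplitudes are free parameters of the simulator,
#' fixed here as a versioned library; band positions only are constrained
#' by the assignments.
#'
#' @return Tibble `component`, `center`, `fwhm`, `amplitude`,
#'   `gauss_fraction`.
#' @export
peak_library <- function() {
  tibble::tribble(
    ~component,              ~center, ~fwhm, ~amplitude, ~gauss_fraction,
    "fibroin_An",             961,     14,    0.60,       0.7,
    "fibroin_An",             1230,    30,    0.30,       0.7,
    "fibroin_An",             1508,    25,    0.55,       0.7,
    "fibroin_An",             1620,    28,    1.00,       0.7,
    "fibroin_An",             1699,    20,    0.25,       0.7,
    "fibroin_AGn",            975,     12,    0.20,       0.7,
    "fibroin_AGn",            998,     12,    0.35,       0.7,
    "fibroin_AGn",            1230,    30,    0.30,       0.7,
    "fibroin_AGn",            1508,    25,    0.55,       0.7,
    "fibroin_AGn",            1620,    28,    0.95,       0.7,
    "fibroin_AGn",            1699,    20,    0.20,       0.7,
    "helix_coil_feedstock",   1245,    28,    0.35,       0.7,
    "helix_coil_feedstock",   1270,    22,    0.20,       0.7,
    "helix_coil_feedstock",   1308,    20,    0.30,       0.7,
    "helix_coil_feedstock",   1547,    30,    0.60,       0.7,
    "helix_coil_feedstock",   1642,    35,    1.00,       0.7,
    "sericin",                1058,    25,    0.40,       0.7,
    "sericin",                1075,    22,    0.25,       0.7,
    "sericin",                1395,    18,    0.50,       0.7,
    "sericin",                1535,    30,    0.45,       0.7,
    "sericin",                1650,    35,    0.55,       0.7,
    "calcium_oxalate",        779,     12,    0.60,       0.7,
    "calcium_oxalate",        1315,    18,    0.90,       0.7,
    "calcium_oxalate",        1620,    25,    0.35,       0.7,
    "phenolic",               1035,    25,    0.25,       0.7,
    "phenolic",               1103,    25,    0.50,       0.7,
    "phenolic",               1733,    20,    0.25,       0.7,
    "water",                  1642,    40,    0.30,       0.7,
    "water",                  2130,    150,   0.08,       0.7,
    "water",                  3300,    300,   0.80,       0.7
  )
}

#' Render a component spectrum on a wavenumber grid
#'
#' Sums pseudo-Voigt profiles: each peak is
#' `gauss_fraction * Gaussian + (1 - gauss_fraction) * Lorentzian`, both
#' with the given center, full width at half maximum and peak amplitude.
#'
#' @param peaks Tibble with `center`, `fwhm`, `amplitude`, `gauss_fraction`
#'   (one row per peak).
#' @param grid Wavenumber vector (cm^-1).
#' @return Numeric vector of absorbance values, one per grid point.
#' @export
render_component <- function(peaks, grid) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("center", "fwhm", "amplitude", "gauss_fraction") %in% names(peaks)),
            all(peaks$fwhm > 0), all(peaks$amplitude >= 0),
            all(peaks$gauss_fraction >= 0 & peaks$gauss_fraction <= 1))
  y <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    dx <- grid - peaks$center[i]
    hw <- peaks$fwhm[i] / 2
    gauss <- exp(-log(2) * (dx / hw)^2)
    lorentz <- hw^2 / (dx^2 + hw^2)
    y <- y + peaks$amplitude[i] *
      (peaks$gauss_fraction[i] * gauss + (1 - peaks$gauss_fraction[i]) * lorentz)
  }
  y
}

component_basis <- function(library, grid) {
  comps <- unique(library$component)
  B <- t(vapply(comps, function(cn) {
    render_component(library[library$component == cn, ], grid)
  }, numeric(length(grid))))
  rownames(B) <- comps
  B
}

#' Construct a simulation scenario
#'
#' A scenario fixes everything about a simulated study except the random
#' draws: the wavenumber grid, the per-(species, sample_type) component
#' concentration vectors, replicate counts, the replicate-level
#' concentration variability, and the measurement model (multiplicative
#' contact gain, linear baseline drift, additive white noise) whose
#' artefacts the pre-processing chain is designed to remove.
#'
#' @param concentrations Tibble `species`, `genus`, `family`,
#'   `sample_type`, `component`, `concentration` (>= 0; every
#'   species x sample_type needs at least one positive component).
#' @param n_per Replicate spectra per species x sample_type; a single
#'   integer or a tibble `species`, `sample_type`, `n`.
#' @param grid Wavenumber grid.
#' @param within_species_cv Relative s.d. of concentrations between
#'   replicate spectra (lognormal).
#' @param gain_log_sd Lognormal s.d. of the multiplicative contact gain.
#' @param baseline_offset_sd S.d. of the additive baseline offset.
#' @param baseline_slope_sd S.d. of the baseline slope (absorbance per
#'   cm^-1).
#' @param noise_sd S.d. of additive white noise per grid point.
#' @param library Peak library tibble; default [peak_library()].
#' @return An `ir_scenario` list.
#' @export
scenario <- function(concentrations, n_per = 18, grid = default_grid(),
                     within_species_cv = 0.05,
                     gain_log_sd = 0.15, baseline_offset_sd = 0.02,
                     baseline_slope_sd = 2e-5, noise_sd = 0.002,
                     library = peak_library()) {
  sc <- structure(list(
    concentrations = tibble::as_tibble(concentrations),
    n_per = n_per, grid = grid,
    within_species_cv = within_species_cv,
    measurement = list(gain_log_sd = gain_log_sd,
                       baseline_offset_sd = baseline_offset_sd,
                       baseline_slope_sd = baseline_slope_sd,
                       noise_sd = noise_sd),
    library = tibble::as_tibble(library)
  ), class = "ir_scenario")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "ir_scenario"))
  cc <- sc$concentrations
  needed <- c("species", "genus", "family", "sample_type", "component", "concentration")
  missing <- setdiff(needed, names(cc))
  if (length(missing)) {
    stop("scenario concentrations missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(cc$sample_type), sample_types())
  if (length(bad_type)) {
    stop("invalid sample_type in scenario: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (any(cc$concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  bad_comp <- setdiff(unique(cc$component), unique(sc$library$component))
  if (length(bad_comp)) {
    stop("component(s) not in peak library: ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  }
  tot <- stats::aggregate(concentration ~ species + sample_type, data = cc, FUN = sum)
  if (any(tot$concentration <= 0)) {
    stop("every species x sample_type needs at least one positive component",
         call. = FALSE)
  }
  if (length(unique(cc$species)) < 2) {
    stop("a classification scenario needs >= 2 species", call. = FALSE)
  }
  ms <- unlist(sc$measurement)
  if (any(ms < 0) || sc$within_species_cv < 0) {
    stop("all scenario standard deviations must be >= 0", call. = FALSE)
  }
  if (is.numeric(sc$n_per) && length(sc$n_per) == 1) {
    if (sc$n_per < 1) stop("n_per must be >= 1", call. = FALSE)
  } else {
    np <- tibble::as_tibble(sc$n_per)
    stopifnot(all(c("species", "sample_type", "n") %in% names(np)), all(np$n >= 1))
  }
  sc
}

#' @export
print.ir_scenario <- function(x, ...) {
  cc <- x$concentrations
  cat(sprintf("<ir_scenario> %d species, %d genera, sample types: %s\n",
              length(unique(cc$species)), length(unique(cc$genus)),
              paste(sort(unique(cc$sample_type)), collapse = ", ")))
  cat(sprintf("  grid %g-%g cm-1 (%d pts); cv %.3g; noise_sd %.3g; gain_log_sd %.3g\n",
              min(x$grid), max(x$grid), length(x$grid), x$within_species_cv,
              x$measurement$noise_sd, x$measurement$gain_log_sd))
  invisible(x)
}

#' Multiply the scenario noise sources
#'
#' Scales the stochastic spectral noise of a scenario — replicate
#' concentration variability and additive white noise — by a common
#' factor, for noise-robustness experiments. The measurement artefacts
#' (contact gain, baseline offset and slope) are left at their scenario
#' values: gain and offset are cancelled exactly by the pre-processing,
#' and inflating any baseline term merely produces unphysical spectra
#' whose integrated absorbance is negative (which normalization rejects)
#' rather than a harder classification task.
#'
#' @param sc An `ir_scenario`.
#' @param multiplier Non-negative factor.
#' @return The scaled scenario.
#' @export
scale_noise <- function(sc, multiplier) {
  stopifnot(inherits(sc, "ir_scenario"), multiplier >= 0)
  sc$within_species_cv <- sc$within_species_cv * multiplier
  sc$measurement$noise_sd <- sc$measurement$noise_sd * multiplier
  validate_scenario(sc)
}

#' Forward-simulate a labelled spectral dataset
#'
#' For every species x sample_type x replicate, draws replicate
#' concentrations (lognormal around the scenario values with relative s.d.
#' `within_species_cv`), composes
#' `A(v) = gain * sum_k c_k B_k(v) + offset + slope * v + noise(v)`,
#' and returns the aligned dataset, its manifest and the drawn ground-truth
#' concentrations. Bit-reproducible for a given seed.
#'
#' @param sc An `ir_scenario`.
#' @param seed Integer seed driving every random draw.
#' @return List with `dataset` (an `ir_dataset`) and `ground_truth`
#'   (tibble `spectrum_id`, `species`, `sample_type`, `replicate`,
#'   `component`, `concentration`).
#' @export
simulate_spectra <- function(sc, seed = 1L) {
  validate_scenario(sc)
  cc <- sc$concentrations
  B <- component_basis(sc$library, sc$grid)
  comps <- rownames(B)
  groups <- dplyr::distinct(cc, .data$species, .data$genus, .data$family,
                            .data$sample_type)
  if (is.numeric(sc$n_per) && length(sc$n_per) == 1) {
    groups$n <- as.integer(sc$n_per)
  } else {
    groups <- dplyr::left_join(groups, tibble::as_tibble(sc$n_per),
                               by = c("species", "sample_type"))
    if (anyNA(groups$n)) stop("n_per table misses some species x sample_type",
                              call. = FALSE)
  }
  conc_vec <- function(sp, st) {
    rows <- cc[cc$species == sp & cc$sample_type == st, ]
    v <- stats::setNames(rep(0, length(comps)), comps)
    v[rows$component] <- rows$concentration
    v
  }
  ms <- sc$measurement
  n_total <- sum(groups$n)
  mat <- matrix(0, nrow = n_total, ncol = length(sc$grid))
  manifest <- vector("list", nrow(groups))
  gt <- vector("list", nrow(groups))
  withr::with_seed(seed, {
    row <- 0L
    for (gi in seq_len(nrow(groups))) {
      sp <- groups$species[gi]; st <- groups$sample_type[gi]
      base <- conc_vec(sp, st)
      ids <- sprintf("%s_%s_r%02d", gsub("[^A-Za-z0-9]+", "-", sp), st,
                     seq_len(groups$n[gi]))
      gtl <- vector("list", groups$n[gi])
      for (r in seq_len(groups$n[gi])) {
        conc <- base * exp(stats::rnorm(length(base), 0, sc$within_species_cv))
        gain <- exp(stats::rnorm(1, 0, ms$gain_log_sd))
        offset <- stats::rnorm(1, 0, ms$baseline_offset_sd)
        slope <- stats::rnorm(1, 0, ms$baseline_slope_sd)
        eps <- stats::rnorm(length(sc$grid), 0, ms$noise_sd)
        row <- row + 1L
        mat[row, ] <- gain * as.vector(conc %*% B) + offset + slope * sc$grid + eps
        gtl[[r]] <- tibble::tibble(spectrum_id = ids[r], species = sp,
                                   sample_type = st, replicate = r,
                                   component = comps,
                                   concentration = unname(conc))
      }
      manifest[[gi]] <- tibble::tibble(
        spectrum_id = ids, species = sp, genus = groups$genus[gi],
        family = groups$family[gi], sample_type = st,
        replicate = seq_len(groups$n[gi]))
      gt[[gi]] <- dplyr::bind_rows(gtl)
    }
  })
  manifest <- dplyr::bind_rows(manifest)
  rownames(mat) <- manifest$spectrum_id
  list(dataset = new_ir_dataset(sc$grid, mat, manifest),
       ground_truth = dplyr::bind_rows(gt))
}

#' Default cocoon-study scenario: 35 species in 5 genus-level groups
#'
#' Emulates the structure of a 35-species cocoon survey with inner and
#' outer layer measurements (18 replicate spectra per species per layer,
#' 1260 spectra in total): one phenolic-rich group, one calcium
#' oxalate-rich group, one highly crystalline (A)n-rich group, one
#' (AG)n-type group with sericin-rich outer layers, and one group of
#' intermediate composition. Outer layers are enriched in oxalate,
#' phenolics and sericin relative to inner layers. Species within a genus
#' share the genus profile times lognormal species offsets drawn from
#' `offset_seed` (a fixed property of the scenario, independent of the
#' simulation seed).
#'
#' @param n_per Spectra per species per layer (default 18).
#' @param grid Wavenumber grid.
#' @param species_offset_scale Lognormal s.d. of per-species component
#'   offsets around the genus profile.
#' @param offset_seed Seed fixing the species offsets.
#' @param ... Passed on to [scenario()] (noise levels etc.).
#' @return An `ir_scenario`.
#' @export
paperlike_scenario <- function(n_per = 18, grid = default_grid(),
                               species_offset_scale = 0.2, offset_seed = 101L,
                               ...) {
  profiles <- list(
    Phenolica = list(
      family = "Saturniidae",
      cocoon_inner = c(fibroin_An = 0.90, fibroin_AGn = 0, sericin = 0.25,
                       calcium_oxalate = 0.02, phenolic = 0.15, water = 0.30),
      cocoon_outer = c(fibroin_An = 0.70, fibroin_AGn = 0, sericin = 0.45,
                       calcium_oxalate = 0.05, phenolic = 0.60, water = 0.30)),
    Oxalata = list(
      family = "Lasiocampidae",
      cocoon_inner = c(fibroin_An = 0.80, fibroin_AGn = 0, sericin = 0.30,
                       calcium_oxalate = 0.15, phenolic = 0.05, water = 0.30),
      cocoon_outer = c(fibroin_An = 0.60, fibroin_AGn = 0, sericin = 0.40,
                       calcium_oxalate = 0.90, phenolic = 0.10, water = 0.30)),
    Crystallina = list(
      family = "Saturniidae",
      cocoon_inner = c(fibroin_An = 1.40, fibroin_AGn = 0, sericin = 0.20,
                       calcium_oxalate = 0.03, phenolic = 0.05, water = 0.30),
      cocoon_outer = c(fibroin_An = 1.20, fibroin_AGn = 0, sericin = 0.35,
                       calcium_oxalate = 0.08, phenolic = 0.10, water = 0.30)),
    Bombyxoida = list(
      family = "Bombycidae",
      cocoon_inner = c(fibroin_An = 0.10, fibroin_AGn = 0.90, sericin = 0.50,
                       calcium_oxalate = 0.01, phenolic = 0.03, water = 0.30),
      cocoon_outer = c(fibroin_An = 0.10, fibroin_AGn = 0.70, sericin = 0.90,
                       calcium_oxalate = 0.01, phenolic = 0.05, water = 0.30)),
    Media = list(
      family = "Saturniidae",
      cocoon_inner = c(fibroin_An = 0.70, fibroin_AGn = 0.05, sericin = 0.35,
                       calcium_oxalate = 0.06, phenolic = 0.12, water = 0.30),
      cocoon_outer = c(fibroin_An = 0.55, fibroin_AGn = 0.05, sericin = 0.50,
                       calcium_oxalate = 0.12, phenolic = 0.20, water = 0.30))
  )
  comps <- names(profiles[[1]]$cocoon_inner)
  cc <- withr::with_seed(offset_seed, {
    rows <- list()
    for (genus in names(profiles)) {
      for (sp_i in 1:7) {
        species <- sprintf("%s sp%02d", genus, sp_i)
        offs <- exp(stats::rnorm(length(comps), 0, species_offset_scale))
        names(offs) <- comps
        for (layer in c("cocoon_inner", "cocoon_outer")) {
          conc <- profiles[[genus]][[layer]] * offs
          rows[[length(rows) + 1L]] <- tibble::tibble(
            species = species, genus = genus,
            family = profiles[[genus]]$family, sample_type = layer,
            component = comps, concentration = unname(conc))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  scenario(cc, n_per = n_per, grid = grid, ...)
}

#' Six-species feedstock scenario with strong class separation
#'
#' Emulates a native-feedstock identification study: six species with
#' well-separated component concentration vectors (between-class spectral
#' separation far exceeding the within-class spread), 52 spectra in total
#' allocated near-evenly across species. Replicate variability and
#' measurement noise are kept small relative to the class differences so
#' that a hold-out validation of the full pipeline should identify every
#' spectrum.
#'
#' @param n_spectra Total number of spectra (default 52).
#' @param grid Wavenumber grid.
#' @param within_species_cv Replicate concentration variability.
#' @param ... Passed on to [scenario()].
#' @return An `ir_scenario`.
#' @export
feedstock_scenario <- function(n_spectra = 52, grid = default_grid(),
                               within_species_cv = 0.01,
                               ...) {
  specs <- tibble::tribble(
    ~species,        ~genus,      ~An,  ~helix, ~ser,  ~phen, ~wat,
    "Feedstock A",   "GenusI",    0.20, 1.20,   0.60,  0.05,  0.60,
    "Feedstock B",   "GenusI",    0.80, 0.80,   0.20,  0.10,  0.50,
    "Feedstock C",   "GenusII",   0.50, 1.00,   0.90,  0.30,  0.40,
    "Feedstock D",   "GenusII",   1.10, 0.50,   0.40,  0.05,  0.70,
    "Feedstock E",   "GenusIII",  0.35, 1.40,   0.15,  0.50,  0.55,
    "Feedstock F",   "GenusIII",  0.90, 1.10,   0.70,  0.60,  0.30
  )
  cc <- specs |>
    tidyr::pivot_longer(cols = c("An", "helix", "ser", "phen", "wat"),
                        names_to = "component", values_to = "concentration") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            An = "fibroin_An",
                                            helix = "helix_coil_feedstock",
                                            ser = "sericin",
                                            phen = "phenolic",
                                            wat = "water"),
                  family = "Synthetica", sample_type = "feedstock")
  n_sp <- length(unique(cc$species))
  counts <- largest_remainder(rep(n_spectra / n_sp, n_sp), n_spectra,
                              floor_min = 1, cap = rep(Inf, n_sp))
  n_per <- tibble::tibble(species = unique(cc$species),
                          sample_type = "feedstock", n = as.integer(counts))
  scenario(cc, n_per = n_per, grid = grid,
           within_species_cv = within_species_cv,
           gain_log_sd = 0.10, baseline_offset_sd = 0.01,
           baseline_slope_sd = 1e-5, noise_sd = 5e-4, ...)
}

#' Marker-recovery scenario: independent marker concentrations per species
#'
#' Builds a single-layer cocoon scenario in which each species draws its
#' five marker-component concentrations independently and uniformly, on
#' top of a constant amorphous protein scaffold that dominates the
#' normalization area. Used to check that scaled composition profiles
#' recover the generating concentrations (rank correlation per marker).
#'
#' @param n_species Number of species (>= 10 recommended).
#' @param n_per Spectra per species.
#' @param grid Wavenumber grid.
#' @param conc_seed Seed fixing the species concentration draws.
#' @param ... Passed on to [scenario()].
#' @return An `ir_scenario`.
#' @export
marker_recovery_scenario <- function(n_species = 12, n_per = 12,
                                     grid = default_grid(), conc_seed = 7L,
                                     ...) {
  ranges <- list(fibroin_An = c(0.30, 1.00), fibroin_AGn = c(0.05, 0.40),
                 calcium_oxalate = c(0.02, 0.40), phenolic = c(0.05, 0.40),
                 sericin = c(0.10, 0.60))
  cc <- withr::with_seed(conc_seed, {
    rows <- lapply(seq_len(n_species), function(i) {
      conc <- vapply(ranges, function(r) stats::runif(1, r[1], r[2]), numeric(1))
      tibble::tibble(
        species = sprintf("Marker sp%02d", i),
        genus = sprintf("MarkerGenus%02d", i),
        family = "Synthetica", sample_type = "cocoon_inner",
        component = c(names(ranges), "helix_coil_feedstock", "water"),
        concentration = c(unname(conc), 2.5, 0.30))
    })
    dplyr::bind_rows(rows)
  })
  scenario(cc, n_per = n_per, grid = grid, ...)
}

#' Simulate spectra spanned by exactly `n_components` latent components
#'
#' Generates random nonnegative mixtures of a fixed set of latent
#' pseudo-Voigt component spectra plus additive white measurement noise.
#' Because every noiseless spectrum lies in the span of the components,
#' such data carry at most `n_components` informative dimensions; the
#' check of interest is how much of the correlation-PCA variance of the
#' derivative spectra those dimensions retain.
#'
#' The latent components tile the whole simulated range so that no
#' spectral channel is strictly signal-free — with real derivative spectra
#' no channel is, and a Pearson (correlation) PCA weights every channel
#' equally. `noise_frac` states the share of noise in the variance that
#' the multivariate analysis actually decomposes: the white-noise standard
#' deviation is calibrated (by root finding) so that, after the
#' Savitzky-Golay first derivative and per-variable standardization, noise
#' accounts for `noise_frac` of the total variance, averaged over
#' variables.
#'
#' @param n_spectra Number of spectra.
#' @param n_components Number of latent components.
#' @param noise_frac Mean fraction of per-variable derivative-domain
#'   variance contributed by noise (default 0.05).
#' @param grid Wavenumber grid; default 800-1950 cm^-1 at the standard
#'   spacing so the usual pre-processing windows apply.
#' @param peaks_per_component Peaks per latent component.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters assumed by the
#'   noise calibration; keep equal to the analysis settings.
#' @param seed Integer seed.
#' @return List with `dataset` (an `ir_dataset` with generic manifest),
#'   `weights` (n_spectra x n_components) and `basis`.
#' @export
simulate_latent_mixture <- function(n_spectra = 60, n_components = 10,
                                    noise_frac = 0.05,
                                    grid = seq(800, 1950, by = 5500 / 2852),
                                    peaks_per_component = 6,
                                    sg_window = 9, sg_polyorder = 2,
                                    seed = 1L) {
  stopifnot(n_spectra >= 2, n_components >= 1, noise_frac >= 0, noise_frac < 1)
  withr::with_seed(seed, {
    basis <- t(vapply(seq_len(n_components), function(k) {
      peaks <- tibble::tibble(
        center = stats::runif(peaks_per_component, min(grid) + 10, 1890),
        fwhm = stats::runif(peaks_per_component, 15, 60),
        amplitude = stats::runif(peaks_per_component, 0.3, 1),
        gauss_fraction = 0.7)
      render_component(peaks, grid)
    }, numeric(length(grid))))
    W <- matrix(stats::runif(n_spectra * n_components), n_spectra, n_components)
    S <- W %*% basis
    sd_noise <- 0
    if (noise_frac > 0) {
      step <- uniform_step(grid)
      dS <- t(apply(S, 1, sg_deriv_vec, step = step,
                    window_pts = sg_window, polyorder = sg_polyorder))
      vs <- apply(dS, 2, stats::var)
      # white noise of variance s2 passes the SG derivative filter with gain k2
      Fm <- signal::sgolay(p = sg_polyorder, n = sg_window, m = 1, ts = step)
      k2 <- sum(Fm[(sg_window + 1) / 2, ]^2)
      vn <- stats::uniroot(function(v) mean(v / (v + vs)) - noise_frac,
                           c(1e-20, max(vs) * 1e3), tol = 1e-18)$root
      sd_noise <- sqrt(vn / k2)
    }
    X <- S + matrix(stats::rnorm(length(S), 0, sd_noise), nrow(S), ncol(S))
    ids <- sprintf("mix_%03d", seq_len(n_spectra))
    rownames(X) <- ids
    manifest <- tibble::tibble(spectrum_id = ids, species = "mixture",
                               genus = "Mixture", family = "Synthetica",
                               sample_type = "feedstock",
                               replicate = seq_len(n_spectra))
    list(dataset = new_ir_dataset(grid, X, manifest), weights = W, basis = basis)
  })
}
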