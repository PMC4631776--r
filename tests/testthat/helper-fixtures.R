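# Shared fixtures: small spectra/manifest builders and a reduced analysis
# grid (standard spacing, fingerprint range) used to keep simulations fast.

reduced_grid <- function(lo = 500, hi = 2000) seq(lo, hi, by = 5500 / 2852)

toy_spectra <- function(ids = c("s1", "s2"), grid = seq(1000, 2000, by = 10),
                        fun = function(w, i) sin(w / 50) + i) {
  dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(spectrum_id = ids[i], wavenumber = grid,
                   absorbance = fun(grid, i))
  }))
}

toy_manifest <- function(ids, species = ids, genus = species,
                         family = "Fam", sample_type = "feedstock") {
  tibble::tibble(spectrum_id = ids, species = species, genus = genus,
                 family = family, sample_type = sample_type,
                 replicate = seq_along(ids))
}

# smooth pseudo-random spectrum: positive Gaussian bumps confined to the
# fingerprint region, so the 1900-1950 offset window stays signal-free
# (the structure the offset/normalization protocol assumes)
random_smooth_spectrum <- function(grid, seed) {
  withr::with_seed(seed, {
    ctr <- stats::runif(5, max(850, min(grid) + 50), 1750)
    wd <- stats::runif(5, 40, 150)
    amp <- stats::runif(5, 0.2, 1)
    y <- rep(0.01, length(grid))
    for (j in 1:5) y <- y + amp[j] * exp(-(grid - ctr[j])^2 / (2 * (wd[j] / 2.355)^2))
    y
  })
}

single_spectrum <- function(grid, absorbance, id = "s1") {
  tibble::tibble(spectrum_id = id, wavenumber = grid, absorbance = absorbance)
}

# dataset wrapper around a plain matrix for chemometrics tests
matrix_dataset <- function(mat, grid = seq_len(ncol(mat)) + 499,
                           species = rownames(mat)) {
  ids <- sprintf("m%03d", seq_len(nrow(mat)))
  rownames(mat) <- ids
  silkir:::new_ir_dataset(grid, mat,
                          toy_manifest(ids, species = species, genus = species))
}
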