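#' Default chemical marker band panel
#'
#' The five marker bands used to compare cocoon chemistry across species,
#' each quantified by baseline-corrected integration:
#' calcium oxalate (740-800 cm^-1, the well-resolved 779 cm^-1 mode),
#' poly-alanine (A)n beta-sheet crystallinity (931-983 cm^-1, 961 cm^-1 peak),
#' poly(alanine-glycine) (AG)n beta-sheet (984-1006 cm^-1, 975/998 cm^-1
#' peaks, excluding the 961 cm^-1 (A)n band), phenolic/tannin compounds
#' (1094-1135 cm^-1) and the sericin serine marker (1384-1403 cm^-1).
#'
#' @return Tibble with columns `name`, `lo`, `hi`, `assignment`.
#' @export
marker_panel <- function() {
  tibble::tribble(
    ~name,             ~lo,  ~hi,  ~assignment,
    "calcium_oxalate", 740,  800,  "calcium oxalate monohydrate C-C/C-O modes (779 cm-1)",
    "a_n_beta_sheet",  931,  983,  "poly-alanine (A)n antiparallel beta-sheet (961 cm-1)",
    "ag_n_beta_sheet", 984,  1006, "poly(alanine-glycine) (AG)n beta-sheet (975/998 cm-1)",
    "phenolics",       1094, 1135, "tannin / polyphenol C-C aromatic stretching",
    "sericin",         1384, 1403, "serine-rich sericin CH2/COO modes"
  )
}

#' Read a marker band table from CSV
#'
#' @param path CSV with header `name,lo_cm-1,hi_cm-1,assignment`.
#' @return Band tibble usable as a panel in [quantify_markers()].
#' @export
read_band_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("name", "lo_cm-1", "hi_cm-1")
  if (!all(needed %in% names(df))) {
    stop("band table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(name = df$name, lo = df[["lo_cm-1"]], hi = df[["hi_cm-1"]],
                        assignment = if ("assignment" %in% names(df)) df$assignment else NA_character_)
  normalize_bands(out)
}

#' Quantify marker bands for every spectrum
#'
#' Computes the baseline-corrected band area ([band_area()]) of each marker
#' for each spectrum. Intended to run on offset-corrected, area-normalized
#' (non-derivative) spectra.
#'
#' @param x An `ir_dataset` or long spectra tibble.
#' @param panel Band table, by default [marker_panel()].
#' @return Tibble with `spectrum_id`, `marker`, `area`.
#' @export
quantify_markers <- function(x, panel = marker_panel()) {
  out <- band_area(x, panel)
  dplyr::rename(out, marker = "band")
}

#' Aggregate marker areas per species and layer, with min-max scaling
#'
#' Computes the mean and sample standard deviation (n-1 denominator) of each
#' marker area per (species, sample_type), then rescales the means of each
#' marker to the unit interval across all (species, sample_type) rows
#' pooled: 1 is the highest mean area observed for that marker, 0 the
#' lowest. If all means of a marker coincide the scale is degenerate and
#' scaled values are set to 0 with a warning.
#'
#' @param areas Per-spectrum marker table from [quantify_markers()].
#' @param manifest Manifest tibble covering every `spectrum_id` in `areas`.
#' @return Composition tibble: `species`, `sample_type`, `marker`, `n_obs`,
#'   `raw_mean`, `raw_sd`, `scaled_mean`.
#' @export
aggregate_by_species <- function(areas, manifest) {
  manifest <- validate_manifest(tibble::as_tibble(manifest))
  orphans <- setdiff(unique(areas$spectrum_id), manifest$spectrum_id)
  if (length(orphans)) {
    stop("spectra without manifest record: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(areas, manifest, by = "spectrum_id")
  agg <- joined |>
    dplyr::group_by(.data$species, .data$sample_type, .data$marker) |>
    dplyr::summarise(n_obs = dplyr::n(),
                     raw_mean = mean(.data$area),
                     raw_sd = if (dplyr::n() >= 2) stats::sd(.data$area) else NA_real_,
                     .groups = "drop")
  agg <- agg |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(scaled_mean = minmax_scale(.data$raw_mean, .data$marker[1])) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$marker, .data$species, .data$sample_type)
  agg
}

minmax_scale <- function(x, label) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    warning("degenerate min-max scale for marker '", label,
            "' (all means equal); scaled values set to 0", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Write a composition table to tidy CSV
#'
#' @param composition Output of [aggregate_by_species()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_csv <- function(composition, path) {
  cols <- c("species", "sample_type", "marker", "n_obs",
            "raw_mean", "raw_sd", "scaled_mean")
  readr::write_csv(composition[cols], path)
  invisible(path)
}
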