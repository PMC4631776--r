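#' Read a multi-spectrum CSV file
#'
#' Reads the canonical interchange format for ATR-IR spectra: a CSV whose
#' first column is `wavenumber_cm-1` and whose remaining columns each hold
#' the absorbance trace of one spectrum, named by its `spectrum_id`.
#' Instrument exports frequently store wavenumbers descending; rows are
#' re-sorted so wavenumbers are always ascending in the returned table.
#'
#' @param path Path to a spectra CSV file.
#' @return A tibble in long format with columns `spectrum_id`, `wavenumber`
#'   (cm^-1, ascending within each spectrum) and `absorbance`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("wavenumber_cm-1,s1,s2", "1000,0.1,0.2", "1002,0.3,0.4"), tf)
#' read_spectra_csv(tf)
#' @export
read_spectra_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub("^\"|\"$", "", trimws(header))
  if (length(header) < 2L || header[1] != "wavenumber_cm-1") {
    stop("spectra CSV must start with a 'wavenumber_cm-1' column, found: ",
         header[1], call. = FALSE)
  }
  ids <- header[-1]
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum_id column(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  num <- suppressWarnings(
    lapply(raw, function(col) as.numeric(col))
  )
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !(is.na(raw[[j]]) | raw[[j]] == "" | toupper(raw[[j]]) == "NA"))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   raw[[j]][bad[1]], bad[1], names(raw)[j]), call. = FALSE)
    }
    if (anyNA(num[[j]])) {
      stop(sprintf("missing value at data row %d, column '%s'",
                   which(is.na(num[[j]]))[1], names(raw)[j]), call. = FALSE)
    }
  }
  wn <- num[[1]]
  out <- tibble::tibble(
    spectrum_id = rep(ids, each = length(wn)),
    wavenumber  = rep(wn, times = length(ids)),
    absorbance  = unlist(num[-1], use.names = FALSE)
  )
  out <- dplyr::arrange(out, factor(.data$spectrum_id, levels = ids),
                        .data$wavenumber)
  validate_spectra(out)
  out
}

#' Write spectra to the multi-spectrum CSV format
#'
#' Inverse of [read_spectra_csv()]. All spectra must share one wavenumber
#' grid. Values are written with enough digits to round-trip doubles.
#'
#' @param data Long spectra tibble (`spectrum_id`, `wavenumber`, `absorbance`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(data, path) {
  data <- as_spectra(data)
  wide <- tidyr::pivot_wider(data, id_cols = "wavenumber",
                             names_from = "spectrum_id",
                             values_from = "absorbance")
  wide <- dplyr::arrange(wide, .data$wavenumber)
  names(wide)[1] <- "wavenumber_cm-1"
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest maps each `spectrum_id` to its taxonomy and sample type.
#' `sample_type` is a closed vocabulary: `feedstock`, `cocoon_inner`,
#' `cocoon_outer` or `fibre`.
#'
#' @param path Path to a manifest CSV with header exactly
#'   `spectrum_id,species,genus,family,sample_type,replicate`.
#' @return A validated tibble with those six columns.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_manifest(tibble::as_tibble(df))
}

#' Sample types recognised in a manifest
#' @return Character vector of the four valid `sample_type` values.
#' @export
sample_types <- function() c("feedstock", "cocoon_inner", "cocoon_outer", "fibre")

validate_manifest <- function(df) {
  required <- c("spectrum_id", "species", "genus", "family",
                "sample_type", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[required]
  bad <- setdiff(unique(df$sample_type), sample_types())
  if (length(bad)) {
    stop("unknown sample_type value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(sample_types(), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$spectrum_id)) {
    stop("duplicate spectrum_id in manifest: ",
         paste(unique(df$spectrum_id[duplicated(df$spectrum_id)]), collapse = ", "),
         call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  df
}

as_spectra <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"spectrum_id" %in% names(data)) data$spectrum_id <- "spectrum"
  needed <- c("spectrum_id", "wavenumber", "absorbance")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("spectra table needs column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data
}

validate_spectra <- function(data) {
  ok <- vapply(split(data$wavenumber, data$spectrum_id),
               function(w) length(w) >= 2 && all(diff(w) > 0), logical(1))
  if (!all(ok)) {
    stop("wavenumbers must be strictly increasing (length >= 2) for: ",
         paste(names(ok)[!ok], collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(data$absorbance))) {
    stop("non-finite absorbance values present", call. = FALSE)
  }
  invisible(data)
}

#' Default mid-infrared analysis grid
#'
#' A uniform 2853-point grid from 500 to 6000 cm^-1 (spacing ~= 1.9285 cm^-1),
#' the unique uniform grid consistent with the instrument range and the
#' variable count used throughout the multivariate analysis.
#'
#' @param lo,hi Grid limits in cm^-1.
#' @param n Number of grid points.
#' @return Numeric vector of `n` equally spaced wavenumbers.
#' @export
default_grid <- function(lo = 500, hi = 6000, n = 2853) {
  stopifnot(lo < hi, n >= 2)
  seq(lo, hi, length.out = n)
}

#' Assemble an aligned spectral dataset
#'
#' Linearly interpolates every spectrum onto a common wavenumber grid and
#' binds the result to its manifest, producing the `ir_dataset` container
#' consumed by the pre-processing and chemometric stages. Rows follow
#' manifest order.
#'
#' @param spectra Long spectra tibble from [read_spectra_csv()] or
#'   [simulate_spectra()].
#' @param manifest Manifest tibble (see [read_manifest()]); every
#'   `spectrum_id` must appear in `spectra` and vice versa.
#' @param grid Target wavenumber grid; defaults to [default_grid()].
#' @return An `ir_dataset`: list with `grid` (numeric), `absorbance`
#'   (n_spectra x n_points matrix, rownames = spectrum ids) and `manifest`.
#' @export
build_dataset <- function(spectra, manifest, grid = default_grid()) {
  spectra <- as_spectra(spectra)
  validate_spectra(spectra)
  manifest <- validate_manifest(tibble::as_tibble(manifest))
  by_id <- split(spectra[c("wavenumber", "absorbance")], spectra$spectrum_id)
  orphans <- setdiff(manifest$spectrum_id, names(by_id))
  extras  <- setdiff(names(by_id), manifest$spectrum_id)
  if (length(orphans) || length(extras)) {
    stop("manifest/spectra mismatch; in manifest only: [",
         paste(orphans, collapse = ", "), "]; in spectra only: [",
         paste(extras, collapse = ", "), "]", call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = nrow(manifest), ncol = length(grid),
                dimnames = list(manifest$spectrum_id, NULL))
  for (i in seq_len(nrow(manifest))) {
    sp <- by_id[[manifest$spectrum_id[i]]]
    if (min(sp$wavenumber) > min(grid) || max(sp$wavenumber) < max(grid)) {
      stop(sprintf("spectrum '%s' (%.6g-%.6g cm-1) does not cover the grid (%.6g-%.6g cm-1)",
                   manifest$spectrum_id[i], min(sp$wavenumber), max(sp$wavenumber),
                   min(grid), max(grid)), call. = FALSE)
    }
    mat[i, ] <- stats::approx(sp$wavenumber, sp$absorbance, xout = grid)$y
  }
  new_ir_dataset(grid, mat, manifest)
}

new_ir_dataset <- function(grid, absorbance, manifest) {
  stopifnot(is.matrix(absorbance),
            ncol(absorbance) == length(grid),
            nrow(absorbance) == nrow(manifest),
            all(diff(grid) > 0))
  structure(list(grid = grid, absorbance = absorbance,
                 manifest = tibble::as_tibble(manifest)),
            class = "ir_dataset")
}

#' @export
print.ir_dataset <- function(x, ...) {
  cat(sprintf("<ir_dataset> %d spectra x %d points, %.6g-%.6g cm-1\n",
              nrow(x$absorbance), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  species: %d; sample types: %s\n",
              length(unique(x$manifest$species)),
              paste(sort(unique(x$manifest$sample_type)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ir_dataset <- function(x) dim(x$absorbance)

#' Tidy a spectral dataset into long format
#'
#' @param x An `ir_dataset`.
#' @param ... Unused.
#' @return Long tibble with `spectrum_id`, `wavenumber`, `absorbance`,
#'   joined to the manifest columns.
#' @exportS3Method generics::tidy
tidy.ir_dataset <- function(x, ...) {
  long <- tibble::tibble(
    spectrum_id = rep(rownames(x$absorbance), each = length(x$grid)),
    wavenumber  = rep(x$grid, times = nrow(x$absorbance)),
    absorbance  = as.vector(t(x$absorbance))
  )
  dplyr::left_join(long, x$manifest, by = "spectrum_id")
}

#' Read a simple JCAMP-DX spectrum
#'
#' Minimal reader for single-spectrum JCAMP-DX files whose `##XYDATA=(X++(Y..Y))`
#' block stores one X value followed by evenly spaced Y values per line.
#' Descending files are normalized to ascending wavenumber.
#'
#' @param path Path to a `.jdx` file.
#' @param spectrum_id Identifier for the returned spectrum; defaults to the
#'   file's `##TITLE` or the file name.
#' @return Long spectra tibble with one `spectrum_id`.
#' @export
read_jdx <- function(path, spectrum_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    m <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", m[1]))
  }
  if (is.null(spectrum_id)) {
    spectrum_id <- get_field("TITLE")
    if (is.null(spectrum_id) || !nzchar(spectrum_id)) spectrum_id <- basename(path)
  }
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block in ", path, call. = FALSE)
  end <- grep("^##END", lines)
  end <- min(end[end > start[1]], length(lines) + 1L)
  block <- lines[(start[1] + 1L):(end - 1L)]
  block <- block[nzchar(trimws(block)) & !grepl("^##", block)]
  firstx <- as.numeric(get_field("FIRSTX"))
  lastx  <- as.numeric(get_field("LASTX"))
  npt    <- as.numeric(get_field("NPOINTS"))
  ys <- lapply(block, function(l) {
    v <- as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    v[-1]  # first token is the line's X start
  })
  y <- unlist(ys) * yfac
  if (is.na(npt)) npt <- length(y)
  if (length(y) != npt) {
    stop(sprintf("JCAMP-DX NPOINTS=%d but %d Y values read", npt, length(y)),
         call. = FALSE)
  }
  x <- seq(firstx * xfac, lastx * xfac, length.out = npt)
  out <- tibble::tibble(spectrum_id = spectrum_id, wavenumber = x, absorbance = y)
  out <- dplyr::arrange(out, .data$wavenumber)
  validate_spectra(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
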