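#' Pre-processing configuration
#'
#' Bundles the parameters of the standard ATR-IR pre-processing chain:
#' offset subtraction over a signal-free window, normalization by the
#' integrated fingerprint absorbance (compensating variable sample/crystal
#' contact), and a Savitzky-Golay first derivative for the multivariate
#' stage.
#'
#' @param offset_window Wavenumber window (cm^-1) whose mean absorbance is
#'   subtracted from each spectrum; default `c(1900, 1950)`, a region free
#'   of silk bands.
#' @param norm_window Window whose integrated absorbance is scaled to
#'   `norm_target`; default `c(800, 1900)`, the protein fingerprint region.
#' @param norm_target Target integrated absorbance after normalization
#'   (absorbance * cm^-1). Any positive constant is equivalent downstream;
#'   default 1.
#' @param derivative_window_pts Savitzky-Golay window length (odd, >= 5).
#' @param derivative_polyorder Savitzky-Golay polynomial order (>= 1).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(offset_window = c(1900, 1950),
                              norm_window = c(800, 1900),
                              norm_target = 1,
                              derivative_window_pts = 9,
                              derivative_polyorder = 2) {
  check_window(offset_window)
  check_window(norm_window)
  stopifnot(norm_target > 0,
            derivative_window_pts %% 2 == 1, derivative_window_pts >= 5,
            derivative_polyorder >= 1,
            derivative_polyorder < derivative_window_pts)
  structure(list(offset_window = offset_window, norm_window = norm_window,
                 norm_target = norm_target,
                 derivative_window_pts = derivative_window_pts,
                 derivative_polyorder = derivative_polyorder),
            class = "preprocess_config")
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 2 || !(window[1] < window[2])) {
    stop("window must be numeric c(lo, hi) with lo < hi", call. = FALSE)
  }
  invisible(window)
}

# Trapezoid-rule weights over [lo, hi] as a linear functional on the grid
# values, using grid points inside the window plus linearly interpolated
# endpoint values. area = sum(weights * absorbance).
window_weights <- function(grid, lo, hi, baseline = FALSE) {
  check_window(c(lo, hi))
  n <- length(grid)
  if (lo < grid[1] || hi > grid[n]) {
    stop(sprintf("window [%g, %g] outside grid [%g, %g]",
                 lo, hi, grid[1], grid[n]), call. = FALSE)
  }
  # interpolation weights for an off-grid point
  interp_w <- function(x) {
    j <- findInterval(x, grid)
    if (j == n || grid[j] == x) return(list(idx = j, w = 1))
    t <- (x - grid[j]) / (grid[j + 1] - grid[j])
    list(idx = c(j, j + 1), w = c(1 - t, t))
  }
  wlo <- interp_w(lo)
  whi <- interp_w(hi)
  w <- numeric(n)
  if (baseline) {
    # area under the straight line joining (lo, A(lo)) and (hi, A(hi))
    half <- (hi - lo) / 2
    w[wlo$idx] <- w[wlo$idx] + half * wlo$w
    w[whi$idx] <- w[whi$idx] + half * whi$w
    return(w)
  }
  inside <- which(grid > lo & grid < hi)
  xs <- c(lo, grid[inside], hi)
  m <- length(xs)
  coef <- numeric(m)
  coef[1] <- (xs[2] - xs[1]) / 2
  coef[m] <- (xs[m] - xs[m - 1]) / 2
  if (m > 2) coef[2:(m - 1)] <- (xs[3:m] - xs[1:(m - 2)]) / 2
  w[wlo$idx] <- w[wlo$idx] + coef[1] * wlo$w
  if (length(inside)) w[inside] <- w[inside] + coef[2:(m - 1)]
  w[whi$idx] <- w[whi$idx] + coef[m] * whi$w
  w
}

window_mean_idx <- function(grid, window) {
  idx <- which(grid >= window[1] & grid <= window[2])
  if (!length(idx)) {
    stop(sprintf("window [%g, %g] contains no grid points", window[1], window[2]),
         call. = FALSE)
  }
  idx
}

#' Subtract a signal-free offset from spectra
#'
#' Subtracts from each spectrum the mean absorbance over a window expected
#' to carry no chemical signal (default 1900-1950 cm^-1), removing additive
#' baseline offsets. Idempotent.
#'
#' @param x An `ir_dataset`, or a long spectra tibble with `spectrum_id`,
#'   `wavenumber`, `absorbance`.
#' @param window Offset window `c(lo, hi)` in cm^-1.
#' @return Object of the same type with corrected absorbance.
#' @export
subtract_offset <- function(x, window = c(1900, 1950)) UseMethod("subtract_offset")

#' @export
subtract_offset.ir_dataset <- function(x, window = c(1900, 1950)) {
  check_window(window)
  idx <- window_mean_idx(x$grid, window)
  off <- rowMeans(x$absorbance[, idx, drop = FALSE])
  x$absorbance <- x$absorbance - off
  x
}

#' @export
subtract_offset.data.frame <- function(x, window = c(1900, 1950)) {
  check_window(window)
  x <- as_spectra(x)
  dplyr::mutate(dplyr::group_by(x, .data$spectrum_id),
                absorbance = {
                  idx <- window_mean_idx(.data$wavenumber, window)
                  .data$absorbance - mean(.data$absorbance[idx])
                }) |> dplyr::ungroup()
}

#' Trapezoidal band integral of spectra
#'
#' Integrates absorbance over a wavenumber window using the trapezoid rule
#' on the native grid, with linearly interpolated values at the exact window
#' limits.
#'
#' @inheritParams subtract_offset
#' @param window Integration window `c(lo, hi)` in cm^-1, inside the grid.
#' @return Tibble with `spectrum_id` and `area` (absorbance * cm^-1).
#' @export
integrate_area <- function(x, window) UseMethod("integrate_area")

#' @export
integrate_area.ir_dataset <- function(x, window) {
  w <- window_weights(x$grid, window[1], window[2])
  tibble::tibble(spectrum_id = rownames(x$absorbance),
                 area = as.vector(x$absorbance %*% w))
}

#' @export
integrate_area.data.frame <- function(x, window) {
  x <- as_spectra(x)
  ids <- unique(x$spectrum_id)
  area <- vapply(ids, function(id) {
    sp <- x[x$spectrum_id == id, ]
    sum(window_weights(sp$wavenumber, window[1], window[2]) * sp$absorbance)
  }, numeric(1))
  tibble::tibble(spectrum_id = ids, area = unname(area))
}

#' Normalize spectra to a target integrated absorbance
#'
#' Rescales each spectrum so its integrated absorbance over `window` equals
#' `target`, cancelling the multiplicative signal variation caused by
#' differing sample contact with the ATR crystal. Idempotent and invariant
#' to any positive gain applied to the input.
#'
#' @inheritParams subtract_offset
#' @param window Normalization window `c(lo, hi)` in cm^-1.
#' @param target Positive target area.
#' @return Object of the same type, rescaled.
#' @export
normalize_area <- function(x, window = c(800, 1900), target = 1) {
  UseMethod("normalize_area")
}

#' @export
normalize_area.ir_dataset <- function(x, window = c(800, 1900), target = 1) {
  stopifnot(target > 0)
  area <- integrate_area(x, window)$area
  if (any(area <= 0)) {
    stop("non-positive window area for: ",
         paste(rownames(x$absorbance)[area <= 0], collapse = ", "),
         " (empty or invalid spectrum)", call. = FALSE)
  }
  x$absorbance <- x$absorbance * (target / area)
  x
}

#' @export
normalize_area.data.frame <- function(x, window = c(800, 1900), target = 1) {
  stopifnot(target > 0)
  x <- as_spectra(x)
  areas <- integrate_area(x, window)
  if (any(areas$area <= 0)) {
    stop("non-positive window area for: ",
         paste(areas$spectrum_id[areas$area <= 0], collapse = ", "),
         " (empty or invalid spectrum)", call. = FALSE)
  }
  x |>
    dplyr::left_join(areas, by = "spectrum_id") |>
    dplyr::mutate(absorbance = .data$absorbance * target / .data$area) |>
    dplyr::select(-"area")
}

#' Baseline-corrected band areas
#'
#' For each band, integrates absorbance over `[lo, hi]` and subtracts the
#' area under the straight line joining the interpolated absorbance at the
#' two band limits (a two-point linear baseline). The result is invariant
#' to adding any global straight line to the spectrum and may be negative
#' for concave-down local baselines; negative values are reported as-is.
#'
#' @inheritParams subtract_offset
#' @param bands Either a window `c(lo, hi)` or a band table: tibble with
#'   columns `name`, `lo`, `hi` (cm^-1) such as [marker_panel()].
#' @return Tibble with `spectrum_id`, `band`, `area`.
#' @export
band_area <- function(x, bands) UseMethod("band_area")

normalize_bands <- function(bands) {
  if (is.numeric(bands) && length(bands) == 2) {
    bands <- tibble::tibble(name = "band", lo = bands[1], hi = bands[2])
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("name", "lo", "hi") %in% names(bands)))
  if (anyDuplicated(bands$name)) stop("band names must be unique", call. = FALSE)
  if (!all(bands$lo < bands$hi)) stop("each band needs lo < hi", call. = FALSE)
  bands
}

#' @export
band_area.ir_dataset <- function(x, bands) {
  bands <- normalize_bands(bands)
  res <- purrr::pmap(bands, function(name, lo, hi, ...) {
    w <- tryCatch(
      window_weights(x$grid, lo, hi) - window_weights(x$grid, lo, hi, baseline = TRUE),
      error = function(e) stop("band '", name, "': ", conditionMessage(e), call. = FALSE))
    tibble::tibble(spectrum_id = rownames(x$absorbance), band = name,
                   area = as.vector(x$absorbance %*% w))
  })
  dplyr::bind_rows(res)
}

#' @export
band_area.data.frame <- function(x, bands) {
  bands <- normalize_bands(bands)
  x <- as_spectra(x)
  by_id <- split(x, x$spectrum_id)[unique(x$spectrum_id)]
  res <- purrr::map(by_id, function(sp) {
    purrr::pmap(bands, function(name, lo, hi, ...) {
      w <- window_weights(sp$wavenumber, lo, hi) -
        window_weights(sp$wavenumber, lo, hi, baseline = TRUE)
      tibble::tibble(spectrum_id = sp$spectrum_id[1], band = name,
                     area = sum(w * sp$absorbance))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(res)
}

#' Savitzky-Golay first derivative of spectra
#'
#' Smoothed first derivative with respect to wavenumber (units
#' absorbance/cm^-1) by local polynomial (Savitzky-Golay) filtering.
#' Edge points are handled by evaluating the fitted polynomial of the
#' terminal window. Requires a uniform wavenumber grid. The operator is
#' linear and reproduces the exact derivative of any polynomial up to
#' `polyorder`.
#'
#' @inheritParams subtract_offset
#' @param window_pts Odd filter window length in points (> `polyorder`).
#' @param polyorder Polynomial order (>= 1).
#' @return Object of the same type holding d(absorbance)/d(wavenumber).
#' @export
first_derivative <- function(x, window_pts = 9, polyorder = 2) {
  UseMethod("first_derivative")
}

check_sg <- function(window_pts, polyorder, n_points) {
  if (window_pts %% 2 != 1 || window_pts < 5) {
    stop("window_pts must be odd and >= 5", call. = FALSE)
  }
  if (polyorder < 1 || polyorder >= window_pts) {
    stop("polyorder must satisfy 1 <= polyorder < window_pts", call. = FALSE)
  }
  if (window_pts > n_points) {
    stop("window_pts exceeds the number of grid points", call. = FALSE)
  }
}

sg_deriv_vec <- function(y, step, window_pts, polyorder) {
  signal::sgolayfilt(y, p = polyorder, n = window_pts, m = 1, ts = step)
}

uniform_step <- function(grid) {
  d <- diff(grid)
  if (max(d) - min(d) > 1e-8 * mean(d)) {
    stop("first_derivative requires a uniform wavenumber grid; interpolate with build_dataset() first",
         call. = FALSE)
  }
  mean(d)
}

#' @export
first_derivative.ir_dataset <- function(x, window_pts = 9, polyorder = 2) {
  check_sg(window_pts, polyorder, length(x$grid))
  step <- uniform_step(x$grid)
  x$absorbance <- t(apply(x$absorbance, 1, sg_deriv_vec, step = step,
                          window_pts = window_pts, polyorder = polyorder))
  x
}

#' @export
first_derivative.data.frame <- function(x, window_pts = 9, polyorder = 2) {
  x <- as_spectra(x)
  dplyr::mutate(dplyr::group_by(x, .data$spectrum_id),
                absorbance = {
                  check_sg(window_pts, polyorder, length(.data$wavenumber))
                  sg_deriv_vec(.data$absorbance, uniform_step(.data$wavenumber),
                               window_pts, polyorder)
                }) |> dplyr::ungroup()
}

#' Apply the standard pre-processing chain to a dataset
#'
#' Convenience wrapper: offset subtraction then area normalization, and
#' optionally the Savitzky-Golay first derivative. Marker-band
#' quantification should consume the normalized (non-derivative) spectra;
#' only the multivariate stage uses the derivative.
#'
#' @param x An `ir_dataset`.
#' @param config A [preprocess_config()].
#' @param derivative If `TRUE`, also apply [first_derivative()].
#' @return Pre-processed `ir_dataset`.
#' @export
preprocess <- function(x, config = preprocess_config(), derivative = FALSE) {
  stopifnot(inherits(x, "ir_dataset"), inherits(config, "preprocess_config"))
  x <- subtract_offset(x, config$offset_window)
  x <- normalize_area(x, config$norm_window, config$norm_target)
  if (derivative) {
    x <- first_derivative(x, config$derivative_window_pts,
                          config$derivative_polyorder)
  }
  x
}
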