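#' Correlation-matrix (Pearson) principal component analysis
#'
#' PCA on standardized variables — equivalent to an eigendecomposition of
#' the Pearson correlation matrix — computed via the singular value
#' decomposition of the centred, unit-variance data matrix. Standardization
#' makes the result invariant to any per-variable rescaling, the property
#' that motivates this convention for derivative spectra. Constant
#' (zero-variance) variables carry no correlation information; they are
#' dropped with a warning and recorded in the model.
#'
#' @param x An `ir_dataset` (rows = spectra) or a numeric matrix /
#'   data frame of observations x variables.
#' @param k Number of components to retain (<= rank of the data).
#' @return An object of class `ir_pca`: `means`, `sds` (per kept variable),
#'   `loadings` (variables x k, orthonormal), `explained_variance_pct`
#'   (length k, non-increasing), `eig` (all positive eigenvalues),
#'   `kept_vars` (indices into the original variables), `dropped_vars`,
#'   `k`, `n_obs`, and `scores` (training scores, n x k).
#' @export
fit_pca <- function(x, k = 10) {
  X <- as_matrix_input(x)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) stop("all variables are constant", call. = FALSE)
  if (length(keep) < ncol(X)) {
    warning(ncol(X) - length(keep),
            " constant variable(s) dropped before correlation PCA", call. = FALSE)
  }
  Z <- scale(X[, keep, drop = FALSE], center = means[keep], scale = sds[keep])
  sv <- svd(Z)
  eig <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (k > rank) {
    stop(sprintf("k = %d exceeds the data rank (%d)", k, rank), call. = FALSE)
  }
  total_var <- length(keep)  # trace of the correlation matrix
  structure(list(
    means = means[keep], sds = sds[keep],
    loadings = sv$v[, seq_len(k), drop = FALSE],
    explained_variance_pct = 100 * eig[seq_len(k)] / total_var,
    eig = eig[seq_len(rank)],
    kept_vars = keep,
    dropped_vars = setdiff(seq_len(ncol(X)), keep),
    k = k, n_obs = n, n_vars = length(keep),
    scores = Z %*% sv$v[, seq_len(k), drop = FALSE]
  ), class = "ir_pca")
}

as_matrix_input <- function(x) {
  if (inherits(x, "ir_dataset")) return(x$absorbance)
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  stop("expected an ir_dataset, matrix or data frame", call. = FALSE)
}

#' Project observations onto fitted principal components
#'
#' Applies the training standardization (stored means and standard
#' deviations) and the loading matrix to new observations. Projecting the
#' training data reproduces the fit-time scores; projecting the training
#' mean gives the zero vector.
#'
#' @param model An `ir_pca` model.
#' @param x New data with the model's original variable count
#'   (`ir_dataset`, matrix or data frame).
#' @return Scores matrix (n x k), rownames preserved.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "ir_pca"))
  X <- as_matrix_input(x)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  n_orig <- length(model$kept_vars) + length(model$dropped_vars)
  if (ncol(X) != n_orig) {
    stop(sprintf("variable count mismatch: model fitted on %d variables, data has %d",
                 n_orig, ncol(X)), call. = FALSE)
  }
  Z <- scale(X[, model$kept_vars, drop = FALSE],
             center = model$means, scale = model$sds)
  Z %*% model$loadings
}

#' @export
print.ir_pca <- function(x, ...) {
  cat(sprintf("<ir_pca> %d components on %d observations x %d variables\n",
              x$k, x$n_obs, x$n_vars))
  cat(sprintf("  cumulative variance: %.1f%%\n", sum(x$explained_variance_pct)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ir_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k),
                 eigenvalue = x$eig[seq_len(x$k)],
                 variance_pct = x$explained_variance_pct,
                 cumulative_pct = cumsum(x$explained_variance_pct))
}

#' @exportS3Method generics::glance
glance.ir_pca <- function(x, ...) {
  tibble::tibble(k = x$k, n_obs = x$n_obs, n_vars = x$n_vars,
                 n_dropped = length(x$dropped_vars),
                 cumulative_variance_pct = sum(x$explained_variance_pct))
}

#' Split a dataset into training and validation groups
#'
#' Reproducible random partition of the spectra into a training group of
#' size `n_train` and a validation group of the remainder. The stratified
#' mode (default) allocates training slots per species proportionally by
#' largest-remainder rounding, guaranteeing at least one training spectrum
#' per species; the pure random mode reproduces a simple random draw.
#'
#' @param manifest Manifest tibble (or an `ir_dataset`, whose manifest is
#'   used).
#' @param n_train Number of training spectra, `1 <= n_train < n`.
#' @param seed Integer seed; the split is a pure function of
#'   (manifest, n_train, seed).
#' @param stratified Stratify by species (default `TRUE`).
#' @return Tibble `spectrum_id`, `species`, `role` (`"train"`/`"validation"`)
#'   with attributes `seed` and `stratified`.
#' @export
split_dataset <- function(manifest, n_train, seed = 1L, stratified = TRUE) {
  if (inherits(manifest, "ir_dataset")) manifest <- manifest$manifest
  manifest <- tibble::as_tibble(manifest)
  n <- nrow(manifest)
  if (n_train < 1 || n_train >= n) {
    stop(sprintf("n_train must be in [1, %d)", n), call. = FALSE)
  }
  ids <- manifest$spectrum_id
  train_ids <- withr::with_seed(seed, {
    if (!stratified) {
      sample(ids, n_train)
    } else {
      counts <- table(manifest$species)
      if (any(counts < 2)) {
        stop("stratified split needs >= 2 spectra per species; offending: ",
             paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
      }
      quota <- largest_remainder(as.numeric(counts) * n_train / n,
                                 n_train, floor_min = 1,
                                 cap = as.numeric(counts))
      unlist(purrr::map2(names(counts), quota, function(sp, q) {
        sample(ids[manifest$species == sp], q)
      }), use.names = FALSE)
    }
  })
  out <- tibble::tibble(spectrum_id = ids, species = manifest$species,
                        role = ifelse(ids %in% train_ids, "train", "validation"))
  attr(out, "seed") <- seed
  attr(out, "stratified") <- stratified
  out
}

# Largest-remainder apportionment of `total` integer slots given real quotas,
# with per-class floors and caps.
largest_remainder <- function(quota, total, floor_min = 0, cap = Inf) {
  base <- pmin(pmax(floor(quota), floor_min), cap)
  frac <- quota - floor(quota)
  deficit <- total - sum(base)
  ord <- order(frac, decreasing = TRUE)
  i <- 1L
  while (deficit > 0) {
    j <- ord[(i - 1L) %% length(ord) + 1L]
    if (base[j] < cap[j]) {
      base[j] <- base[j] + 1L
      deficit <- deficit - 1L
    }
    i <- i + 1L
  }
  while (deficit < 0) {
    j <- ord[length(ord) - (abs(deficit) - 1L) %% length(ord)]
    if (base[j] > floor_min) {
      base[j] <- base[j] - 1L
      deficit <- deficit + 1L
    } else {
      ord <- ord[ord != j]
    }
  }
  base
}

#' Fisher linear discriminant analysis on PC scores
#'
#' Finds the linear combinations of principal-component scores that
#' maximize between-species relative to within-species scatter. The pooled
#' within-class covariance is regularized as `(1 - s) * S + s * diag(S)`
#' (shrinkage toward its diagonal) to guard near-singularity. Discriminant
#' factors are scaled so the pooled within-class covariance of factor
#' scores is the identity, ordered by decreasing discrimination eigenvalue;
#' the percent discrimination of each factor is reported.
#'
#' @param scores Numeric matrix (n x k) of PC scores, e.g. from
#'   [fit_pca()] / [project()].
#' @param labels Class labels (species), length n; every class needs >= 2
#'   training observations.
#' @param shrinkage Shrinkage intensity in `[0, 1]`; default `1e-4`.
#' @return An `ir_lda` object: `class_labels`, `coefficients` (k x F),
#'   `centroids` (classes x F factor-score centroids), `priors` (equal),
#'   `discrimination_pct`, `grand_mean`, `shrinkage`, `n_factors`.
#' @export
fit_lda <- function(scores, labels, shrinkage = 1e-4) {
  X <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), shrinkage >= 0, shrinkage <= 1)
  classes <- sort(unique(labels))
  g <- length(classes)
  if (g < 2) stop("need at least 2 classes", call. = FALSE)
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) {
    stop("every class needs >= 2 training spectra; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); k <- ncol(X)
  mu <- colMeans(X)
  class_means <- t(vapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                          numeric(k)))
  # pooled within-class scatter; the 1/n normalization makes the model a
  # function of class moments only (duplicating every spectrum changes nothing)
  Sw <- matrix(0, k, k)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / n
  Sw <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), k)
  ew <- eigen(Sw, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-12) {
    stop("within-class scatter is singular; increase shrinkage above 0",
         call. = FALSE)
  }
  W <- ew$vectors %*% diag(1 / sqrt(ew$values), k) %*% t(ew$vectors)
  Sb <- matrix(0, k, k)
  for (i in seq_len(g)) {
    d <- class_means[i, ] - mu
    Sb <- Sb + counts[i] * tcrossprod(d)
  }
  Sb <- Sb / n
  M <- W %*% Sb %*% W
  M <- (M + t(M)) / 2
  eb <- eigen(M, symmetric = TRUE)
  f <- min(k, g - 1)
  coef <- W %*% eb$vectors[, seq_len(f), drop = FALSE]
  colnames(coef) <- paste0("factor_", seq_len(f))
  lambda <- pmax(eb$values[seq_len(f)], 0)
  centroids <- sweep(class_means, 2, mu) %*% coef
  dimnames(centroids) <- list(classes, paste0("factor_", seq_len(f)))
  structure(list(
    class_labels = classes,
    coefficients = coef,
    centroids = centroids,
    priors = stats::setNames(rep(1 / g, g), classes),
    discrimination_pct = 100 * lambda / sum(lambda),
    eig = lambda,
    grand_mean = mu,
    shrinkage = shrinkage,
    n_factors = f,
    counts = as.integer(counts)
  ), class = "ir_lda")
}

#' Factor scores of observations under a fitted LDA
#'
#' @param model An `ir_lda`.
#' @param scores PC-score matrix with the model's variable count.
#' @return Factor-score matrix (n x F).
#' @export
factor_scores <- function(model, scores) {
  stopifnot(inherits(model, "ir_lda"))
  X <- as.matrix(scores)
  if (ncol(X) != nrow(model$coefficients)) {
    stop("PC-score dimension mismatch", call. = FALSE)
  }
  sweep(X, 2, model$grand_mean) %*% model$coefficients
}

#' @export
print.ir_lda <- function(x, ...) {
  cat(sprintf("<ir_lda> %d classes, %d discriminant factors (shrinkage %g)\n",
              length(x$class_labels), x$n_factors, x$shrinkage))
  cat(sprintf("  first two factors: %.1f%% of discrimination\n",
              sum(x$discrimination_pct[seq_len(min(2, x$n_factors))])))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ir_lda <- function(x, ...) {
  tibble::as_tibble(x$centroids, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "factor", names_prefix = "factor_",
                        values_to = "centroid") |>
    dplyr::mutate(factor = as.integer(.data$factor))
}

#' @exportS3Method generics::glance
glance.ir_lda <- function(x, ...) {
  tibble::tibble(n_classes = length(x$class_labels),
                 n_factors = x$n_factors,
                 shrinkage = x$shrinkage,
                 first_two_factors_pct = sum(x$discrimination_pct[seq_len(min(2, x$n_factors))]))
}

#' Classify spectra and score species / genus hit rates
#'
#' Projects pre-processed derivative spectra through the fitted PCA and
#' LDA, assigns each spectrum to the species whose factor-space centroid is
#' nearest (Euclidean distance, equal priors; ties broken by the first
#' label in sorted order), and scores hit rates against the manifest.
#' Because the factor space is whitened to unit pooled within-class
#' covariance, nearest-centroid assignment is the classical Fisher LDA
#' decision rule. Validation species absent from the training classes are
#' counted as automatic misses and flagged.
#'
#' @param x An `ir_dataset` pre-processed identically to the training data
#'   (offset, normalization, derivative), or a PC-score matrix if `pca` is
#'   `NULL`.
#' @param pca Fitted `ir_pca` (or `NULL` when `x` is already PC scores).
#' @param lda Fitted `ir_lda`.
#' @param manifest Manifest for the spectra in `x`; defaults to the
#'   dataset's own manifest.
#' @return An `ir_classification`: `predictions` tibble (`spectrum_id`,
#'   `true_species`, `predicted_species`, `true_genus`, `predicted_genus`,
#'   `factor_1..F`), `species_hit_rate_pct`, `genus_hit_rate_pct`,
#'   `confusion` (classes x classes counts), `unseen_species`.
#' @export
classify <- function(x, pca, lda, manifest = NULL) {
  stopifnot(inherits(lda, "ir_lda"))
  if (inherits(x, "ir_dataset")) {
    if (is.null(manifest)) manifest <- x$manifest
    pcs <- if (is.null(pca)) x$absorbance else project(pca, x)
  } else {
    pcs <- if (is.null(pca)) as.matrix(x) else project(pca, x)
  }
  if (is.null(manifest)) stop("a manifest is required to score hit rates", call. = FALSE)
  manifest <- tibble::as_tibble(manifest)
  fs <- factor_scores(lda, pcs)
  # squared distances to every class centroid
  d2 <- outer(rowSums(fs^2), rowSums(lda$centroids^2), "+") -
    2 * fs %*% t(lda$centroids)
  pred_idx <- apply(d2, 1, which.min)  # which.min takes the first on ties
  predicted <- lda$class_labels[pred_idx]
  genus_map <- dplyr::distinct(manifest, .data$species, .data$genus)
  lookup <- stats::setNames(genus_map$genus, genus_map$species)
  ids <- if (inherits(x, "ir_dataset")) rownames(x$absorbance) else rownames(pcs) %||% manifest$spectrum_id
  m <- manifest[match(ids, manifest$spectrum_id), ]
  preds <- tibble::tibble(
    spectrum_id = ids,
    true_species = m$species,
    predicted_species = predicted,
    true_genus = m$genus,
    predicted_genus = unname(lookup[predicted])
  )
  fs_tbl <- tibble::as_tibble(fs, .name_repair = ~ paste0("factor_", seq_along(.x)))
  preds <- dplyr::bind_cols(preds, fs_tbl)
  unseen <- setdiff(unique(preds$true_species), lda$class_labels)
  species_hit <- preds$true_species == preds$predicted_species
  species_hit[preds$true_species %in% unseen] <- FALSE
  genus_hit <- preds$true_genus == preds$predicted_genus
  all_species <- sort(union(lda$class_labels, unique(preds$true_species)))
  confusion <- table(factor(preds$true_species, levels = all_species),
                     factor(preds$predicted_species, levels = all_species))
  structure(list(
    predictions = preds,
    species_hit_rate_pct = 100 * mean(species_hit),
    genus_hit_rate_pct = 100 * mean(genus_hit),
    confusion = unclass(confusion),
    unseen_species = unseen
  ), class = "ir_classification")
}

#' @export
print.ir_classification <- function(x, ...) {
  cat(sprintf("<ir_classification> %d spectra: species hit rate %.1f%%, genus %.1f%%\n",
              nrow(x$predictions), x$species_hit_rate_pct, x$genus_hit_rate_pct))
  if (length(x$unseen_species)) {
    cat("  species unseen in training (auto-miss): ",
        paste(x$unseen_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ir_classification <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.ir_classification <- function(x, ...) {
  tibble::tibble(n = nrow(x$predictions),
                 species_hit_rate_pct = x$species_hit_rate_pct,
                 genus_hit_rate_pct = x$genus_hit_rate_pct,
                 n_unseen_species = length(x$unseen_species))
}

#' Write predictions to CSV
#'
#' @param classification An `ir_classification`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(classification, path) {
  readr::write_csv(classification$predictions, path)
  invisible(path)
}
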