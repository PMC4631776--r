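#' Write a simulated dataset to interchange files
#'
#' Simulates a scenario and writes the three interchange files consumed by
#' the analysis stages: the multi-spectrum CSV, the manifest CSV and the
#' ground-truth concentration CSV.
#'
#' @param sc An `ir_scenario`.
#' @param dir Output directory (created if needed).
#' @param seed Simulation seed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
simulate_to_files <- function(sc, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_spectra(sc, seed = seed)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             manifest = file.path(dir, "manifest.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  write_spectra_csv(tidy(sim$dataset)[c("spectrum_id", "wavenumber", "absorbance")],
                    paths["spectra"])
  readr::write_csv(sim$dataset$manifest, paths["manifest"])
  readr::write_csv(sim$ground_truth, paths["ground_truth"])
  invisible(paths)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys mirror the
#'   arguments of [run_pipeline()] (and a `preprocess:` section mirroring
#'   [preprocess_config()]).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full chemotaxonomy pipeline on a dataset
#'
#' Executes the complete analysis in the canonical order: offset
#' subtraction and area normalization; marker-band quantification on the
#' normalized (non-derivative) spectra and aggregation per species and
#' layer; Savitzky-Golay first derivative; correlation PCA; a reproducible
#' train/validation split; LDA on the training PC scores; hold-out
#' classification with species and genus hit rates; Euclidean distances
#' between LDA centroids; Ward clustering; a threshold cut into groups;
#' Newick export; and, when a reference phylogeny is supplied, a
#' Robinson-Foulds / cophenetic comparison.
#'
#' @param x An `ir_dataset` (raw, un-preprocessed).
#' @param pca_k Retained principal components (10 suits feedstock-style
#'   runs, 40 cocoon-style runs).
#' @param n_train Training-set size; default 80% of the spectra (rounded).
#' @param seed Seed for the random split.
#' @param stratified Stratify the split by species.
#' @param shrinkage LDA shrinkage intensity.
#' @param hca_factors Number of leading discriminant factors used for the
#'   species tree (default 10).
#' @param cut_threshold Height threshold for grouping; `NULL` picks the
#'   midpoint of the largest gap in merge heights.
#' @param height_scale Dendrogram height convention, `"euclidean"` or
#'   `"squared"`.
#' @param reference_tree Optional reference phylogeny (Newick string, file
#'   or `phylo`); when given, the spectral tree is compared against it on
#'   the shared leaf set.
#' @param config A [preprocess_config()].
#' @param panel Marker band table.
#' @param out_dir If non-`NULL`, results are also written there as CSV /
#'   Newick / YAML files.
#' @return List of class `ir_pipeline_result` with elements `composition`,
#'   `marker_areas`, `pca`, `split`, `lda`, `classification`, `centroid_dist`,
#'   `tree`, `groups`, `newick`, `tree_comparison` (or `NULL`), `seed`,
#'   `params`.
#' @export
run_pipeline <- function(x, pca_k = 40, n_train = NULL, seed = 1L,
                         stratified = TRUE, shrinkage = 1e-4,
                         hca_factors = 10, cut_threshold = NULL,
                         height_scale = "euclidean", reference_tree = NULL,
                         config = preprocess_config(), panel = marker_panel(),
                         out_dir = NULL) {
  stopifnot(inherits(x, "ir_dataset"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  norm <- stage("preprocess", preprocess(x, config, derivative = FALSE))
  areas <- stage("markers", quantify_markers(norm, panel))
  composition <- stage("composition", aggregate_by_species(areas, x$manifest))
  deriv <- stage("derivative",
                 first_derivative(norm, config$derivative_window_pts,
                                  config$derivative_polyorder))
  if (is.null(n_train)) n_train <- max(1L, round(0.8 * nrow(deriv$absorbance)))
  split <- stage("split", split_dataset(x$manifest, n_train, seed = seed,
                                        stratified = stratified))
  train_ids <- split$spectrum_id[split$role == "train"]
  valid_ids <- split$spectrum_id[split$role == "validation"]
  train_idx <- match(train_ids, rownames(deriv$absorbance))
  valid_idx <- match(valid_ids, rownames(deriv$absorbance))
  pca <- stage("pca", fit_pca(deriv$absorbance[train_idx, , drop = FALSE], k = pca_k))
  train_labels <- x$manifest$species[match(train_ids, x$manifest$spectrum_id)]
  lda <- stage("lda", fit_lda(pca$scores, train_labels, shrinkage = shrinkage))
  valid_manifest <- x$manifest[match(valid_ids, x$manifest$spectrum_id), ]
  valid_scores <- stage("project",
                        project(pca, deriv$absorbance[valid_idx, , drop = FALSE]))
  rownames(valid_scores) <- valid_ids
  classification <- stage("classify",
                          classify(valid_scores, pca = NULL, lda = lda,
                                   manifest = valid_manifest))
  d <- stage("centroids", centroid_distances(lda, n_factors = hca_factors))
  tree <- stage("hca", ward_linkage(d, height_scale = height_scale))
  if (is.null(cut_threshold)) {
    h <- sort(tree$height)
    gap <- which.max(diff(h))
    cut_threshold <- (h[gap] + h[gap + 1]) / 2
  }
  groups <- stage("cut", cut_tree(tree, cut_threshold))
  newick <- stage("newick", to_newick(tree))
  comparison <- NULL
  if (!is.null(reference_tree)) {
    comparison <- stage("compare", compare_trees(newick, reference_tree))
  }
  res <- structure(list(
    composition = composition, marker_areas = areas,
    pca = pca, split = split, lda = lda, classification = classification,
    centroid_dist = d, tree = tree, groups = groups, newick = newick,
    tree_comparison = comparison, seed = seed,
    params = list(pca_k = pca_k, n_train = n_train, stratified = stratified,
                  shrinkage = shrinkage, hca_factors = hca_factors,
                  cut_threshold = cut_threshold, height_scale = height_scale,
                  preprocess = unclass(config))
  ), class = "ir_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.ir_pipeline_result <- function(x, ...) {
  cat("<ir_pipeline_result>\n")
  cat(sprintf("  %d training / %d validation spectra; PCA k = %d (%.1f%% variance)\n",
              sum(x$split$role == "train"), sum(x$split$role == "validation"),
              x$pca$k, sum(x$pca$explained_variance_pct)))
  cat(sprintf("  species hit rate %.1f%%, genus %.1f%%\n",
              x$classification$species_hit_rate_pct,
              x$classification$genus_hit_rate_pct))
  cat(sprintf("  tree: %d species, %d groups at threshold %.4g\n",
              length(x$tree$labels), max(x$groups$group_id),
              attr(x$groups, "threshold")))
  invisible(x)
}

#' Write a pipeline result bundle to a directory
#'
#' Emits the composition table, per-spectrum marker areas, predictions,
#' PCA variance table, the Newick tree, the group table, the optional tree
#' comparison and a YAML run manifest (parameters, seed, package version).
#' Numeric CSV content is printed by [readr::write_csv()] at full
#' round-trip precision, so identical runs produce byte-identical files.
#'
#' @param res An `ir_pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_composition_csv(res$composition, file.path(dir, "composition.csv"))
  readr::write_csv(res$marker_areas, file.path(dir, "marker_areas.csv"))
  write_predictions_csv(res$classification, file.path(dir, "predictions.csv"))
  readr::write_csv(tidy(res$pca), file.path(dir, "pca_variance.csv"))
  readr::write_csv(res$split, file.path(dir, "split.csv"))
  writeLines(res$newick, file.path(dir, "tree.nwk"))
  write_groups_csv(res$groups, file.path(dir, "groups.csv"))
  hr <- glance(res$classification)
  readr::write_csv(hr, file.path(dir, "hit_rates.csv"))
  if (!is.null(res$tree_comparison)) {
    readr::write_csv(res$tree_comparison, file.path(dir, "tree_comparison.csv"))
  }
  yaml::write_yaml(list(schema_version = 1L, seed = res$seed,
                        params = res$params,
                        package_version = as.character(utils::packageVersion("silkir"))),
                   file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}
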