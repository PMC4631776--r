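#' Euclidean distances between LDA species centroids
#'
#' Pairwise Euclidean distances between species centroids in discriminant
#' factor space, the input to Ward clustering. By default the 10
#' largest-discrimination factors are used.
#'
#' @param x An `ir_lda` model, or a numeric matrix of centroid coordinates
#'   with species rownames.
#' @param n_factors Number of leading factors to use (capped at the number
#'   available).
#' @return Symmetric distance matrix with zero diagonal, species dimnames.
#' @export
centroid_distances <- function(x, n_factors = 10) {
  cm <- if (inherits(x, "ir_lda")) x$centroids else as.matrix(x)
  if (is.null(rownames(cm))) stop("centroid matrix needs species rownames", call. = FALSE)
  if (anyDuplicated(rownames(cm))) stop("duplicate species in centroid matrix", call. = FALSE)
  if (nrow(cm) < 2) stop("need at least 2 species", call. = FALSE)
  bad <- rownames(cm)[!stats::complete.cases(cm) | apply(!is.finite(cm), 1, any)]
  if (length(bad)) {
    stop("non-finite centroid coordinates for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cm <- cm[, seq_len(min(n_factors, ncol(cm))), drop = FALSE]
  as.matrix(stats::dist(cm))
}

#' Ward hierarchical clustering of species
#'
#' Agglomerative Ward clustering: starting from singleton clusters, each
#' merge minimizes the increase in total within-cluster variance
#' (Lance-Williams update). Merge heights are reported on the Euclidean
#' distance scale by default (two coincident points merge at height 0; two
#' singletons merge at their Euclidean distance), so distance thresholds
#' quoted on that scale apply directly; the squared-scale convention used
#' by some implementations is available via `height_scale = "squared"`.
#'
#' @param d Symmetric distance matrix from [centroid_distances()] (or a
#'   `dist` object of Euclidean distances).
#' @param height_scale `"euclidean"` (default) or `"squared"`.
#' @return An `hclust` object (merge matrix, heights, labels).
#' @export
ward_linkage <- function(d, height_scale = c("euclidean", "squared")) {
  height_scale <- match.arg(height_scale)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("d must be a square distance matrix", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("d must be symmetric", call. = FALSE)
  }
  dd <- stats::as.dist(d)
  if (height_scale == "euclidean") {
    stats::hclust(dd, method = "ward.D2")
  } else {
    stats::hclust(dd^2, method = "ward.D")
  }
}

#' Cut an ultrametric tree at a distance threshold
#'
#' Groups together all species connected by merges whose height is strictly
#' below the threshold (e.g. "species with a Euclidean distance smaller
#' than 525 were grouped together"); species joining only at or above the
#' threshold stay in separate groups. Group ids are numbered by first
#' appearance in the leaf order of the tree.
#'
#' @param tree An `hclust` from [ward_linkage()].
#' @param threshold Positive height threshold.
#' @return Tibble `species`, `group_id`, with the threshold as an attribute.
#' @export
cut_tree <- function(tree, threshold) {
  stopifnot(inherits(tree, "hclust"), threshold > 0)
  n <- length(tree$labels)
  # union-find over merges below the threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cluster_of_merge <- integer(nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    if (tree$height[m] >= threshold) break
    members <- function(v) {
      if (v < 0) -v else cluster_of_merge[v]
    }
    a <- find(members(tree$merge[m, 1]))
    b <- find(members(tree$merge[m, 2]))
    parent[b] <- a
    cluster_of_merge[m] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ord_roots <- unique(roots[tree$order])
  group <- match(roots, ord_roots)
  out <- tibble::tibble(species = tree$labels, group_id = group)
  attr(out, "threshold") <- threshold
  out
}

#' Export an ultrametric tree as Newick
#'
#' Converts the merge tree to a rooted binary Newick string with branch
#' lengths such that every root-to-tip path equals half the root merge
#' height (the ultrametric convention). Labels containing spaces are
#' underscored.
#'
#' @param tree An `hclust`.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy)
}

#' Compare two trees: Robinson-Foulds and cophenetic correlation
#'
#' Quantitative comparison of a spectral tree with a reference phylogeny:
#' the symmetric-difference Robinson-Foulds distance on unrooted
#' topologies, its normalization by the maximum `2(n-3)`, and — when both
#' trees carry branch lengths — the Pearson correlation of their cophenetic
#' (patristic) distance matrices. Leaf names can be normalized before
#' matching.
#'
#' @param a,b Newick strings, Newick file paths, or `phylo` objects with
#'   identical leaf sets.
#' @param name_normalizer Function applied to tip labels before matching
#'   (default: spaces to underscores).
#' @return Tibble with `robinson_foulds`, `normalized_rf`,
#'   `cophenetic_correlation` (`NA` if either tree lacks branch lengths).
#' @export
compare_trees <- function(a, b, name_normalizer = function(x) gsub(" ", "_", x)) {
  ta <- as_phylo_input(a)
  tb <- as_phylo_input(b)
  ta$tip.label <- name_normalizer(ta$tip.label)
  tb$tip.label <- name_normalizer(tb$tip.label)
  only_a <- setdiff(ta$tip.label, tb$tip.label)
  only_b <- setdiff(tb$tip.label, ta$tip.label)
  if (length(only_a) || length(only_b)) {
    stop("leaf sets differ; only in first: [", paste(only_a, collapse = ", "),
         "]; only in second: [", paste(only_b, collapse = ", "), "]",
         call. = FALSE)
  }
  n <- length(ta$tip.label)
  rf <- phangorn::RF.dist(ape::unroot(ta), ape::unroot(tb), normalize = FALSE)
  nrf <- if (n > 3) rf / (2 * (n - 3)) else 0
  coph <- NA_real_
  if (!is.null(ta$edge.length) && !is.null(tb$edge.length)) {
    da <- stats::cophenetic(ta)
    db <- stats::cophenetic(tb)
    db <- db[rownames(da), colnames(da)]
    coph <- stats::cor(da[lower.tri(da)], db[lower.tri(db)])
  }
  tibble::tibble(robinson_foulds = as.integer(rf), normalized_rf = nrf,
                 cophenetic_correlation = coph)
}

as_phylo_input <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (inherits(x, "hclust")) return(ape::as.phylo(x))
  if (is.character(x) && length(x) == 1) {
    if (file.exists(x)) return(ape::read.tree(x))
    return(ape::read.tree(text = x))
  }
  stop("expected a phylo object, hclust, Newick string or file path", call. = FALSE)
}

#' Write a group assignment table to CSV
#'
#' @param groups Output of [cut_tree()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_groups_csv <- function(groups, path) {
  readr::write_csv(groups, path)
  invisible(path)
}
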