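# Brute-force independent oracles for clustering and tree comparison.

# greedy Ward oracle from raw coordinates: at every step enumerate all
# cluster pairs and merge the one with the smallest increase in total
# within-cluster sum of squares; returns merge heights sqrt(2 * deltaSS)
ward_oracle <- function(coords) {
  clusters <- lapply(seq_len(nrow(coords)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- coords[clusters[[i]], , drop = FALSE]
        b <- coords[clusters[[j]], , drop = FALSE]
        na <- nrow(a); nb <- nrow(b)
        dss <- na * nb / (na + nb) *
          sum((colMeans(a) - colMeans(b))^2)
        if (dss < best_d) { best_d <- dss; best <- c(i, j) }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
      height = sqrt(2 * best_d))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# leaf sets below each merge of an hclust object
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[m]] <- sort(c(get(hc$merge[m, 1]), get(hc$merge[m, 2])))
  }
  sets
}

# non-trivial bipartitions of an unrooted phylo, canonicalized
bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  desc <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  internal <- phy$edge[phy$edge[, 2] > n, 2]
  anchor <- sort(phy$tip.label)[1]  # same anchor whatever the tree's tip order
  splits <- lapply(internal, function(nd) {
    side <- sort(desc(nd))
    if (length(side) <= 1 || length(side) >= n - 1) return(NULL)
    other <- sort(setdiff(phy$tip.label, side))
    if (anchor %in% side) paste(side, collapse = "|")
    else paste(other, collapse = "|")
  })
  unique(unlist(splits))
}

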