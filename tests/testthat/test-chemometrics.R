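test_that("correlation PCA matches a dense eigendecomposition oracle", {
  X <- withr::with_seed(1, matrix(rnorm(20 * 50), 20, 50))
  p <- fit_pca(X, k = 19)
  # independent oracle: explicit correlation matrix, dense eigensolver
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  expect_equal(p$eig, ev$values[1:19], tolerance = 1e-8)
  for (j in 1:19) {
    dot <- abs(sum(p$loadings[, j] * ev$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  # loadings are orthonormal
  expect_equal(crossprod(p$loadings), diag(19), tolerance = 1e-8)
  # explained variance is non-increasing and sums to 100 for the full rank
  expect_true(all(diff(p$explained_variance_pct) <= 1e-12))
  Xf <- withr::with_seed(2, matrix(rnorm(60 * 8), 60, 8))
  pf <- fit_pca(Xf, k = 8)
  expect_equal(sum(pf$explained_variance_pct), 100, tolerance = 1e-6)
})

test_that("rank-1 data and per-variable rescaling behave as correlation PCA must", {
  t_ <- withr::with_seed(3, rnorm(20))
  v <- withr::with_seed(4, runif(6, 0.5, 2))
  X <- outer(t_, v)
  p <- suppressWarnings(fit_pca(X, k = 1))
  expect_equal(p$explained_variance_pct[1], 100, tolerance = 1e-8)

  Y <- withr::with_seed(5, matrix(rnorm(15 * 7), 15, 7))
  p1 <- fit_pca(Y, k = 5)
  p2 <- fit_pca(sweep(Y, 2, c(1, 10, 0.1, 5, 2, 100, 0.01), "*"), k = 5)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)

  # constant variable dropped with warning, recorded in the model
  Yc <- cbind(Y, 3)
  expect_warning(pc <- fit_pca(Yc, k = 5), "constant variable")
  expect_equal(pc$dropped_vars, 8L)
  expect_error(fit_pca(Y, k = 20), "rank")
})

test_that("projection is consistent, centred and invertible at full rank", {
  X <- withr::with_seed(6, matrix(rnorm(30 * 10), 30, 10))
  p <- fit_pca(X, k = 10)
  expect_equal(project(p, X), p$scores, tolerance = 1e-10)
  expect_equal(as.vector(project(p, matrix(colMeans(X), 1))), rep(0, 10),
               tolerance = 1e-10)
  # full-rank reconstruction of the standardized data
  Z <- scale(X)
  expect_equal(p$scores %*% t(p$loadings), unclass(Z)[, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(project(p, X[, 1:5]), "mismatch")
})

test_that("train/validation splitting is reproducible and correctly sized", {
  man <- toy_manifest(sprintf("s%02d", 1:52),
                      species = rep(c("A", "B", "C", "D"), each = 13))
  s1 <- split_dataset(man, n_train = 27, seed = 9)
  expect_equal(sum(s1$role == "validation"), 25)
  expect_equal(sort(unique(s1$role)), c("train", "validation"))
  expect_identical(s1, split_dataset(man, n_train = 27, seed = 9))
  expect_false(identical(s1$role, split_dataset(man, 27, seed = 10)$role))

  # stratified proportional allocation: 6 equal classes of 10, 30 train
  man6 <- toy_manifest(sprintf("t%02d", 1:60),
                       species = rep(letters[1:6], each = 10))
  s6 <- split_dataset(man6, n_train = 30, seed = 1, stratified = TRUE)
  per_class <- table(s6$species[s6$role == "train"])
  expect_true(all(per_class == 5))

  # every class keeps at least one training spectrum even when tiny
  man_small <- toy_manifest(sprintf("u%02d", 1:22),
                            species = c(rep("big", 20), "tiny", "tiny"))
  ss <- split_dataset(man_small, n_train = 5, seed = 2, stratified = TRUE)
  expect_gte(sum(ss$role == "train" & ss$species == "tiny"), 1)

  man_bad <- toy_manifest(c("a1", "a2", "b1"), species = c("A", "A", "B"))
  expect_error(split_dataset(man_bad, 2, stratified = TRUE), "B")
  expect_error(split_dataset(man, 52), "n_train")
})

test_that("two-class LDA matches the closed-form Fisher discriminant", {
  set.seed(7)
  n <- 40; k <- 5
  mu1 <- c(2, 0, 1, 0, 0); mu2 <- c(0, 1, 0, 0, 1)
  A <- matrix(rnorm(k * k, sd = 0.3), k, k); Sigma <- crossprod(A) + diag(k) * 0.5
  L <- chol(Sigma)
  X <- rbind(matrix(rnorm(n * k), n, k) %*% L + matrix(mu1, n, k, byrow = TRUE),
             matrix(rnorm(n * k), n, k) %*% L + matrix(mu2, n, k, byrow = TRUE))
  labels <- rep(c("one", "two"), each = n)
  m <- fit_lda(X, labels, shrinkage = 0)
  # oracle: w = Sw^-1 (mu1 - mu2), Sw pooled within-class covariance
  Sw <- matrix(0, k, k)
  for (cl in c("one", "two")) {
    Xi <- scale(X[labels == cl, ], scale = FALSE)
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / (2 * n)
  w_oracle <- solve(Sw, colMeans(X[labels == "one", ]) -
                        colMeans(X[labels == "two", ]))
  cosang <- abs(sum(m$coefficients[, 1] * w_oracle)) /
    sqrt(sum(m$coefficients[, 1]^2) * sum(w_oracle^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
  expect_equal(m$n_factors, 1)
  expect_equal(sum(m$priors), 1)
})

test_that("separated classes give aligned discriminants and 100% training hits", {
  set.seed(8)
  delta <- c(12, 0)
  X <- rbind(matrix(rnorm(30 * 2), 30, 2),
             sweep(matrix(rnorm(30 * 2), 30, 2), 2, delta, "+"))
  labels <- rep(c("p", "q"), each = 30)
  m <- fit_lda(X, labels)
  dirn <- m$coefficients[, 1] / sqrt(sum(m$coefficients[, 1]^2))
  expect_gt(abs(dirn[1]), 0.98)  # parallel to the class-mean difference
  cls <- classify(X, pca = NULL, lda = m,
                  manifest = toy_manifest(sprintf("x%02d", 1:60),
                                          species = labels, genus = labels))
  expect_equal(cls$species_hit_rate_pct, 100)

  # duplicating every training spectrum leaves the model unchanged
  m2 <- fit_lda(rbind(X, X), c(labels, labels))
  expect_equal(m2$centroids, m$centroids, tolerance = 1e-10)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-10)

  # singular within-class scatter advises shrinkage
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_lda(Xs, labels, shrinkage = 0), "shrinkage")
  expect_silent(fit_lda(Xs, labels, shrinkage = 1e-4))
})

test_that("hit rates respect the genus coarsening and label invariances", {
  set.seed(9)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(20 * 2, sd = 0.3), 20, 2), 2, centers[i, ], "+")
  }))
  sp <- rep(c("s1", "s2", "s3", "s4"), each = 20)
  man1 <- toy_manifest(sprintf("a%02d", 1:80), species = sp, genus = sp)
  m <- fit_lda(X, sp)
  c1 <- classify(X, NULL, m, man1)
  # one species per genus: identical rates
  expect_equal(c1$genus_hit_rate_pct, c1$species_hit_rate_pct)
  expect_gte(c1$genus_hit_rate_pct, c1$species_hit_rate_pct)
  # confusion row sums equal per-class counts
  expect_equal(unname(rowSums(c1$confusion)), rep(20, 4))

  # permuting the data row order leaves the rates unchanged
  perm <- sample(80)
  m_p <- fit_lda(X[perm, ], sp[perm])
  c_p <- classify(X[perm, ], NULL, m_p, man1[perm, ])
  expect_equal(c_p$species_hit_rate_pct, c1$species_hit_rate_pct)

  # genus coarser than species: rate can only rise
  man2 <- toy_manifest(sprintf("a%02d", 1:80), species = sp,
                       genus = rep(c("g1", "g1", "g2", "g2"), each = 20))
  c2 <- classify(X, NULL, m, man2)
  expect_gte(c2$genus_hit_rate_pct, c2$species_hit_rate_pct)

  # a validation species unseen in training is an automatic flagged miss
  man3 <- man1
  man3$species[1:20] <- "mystery"
  c3 <- classify(X, NULL, m, man3)
  expect_equal(c3$unseen_species, "mystery")
  expect_lte(c3$species_hit_rate_pct, 75)
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(10)
  X <- rbind(matrix(rnorm(25 * 3), 25, 3),
             sweep(matrix(rnorm(25 * 3), 25, 3), 2, c(3, 1, 0), "+"),
             sweep(matrix(rnorm(25 * 3), 25, 3), 2, c(0, 4, 2), "+"))
  labels <- rep(c("a", "b", "c"), each = 25)
  m <- fit_lda(X, labels, shrinkage = 0)
  ref <- MASS::lda(X, grouping = labels)
  # same discriminant subspace: each reference axis lies in ours
  Q <- qr.Q(qr(m$coefficients))
  for (j in 1:2) {
    v <- ref$scaling[, j]
    resid <- v - Q %*% crossprod(Q, v)
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum(v^2)), 1e-6)
  }
  # identical hold-out predictions under equal priors
  Xnew <- sweep(matrix(rnorm(30 * 3), 30, 3), 2, c(1.5, 2, 1), "+")
  man <- toy_manifest(sprintf("n%02d", 1:30), species = rep("a", 30))
  ours <- classify(Xnew, NULL, m, man)$predictions$predicted_species
  theirs <- as.character(stats::predict(
    MASS::lda(X, grouping = labels, prior = rep(1 / 3, 3)), Xnew)$class)
  expect_equal(ours, theirs)
})
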