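test_that("Gower distance satisfies its defining identities", {
  fm <- random_mixed_fm(10)
  D <- gower_matrix(fm)
  expect_equal(diag(unclass(D)), rep(0, 10), ignore_attr = TRUE)
  expect_lt(max(abs(D - t(D))), 1e-12)
  expect_true(all(D >= 0 & D <= 1))

  # maximal dissimilarity: interval at opposite ends + categorical mismatch
  fm2 <- feature_matrix(cbind(x = c(0, 10, 5), b = c(0, 1, 0)),
                        c("continuous", "binary"))
  D2 <- gower_matrix(fm2)
  expect_equal(D2[1, 2], 1)

  expect_error(gower_matrix(feature_matrix(cbind(x = rep(1, 4), b = c(0, 1, 0, 1)),
                                           c("continuous", "binary"))),
               "zero range")
  expect_error(gower_matrix(fm, weights = rep(0, 6)), "weights are zero")
})

test_that("Gower matrix equals the naive double-loop oracle and cluster::daisy", {
  skip_if_not_installed("cluster")
  for (seed in 1:5) {
    fm <- random_mixed_fm(n = 20, n_cont = 3, n_bin = 3, seed = seed)
    D <- unclass(gower_matrix(fm))
    Do <- gower_oracle(fm$values, fm$meta$kind)
    expect_lt(max(abs(D - Do)), 1e-12)
    # independent library cross-check
    df <- as.data.frame(fm$values)
    for (j in which(fm$meta$kind == "binary")) df[[j]] <- factor(df[[j]])
    Dd <- as.matrix(cluster::daisy(df, metric = "gower"))
    expect_lt(max(abs(D - Dd)), 1e-12)
  }
  # non-uniform weights agree with the oracle too
  fm <- random_mixed_fm(15, seed = 9)
  w <- c(2, 1, 0.5, 1, 3, 1)
  expect_lt(max(abs(unclass(gower_matrix(fm, weights = w)) -
                      gower_oracle(fm$values, fm$meta$kind, w))), 1e-12)
})

test_that("Gower distances satisfy the triangle inequality on random triples", {
  fm <- random_mixed_fm(30, seed = 4)
  D <- unclass(gower_matrix(fm))
  set.seed(5)
  for (rep in 1:200) {
    ijk <- sample(30, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("FAMD reduces to PCA for all-continuous input", {
  set.seed(6)
  vals <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  fm <- feature_matrix(vals, rep("continuous", 4))
  emb <- famd_embed(fm, n_components = 3)
  # oracle: SVD scores of the identically standardized matrix
  Z <- apply(vals, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  sv <- svd(Z)
  scores_o <- sv$u[, 1:3] %*% diag(sv$d[1:3])
  for (c in 1:3) {
    sgn <- sign(sum(scores_o[, c] * emb$scores[, c]))
    expect_lt(max(abs(emb$scores[, c] - sgn * scores_o[, c])), 1e-8)
  }
})

test_that("FAMD matches an MCA oracle for all-categorical input", {
  set.seed(7)
  vals <- matrix(rbinom(36, 1, 0.5), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (j in 1:3) if (length(unique(vals[, j])) == 1) vals[1, j] <- 1 - vals[1, j]
  fm <- feature_matrix(vals, rep("binary", 3))
  emb <- famd_embed(fm, n_components = 2)
  # oracle: correspondence analysis of the full indicator matrix
  G <- cbind(vals == 0, vals == 1) * 1
  P <- G / sum(G)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  row_coord <- diag(1 / sqrt(r)) %*% sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (c in 1:2) {
    expect_gt(abs(cor(emb$scores[, c], row_coord[, c])), 1 - 1e-8)
  }
})

test_that("FAMD embedding maps duplicated rows identically and checks rank", {
  fm <- random_mixed_fm(12, seed = 8)
  vals <- rbind(fm$values, fm$values[3, , drop = FALSE])
  fm2 <- feature_matrix(vals, fm$meta$kind)
  emb <- famd_embed(fm2, n_components = 3)
  expect_equal(emb$scores[13, ], emb$scores[3, ], ignore_attr = TRUE)
  expect_error(famd_embed(fm, n_components = 100), "n_components")
})

test_that("Ward clustering recovers separated groups and matches a hand trace", {
  # two well-separated clouds
  set.seed(9)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 10, 0.1), 10))
  res <- ward_cluster(X, k = 2)
  expect_equal(length(unique(res$labels[1:10])), 1)
  expect_equal(length(unique(res$labels[11:20])), 1)
  expect_false(res$labels[1] == res$labels[11])

  # k = n: every point its own cluster
  res_n <- ward_cluster(X, k = 20)
  expect_equal(sort(unique(res_n$labels)), 1:20)
  expect_error(ward_cluster(X, k = 21), "exceeds")

  # 8-point 1-D configuration: merge heights match a naive Ward
  # (Lance-Williams) agglomeration written out in full here
  x <- c(0, 0.5, 2, 2.4, 6, 6.3, 9, 9.8)
  D2 <- outer(x, x, function(a, b) (a - b)^2)  # squared Euclidean
  naive_ward_heights <- function(D2) {
    n <- nrow(D2)
    active <- seq_len(n)
    size <- rep(1, n)
    d <- D2
    heights <- numeric(n - 1)
    for (step in seq_len(n - 1)) {
      best <- c(NA, NA)
      best_val <- Inf
      for (i in active) for (j in active) {
        if (i < j && d[i, j] < best_val) {
          best_val <- d[i, j]
          best <- c(i, j)
        }
      }
      i <- best[1]; j <- best[2]
      heights[step] <- sqrt(best_val)
      for (h in setdiff(active, c(i, j))) {
        d[i, h] <- d[h, i] <-
          ((size[i] + size[h]) * d[i, h] + (size[j] + size[h]) * d[j, h] -
             size[h] * d[i, j]) / (size[i] + size[j] + size[h])
      }
      size[i] <- size[i] + size[j]
      active <- setdiff(active, j)
    }
    heights
  }
  expected <- naive_ward_heights(D2)
  tree <- attr(ward_cluster(as.matrix(stats::dist(x)), k = 2), "tree")
  expect_equal(tree$height, expected, tolerance = 1e-10)
})

test_that("K-means recovers blobs, respects duplicates, and beats random labelings", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20), matrix(rnorm(40, 5, 0.2), 20))
  res <- kmeans_cluster(X, k = 2, seed = 1)
  expect_equal(length(unique(res$labels[1:20])), 1)
  expect_false(res$labels[1] == res$labels[21])

  # duplicated rows land in the same cluster
  Xd <- rbind(X, X[5, , drop = FALSE])
  resd <- kmeans_cluster(Xd, k = 2, seed = 1)
  expect_equal(resd$labels[41], resd$labels[5])

  expect_error(kmeans_cluster(matrix(rep(1, 10), 5), k = 3), "distinct rows")

  # returned inertia is no worse than 50 random assignments
  set.seed(11)
  Y <- matrix(rnorm(60), 30, 2)
  resy <- kmeans_cluster(Y, k = 3, seed = 2)
  inertia <- function(X, lab) {
    sum(sapply(unique(lab), function(g) {
      Xg <- X[lab == g, , drop = FALSE]
      sum(sweep(Xg, 2, colMeans(Xg))^2)
    }))
  }
  got <- attr(resy, "tot_withinss")
  for (r in 1:50) {
    rand_lab <- sample(1:3, 30, replace = TRUE)
    if (length(unique(rand_lab)) < 3) next
    expect_lte(got, inertia(Y, rand_lab) + 1e-8)
  }
})

test_that("all three pathways are permutation-equivariant", {
  skip_if_not_installed("mclust")
  fm <- random_mixed_fm(40, n_cont = 3, n_bin = 3, seed = 12)
  set.seed(13)
  perm <- sample(40)
  fm_p <- feature_matrix(fm$values[perm, ], fm$meta$kind)

  l1 <- ward_cluster(gower_matrix(fm), 3)$labels
  l1p <- ward_cluster(gower_matrix(fm_p), 3)$labels
  expect_equal(mclust::adjustedRandIndex(l1[perm], l1p), 1)

  e <- famd_embed(scale_features(fm), n_components = 3)
  ep <- famd_embed(scale_features(fm_p), n_components = 3)
  l2 <- ward_cluster(e, 3)$labels
  l2p <- ward_cluster(ep, 3)$labels
  expect_equal(mclust::adjustedRandIndex(l2[perm], l2p), 1)

  # K-means equivariance is checked on separable structure so both runs
  # reach the same global optimum
  set.seed(14)
  Xb <- rbind(matrix(rnorm(30, 0, 0.2), 15), matrix(rnorm(30, 4, 0.2), 15),
              matrix(rnorm(30, 8, 0.2), 15))
  permb <- sample(45)
  l3 <- kmeans_cluster(Xb, 3, seed = 5, n_init = 10)$labels
  l3p <- kmeans_cluster(Xb[permb, ], 3, seed = 5, n_init = 10)$labels
  expect_equal(mclust::adjustedRandIndex(l3[permb], l3p), 1)
})
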