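# t-SNE clustering protocol: distances, conditionals, embedding, k-means,
# silhouettes, model selection, reports.

# Planted low-dimensional blob distance matrix (Euclidean, not RMSD) for
# the embedding/partition machinery.
make_blobs <- function(n_per, centers, spread = 0.1, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    matrix(rnorm(n_per * ncol(centers), sd = spread), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
  }))
  D <- as.matrix(dist(pts))
  attr(D, "labels") <- data.frame(source = "blobs",
                                  frame = seq_len(nrow(pts)))
  class(D) <- "DistanceMatrix"
  list(D = D, truth = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("the RMSD matrix is symmetric, zero-diagonal, and rigid-blind", {
  ens <- fx_coil()$ensemble
  D <- rmsd_matrix(ens)
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-9)
  expect_true(all(diag(unclass(D)) == 0))
  expect_true(all(unclass(D) >= 0))
  # a duplicated, rigidly moved frame sits at distance 0
  dup <- ens
  dup$coords[2, , ] <- random_rigid(get_frame(ens, 1), seed = 3)
  D2 <- rmsd_matrix(dup)
  expect_lt(D2[1, 2], 1e-6)
})

test_that("pairwise RMSD agrees with a rotation-grid oracle on a toy", {
  set.seed(60)
  A <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(9), 3, 3)
  # coarse SO(3) grid + local refinement, independent of the Kabsch path
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((Ac %*% t(rot(p[1], p[2], p[3])) - Bc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13),
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  ref <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
  expect_equal(kabsch_rmsd(A, B), ref, tolerance = 1e-3)
})

test_that("downsampling modes are deterministic and bounded", {
  ens <- fx_coil()$ensemble
  full <- downsample(ens, n_frames(ens))
  expect_equal(full$frames, seq_len(n_frames(ens)))
  s1 <- downsample(ens, 4, mode = "stride")
  s2 <- downsample(ens, 4, mode = "stride")
  expect_identical(s1$frames, s2$frames)
  r1 <- downsample(ens, 4, mode = "random", seed = 5)
  r2 <- downsample(ens, 4, mode = "random", seed = 5)
  expect_identical(r1$frames, r2$frames)
  expect_error(downsample(ens, 99), "target")
})

test_that("conditional calibration hits the target entropy exactly", {
  # 4 mutually equidistant points: conditionals are uniform at any sigma
  D <- matrix(1, 4, 4); diag(D) <- 0
  m <- calibrate_conditionals(D, 3)
  expect_equal(m$P_cond[1, -1], rep(1 / 3, 3), tolerance = 1e-9)
  blobs <- make_blobs(15, rbind(c(0, 0), c(5, 5)), seed = 61)
  m2 <- calibrate_conditionals(blobs$D, 8)
  expect_true(all(abs(m2$entropy - log2(8)) < 1e-5))
  expect_equal(rowSums(m2$P_cond), rep(1, 30), tolerance = 1e-12)
  expect_equal(sum(m2$P_joint), 1, tolerance = 1e-9)
  expect_equal(m2$P_joint, t(m2$P_joint), tolerance = 1e-15)
  expect_error(calibrate_conditionals(D, 1), "perplexity")
  expect_error(calibrate_conditionals(D, 4), "perplexity")
})

test_that("conditional calibration is permutation-equivariant", {
  blobs <- make_blobs(10, rbind(c(0, 0), c(4, 4)), seed = 62)
  m <- calibrate_conditionals(blobs$D, 6)
  p <- sample(20)
  Dp <- unclass(blobs$D)[p, p]
  mp <- calibrate_conditionals(Dp, 6)
  expect_equal(mp$P_joint, m$P_joint[p, p], tolerance = 1e-9)
})

test_that("t-SNE reduces KL and separates planted blobs", {
  blobs <- make_blobs(40, rbind(c(0, 0, 0), c(8, 0, 0)), seed = 63)
  m <- calibrate_conditionals(blobs$D, 12)
  emb <- tsne_embed(m, seed = 2, n_iter = 500)
  expect_gte(emb$kl, 0)
  tr <- emb$trace
  expect_lte(tr$kl[nrow(tr)], tr$kl[tr$iteration == 300] + 1e-6)
  # nearest-centroid separation of the two families is perfect
  y <- emb$Y
  c1 <- colMeans(y[blobs$truth == 1, ]); c2 <- colMeans(y[blobs$truth == 2, ])
  assigned <- ifelse(rowSums(sweep(y, 2, c1)^2) < rowSums(sweep(y, 2, c2)^2), 1, 2)
  expect_equal(unname(assigned), blobs$truth)
  # determinism under seed
  emb2 <- tsne_embed(m, seed = 2, n_iter = 500)
  expect_identical(emb$Y, emb2$Y)
})

test_that("k-means recovers blobs and is reproducible", {
  set.seed(64)
  Y <- rbind(matrix(rnorm(60, sd = 0.2), 30),
             matrix(rnorm(60, sd = 0.2), 30) + 5)
  lab <- kmeans_partition(Y, 2, seed = 9)
  truth <- rep(1:2, each = 30)
  expect_equal(length(unique(paste(lab, truth))), 2)  # exact recovery
  expect_identical(lab, kmeans_partition(Y, 2, seed = 9))
  expect_error(kmeans_partition(Y, 1), "N")
})

test_that("silhouettes match a brute-force double loop and cluster::silhouette", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(3, 3), c(-3, 3)), seed = 65)
  labels <- blobs$truth
  D <- unclass(blobs$D)
  got <- silhouette_score(labels, D)
  # naive double loop
  n <- length(labels)
  ref <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    ref[i] <- (b - a) / max(a, b)
  }
  expect_equal(got$per_point, ref, tolerance = 1e-12)
  cs <- cluster::silhouette(labels, dmatrix = D)
  expect_equal(got$per_point, as.numeric(cs[, "sil_width"]), tolerance = 1e-9)
  # two coincident pairs separated by d > 0 score a perfect 1
  Dp <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0))))
  expect_equal(silhouette_score(c(1, 1, 2, 2), Dp)$mean, 1.0)
  # random labels on a single blob hover near zero
  one <- make_blobs(60, rbind(c(0, 0)), seed = 66)
  set.seed(67)
  rnd <- sample(1:2, 60, replace = TRUE)
  expect_lt(abs(silhouette_score(rnd, one$D)$mean), 0.1)
  expect_error(silhouette_score(rep(1, 10), D[1:10, 1:10]), "single cluster")
})

test_that("the integrated score penalizes embedding-only structure", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(6, 6)), seed = 68)
  m <- calibrate_conditionals(blobs$D, 10)
  emb <- tsne_embed(m, seed = 3)
  lab <- kmeans_partition(emb, 2, seed = 5)
  sil <- integrated_silhouette(lab, emb, blobs$D)
  expect_equal(sil$S_i, sil$S_ld * sil$S_hd)
  expect_gt(sil$S_i, 0.5)  # clean in both spaces
  # structurally unclustered data: good embedding split, S_hd near zero
  one <- make_blobs(50, rbind(c(0, 0)), seed = 69)
  fakeY <- rbind(matrix(rnorm(50, sd = 0.1), 25),
                 matrix(rnorm(50, sd = 0.1), 25) + 10)
  lab2 <- kmeans_partition(fakeY, 2, seed = 6)
  sil2 <- integrated_silhouette(lab2, fakeY, one$D)
  expect_gt(sil2$S_ld, 0.8)
  expect_lt(abs(sil2$S_hd), 0.15)
  expect_lt(sil2$S_i, 0.15)
})

test_that("the hyperparameter scan recovers a planted 4-blob partition", {
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  blobs <- make_blobs(15, centers, spread = 0.15, seed = 70)
  scan <- hyperparameter_scan(blobs$D, c(5, 10), 4, seed = 8)
  expect_equal(nrow(scan$table), 2)
  expect_true(all(scan$best$S_i >= scan$table$S_i - 1e-12))
  # adjusted agreement with the planted partition is perfect
  tab <- table(scan$best$labels, blobs$truth)
  expect_equal(sum(apply(tab, 1, max)), 60)
  scan2 <- hyperparameter_scan(blobs$D, c(5, 10), 4, seed = 8)
  expect_identical(scan$table, scan2$table)
  expect_error(hyperparameter_scan(blobs$D, numeric(0), 4), "empty")
})

test_that("cluster reports summarize per cluster and per source", {
  fx <- fx_coil()
  ens <- fx$ensemble
  D <- rmsd_matrix(list(only = ens))
  labels <- rep(c(1, 2), each = 5)
  rep_tab <- cluster_report(list(only = ens), labels, attr(D, "labels"))
  expect_setequal(names(rep_tab)[1:2], c("cluster", "source"))
  expect_true(all(c("p", "BF", "p_Glob", "HF") %in% names(rep_tab)))
  expect_equal(sum(rep_tab$p, na.rm = TRUE), 1, tolerance = 1e-9)
  # absent cluster-source pair yields an explicit NA row
  two <- cluster_report(list(a = ens, b = ens),
                        c(rep(1, 10), rep(2, 10)),
                        data.frame(source = rep(c("a", "b"), each = 10),
                                   frame = rep(1:10, 2)))
  absent <- two[two$cluster == 1 & two$source == "b", ]
  expect_true(all(is.na(absent[, c("p", "p_Glob", "HF")])))
})
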