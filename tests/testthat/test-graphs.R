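test_that("patch pooling averages each grid block channelwise", {
  # constant map: every pooled vector equals the constant
  fm <- array(3.5, c(6, 6, 4, 2))
  out <- extract_patch_features(fm, c(3, 2, 2))
  expect_equal(dim(out), c(12, 2))
  expect_true(all(out == 3.5))
  # 2x2x1 grid with distinct quadrant values -> quadrant means
  fm2 <- array(0, c(4, 4, 2, 1))
  fm2[1:2, 1:2, , ] <- 1; fm2[3:4, 1:2, , ] <- 2
  fm2[1:2, 3:4, , ] <- 3; fm2[3:4, 3:4, , ] <- 4
  out2 <- extract_patch_features(fm2, c(2, 2, 1))
  expect_equal(as.numeric(out2), c(1, 2, 3, 4))  # x fastest, then y
  expect_error(extract_patch_features(fm2, c(5, 1, 1)), "larger")
})

test_that("patch pooling matches a naive triple-loop oracle", {
  set.seed(12)
  fm <- array(rnorm(8 * 6 * 4 * 3), c(8, 6, 4, 3))
  grid <- c(4, 3, 2)
  out <- extract_patch_features(fm, grid)
  p <- 1
  for (k in 1:grid[3]) for (j in 1:grid[2]) for (i in 1:grid[1]) {
    xs <- ((i - 1) * 2 + 1):(i * 2); ys <- ((j - 1) * 2 + 1):(j * 2)
    zs <- ((k - 1) * 2 + 1):(k * 2)
    for (ch in 1:3)
      expect_equal(out[p, ch], mean(fm[xs, ys, zs, ch]), tolerance = 1e-12)
    p <- p + 1
  }
})

test_that("within-graph connects nearest same-class pairs symmetrically", {
  X <- rbind(c(0, 0), c(1, 0))
  W <- build_within_graph(X, k_w = 1, labels = c("V", "V"))
  expect_equal(W, matrix(c(0, 1, 1, 0), 2))
  # all-distinct classes: empty graph with one warning per isolated class
  X3 <- matrix(rnorm(6), 3)
  ws <- capture_warnings(W3 <- build_within_graph(X3, 1, labels = c("V", "E", "NV")))
  expect_length(ws, 3)
  expect_true(all(grepl("isolated", ws)))
  expect_true(all(W3 == 0))
})

test_that("between-graph links closest cross-class points", {
  X <- rbind(c(0, 0), c(1, 0))
  W <- build_between_graph(X, k_b = 1, labels = c("V", "NV"))
  expect_equal(W, matrix(c(0, 1, 1, 0), 2))
  expect_warning(Wz <- build_between_graph(X, 1, labels = c("V", "V")), "single class")
  expect_true(all(Wz == 0))
})

test_that("graph builders match brute-force k-NN enumeration on labeled fixtures", {
  fx <- random_labeled_points(12, d = 2, seed = 3)
  Ww <- build_within_graph(fx$X, 2, labels = fx$labels, quiet = TRUE)
  Wb <- build_between_graph(fx$X, 2, labels = fx$labels, quiet = TRUE)
  expect_equal(Ww, brute_knn_graph(fx$X, fx$labels, 2, within = TRUE))
  expect_equal(Wb, brute_knn_graph(fx$X, fx$labels, 2, within = FALSE))
  expect_true(all(Ww * Wb == 0))
})

test_that("graph construction is permutation-equivariant", {
  fx <- random_labeled_points(15, d = 3, seed = 6)
  perm <- sample(15)
  for (builder in list(function(X, l) build_within_graph(X, 3, labels = l, quiet = TRUE),
                       function(X, l) build_between_graph(X, 2, labels = l, quiet = TRUE))) {
    W <- builder(fx$X, fx$labels)
    Wp <- builder(fx$X[perm, , drop = FALSE], fx$labels[perm])
    expect_equal(Wp, W[perm, perm])
  }
})

test_that("normalized adjacency has the stated closed forms and unit spectral bound", {
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  W2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(W2), matrix(0.5, 2, 2))
  set.seed(5)
  for (r in 1:5) {
    n <- sample(5:20, 1)
    W <- matrix(rbinom(n * n, 1, 0.3), n); W <- (W + t(W)) > 0
    W <- W * 1; diag(W) <- 0
    Wh <- normalize_adjacency(W)
    expect_equal(Wh, t(Wh))
    expect_lte(max(abs(eigen(Wh, symmetric = TRUE, only.values = TRUE)$values)),
               1 + 1e-9)
  }
})

test_that("Laplacian L = Diag - W: zero row sums and positive semidefinite", {
  expect_equal(laplacian_matrix(matrix(0, 3, 3)), matrix(0, 3, 3))
  W2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(laplacian_matrix(W2), matrix(c(1, -1, -1, 1), 2))
  set.seed(9)
  for (r in 1:5) {
    n <- sample(5:15, 1)
    W <- matrix(runif(n * n), n); W <- W + t(W); diag(W) <- 0
    L <- laplacian_matrix(W)
    expect_equal(rowSums(L), rep(0, n), tolerance = 1e-12)
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("discriminant graph bundle keeps within/between edges disjoint", {
  fx <- random_labeled_points(20, d = 4, seed = 13)
  pf <- patch_feature_set(list(fx$X), class_label = "V")
  expect_equal(pf$T, 1L)
  g <- discriminant_graph(fx$X, k_w = 3, k_b = 2, labels = fx$labels, quiet = TRUE)
  expect_true(all(g$W_w * g$W_b == 0))
  expect_equal(diag(g$W_w), rep(0, 20))
  expect_equal(g$L, laplacian_matrix(g$W_w))
  # triplet serialization inverts
  df <- graph_triplets(g$W_w)
  expect_equal(nrow(df), sum(g$W_w) / 2)
})
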