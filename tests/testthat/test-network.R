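# dense straight-line oracle for the GCN branch forward pass, written
# independently of the package implementation
oracle_temporal <- function(X0, Wb_hat, Ww_hat, params, K, residual = TRUE) {
  H <- X0 %*% params$t_proj
  for (k in 1:K) {
    Z <- Wb_hat %*% H %*% params[[paste0("t_B", k)]] -
         Ww_hat %*% H %*% params[[paste0("t_B", k)]]
    mu <- colMeans(Z)
    v <- colMeans((Z - matrix(mu, nrow(Z), ncol(Z), byrow = TRUE))^2)
    Zh <- (Z - matrix(mu, nrow(Z), ncol(Z), byrow = TRUE)) /
      matrix(sqrt(v + 1e-5), nrow(Z), ncol(Z), byrow = TRUE)
    A <- ifelse(Zh > 0, Zh, 0.1 * Zh)
    H <- if (residual && k >= 2) A + H else A
  }
  apply(H, 2, max)
}

test_that("backbone maps the reference-intensity volume to zero and keeps shape arithmetic", {
  m <- tiny_model()
  # intensity == normalization scale => normalized input 0 => zero features
  v0 <- array(m$intensity_scale, dim = m$volume_shape)
  f <- backbone_features(list(volumes = list(v0)) |> structure(class = "dce_sequence"), m)
  expect_equal(max(abs(f[[1]])), 0)
  # two x2 pools: feature grid = floor(shape / 4)
  expect_equal(dim(f[[1]])[1:3], m$volume_shape %/% 4L)
  # deterministic
  set.seed(1); v <- array(rnorm(prod(m$volume_shape), 100, 10), m$volume_shape)
  s <- dce_sequence(list(v), times = 0)
  expect_identical(backbone_features(s, m), backbone_features(s, m))
  expect_error(backbone_features(dce_sequence(list(array(100, c(4, 4, 2))), 0), m),
               "geometry")
})

test_that("temporal branch obeys the cancellation and residual identities and matches a dense oracle", {
  m <- tiny_model()
  set.seed(2)
  N <- 8; d0 <- m$d0
  X0 <- matrix(rnorm(N * d0), N, d0)
  W <- matrix(rbinom(N * N, 1, 0.4), N); W <- ((W + t(W)) > 0) * 1; diag(W) <- 0
  Wh <- normalize_adjacency(W)
  # identical between/within graphs cancel at every layer
  tb <- temporal_branch(X0, Wh, Wh, m)
  expect_equal(max(abs(tb$f_t)), 0)
  # residual identity: B_k = 0 for k >= 2 freezes the layer-1 output
  m0 <- m
  for (k in 2:m$config$K) m0$params[[paste0("t_B", k)]][] <- 0
  W2 <- matrix(rbinom(N * N, 1, 0.3), N); W2 <- ((W2 + t(W2)) > 0) * 1; diag(W2) <- 0
  Wb <- normalize_adjacency(W2)
  full <- temporal_branch(X0, Wb, Wh, m0)
  m1 <- m0; m1$config$K <- 1L
  one <- temporal_branch(X0, Wb, Wh, m1)
  expect_equal(full$f_t, one$f_t, tolerance = 1e-12)
  # dense straight-line oracle agreement
  for (r in 1:3) {
    set.seed(10 + r)
    X0r <- matrix(rnorm(N * d0), N, d0)
    tbr <- temporal_branch(X0r, Wb, Wh, m, training = TRUE)
    expect_equal(tbr$f_t,
                 oracle_temporal(X0r, Wb, Wh, m$params, m$config$K),
                 tolerance = 1e-6)
  }
})

test_that("temporal branch is permutation-equivariant in the graph nodes", {
  m <- tiny_model()
  set.seed(3)
  N <- 10
  X0 <- matrix(rnorm(N * m$d0), N, m$d0)
  W <- matrix(rbinom(N * N, 1, 0.4), N); W <- ((W + t(W)) > 0) * 1; diag(W) <- 0
  Wh <- normalize_adjacency(W)
  Wb <- normalize_adjacency(matrix(0, N, N))
  f1 <- temporal_branch(X0, Wb, Wh, m)$f_t
  perm <- sample(N)
  f2 <- temporal_branch(X0[perm, ], Wb, Wh[perm, perm], m)$f_t
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("structural branch reduces to one graph pass for T=1 and shares weights across volumes", {
  m <- tiny_model()
  set.seed(4)
  P <- m$P
  Xv <- matrix(rnorm(P * m$d0), P, m$d0)
  g1 <- list(Ww_hat = normalize_adjacency(brute_knn_graph(Xv, rep("x", P), 2)),
             Wb_hat = diag(P))
  one <- structural_branch(list(Xv), list(g1), m)
  expect_length(one$f_s, m$s_dims[length(m$s_dims)])
  # identical volumes with shared parameters give identical per-volume blocks
  two <- structural_branch(list(Xv, Xv), list(g1, g1), m)
  half <- length(two$f_s) / 2
  expect_equal(two$f_s[1:half], two$f_s[half + 1:half])
  # dense oracle (single layer chain, rectangular weights)
  G <- Xv %*% m$params$s_proj
  A <- g1$Wb_hat - g1$Ww_hat
  for (mm in 1:m$config$M) {
    Z <- A %*% G %*% m$params[[paste0("s_B", mm)]]
    mu <- colMeans(Z); v <- colMeans((Z - matrix(mu, nrow(Z), ncol(Z), byrow = TRUE))^2)
    Zh <- (Z - matrix(mu, nrow(Z), ncol(Z), byrow = TRUE)) /
      matrix(sqrt(v + 1e-5), nrow(Z), ncol(Z), byrow = TRUE)
    G <- ifelse(Zh > 0, Zh, 0.1 * Zh)
  }
  two_tr <- structural_branch(list(Xv), list(g1), m, training = TRUE)
  expect_equal(two_tr$f_s, apply(G, 2, max), tolerance = 1e-6)
})

test_that("discriminator yields sigmoid scores and a constant for the zero-weight net", {
  m <- tiny_model()
  for (nm in names(m$params))
    if (startsWith(nm, "disc_")) m$params[[nm]][] <- 0
  V <- prod(m$volume_shape)
  set.seed(6)
  s1 <- discriminator(matrix(rnorm(V * 3), V, 3), m)$score
  s2 <- discriminator(matrix(rnorm(V * 3, 5, 10), V, 3), m)$score
  expect_equal(s1, 0.5)  # sigmoid of the zero bias
  expect_equal(s2, 0.5)
  m2 <- tiny_model()
  s3 <- discriminator(matrix(rnorm(V * 3), V, 3), m2)$score
  expect_true(s3 > 0 && s3 < 1)
  expect_error(discriminator(matrix(0, 10, 3), m2), "geometry")
})

test_that("decoder emits a voxelwise two-class softmax and input-shaped volumes", {
  m <- tiny_model()
  set.seed(7)
  fwd <- stdgnn_forward(m, lapply(1:2, function(i) matrix(rnorm(m$P * m$d0), m$P, m$d0)),
                        label = "V")
  expect_equal(rowSums(fwd$decoder$cache$mask_prob2),
               rep(1, prod(m$volume_shape)), tolerance = 1e-6)
  expect_equal(dim(fwd$decoder$intensity), c(prod(m$volume_shape), m$n_phases))
  expect_equal(sum(fwd$probs), 1, tolerance = 1e-6)
  expect_error(decoder(rnorm(10), m), "dimension")
})
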