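test_that("tumor loss: one-hot, uniform and loop-oracle cases", {
  onehot <- diag(3)[c(1, 2, 3), ]
  p <- pmin(pmax(onehot, 1e-12), 1 - 1e-12)
  expect_lt(tumor_loss(p, c("V", "E", "NV")), 1e-9)
  D <- 7
  unif <- matrix(1 / 3, D, 3)
  expect_equal(tumor_loss(unif, rep("V", D)), D * log(3), tolerance = 1e-12)
  # random instance vs scalar loop
  set.seed(3)
  pr <- matrix(runif(15), 5); pr <- pr / rowSums(pr)
  tg <- sample(1:3, 5, replace = TRUE)
  w <- runif(5)
  ref <- 0
  for (i in 1:5) ref <- ref + w[i] * -log(pr[i, tg[i]])
  expect_equal(tumor_loss(pr, tg, w), ref, tolerance = 1e-9)
  # mask form: mean voxel binary cross-entropy per sample, summed
  mask <- c(1, 0, 0, 1)
  prob <- c(0.9, 0.2, 0.1, 0.6)
  ref2 <- -mean(mask * log(prob) + (1 - mask) * log(1 - prob))
  expect_equal(tumor_loss(list(prob), list(mask)), ref2, tolerance = 1e-12)
})

test_that("sliced Wasserstein: exact small cases and metric behavior", {
  set.seed(2)
  a <- matrix(rnorm(40), 20, 2)
  expect_equal(sliced_wasserstein(a, a, 32), 0)
  expect_equal(sliced_wasserstein(0, 1), 1)          # 1-D two-point sets
  expect_equal(sliced_wasserstein(c(0, 0), c(1, 1)), 1)
  b <- matrix(rnorm(40, 2), 20, 2)
  d_ab <- sliced_wasserstein(a, b, 64, seed = 4)
  expect_equal(d_ab, sliced_wasserstein(b, a, 64, seed = 4))  # symmetric
  expect_gt(d_ab, 0)
  expect_error(sliced_wasserstein(matrix(0, 0, 2), b), "empty")
  # triangle inequality spot check (same projections)
  cc <- matrix(rnorm(40, -1), 20, 2)
  d_ac <- sliced_wasserstein(a, cc, 64, seed = 4)
  d_cb <- sliced_wasserstein(cc, b, 64, seed = 4)
  expect_lte(d_ab, d_ac + d_cb + 1e-9)
})

test_that("adversarial loss reduces to the standard form and matches a loop oracle", {
  set.seed(5)
  real <- runif(6, 0.5, 0.95); fake <- runif(6, 0.05, 0.5)
  feats <- matrix(rnorm(18 * 4), 18, 4)
  labs <- rep(c("V", "E", "NV"), 6)
  # phi = 0, xi = 1: standard adversarial loss
  r <- adversarial_loss(real, fake, feats, labs, phi = 0, xi = 1)
  expect_equal(r$E_adv, -mean(log(real)) - mean(log(1 - fake)), tolerance = 1e-12)
  # identical class-conditional sets -> c = 0
  same <- rbind(feats[1:6, ], feats[1:6, ], feats[1:6, ])
  labs2 <- rep(c("V", "E", "NV"), each = 6)
  r2 <- adversarial_loss(real, fake, same, labs2, phi = 30, xi = 0.35)
  expect_equal(r2$c, 0)
  expect_equal(r2$E_adv, -mean(log(real)) - 0.35 * mean(log(1 - fake)),
               tolerance = 1e-12)
  # general case against a straight-line recomputation
  r3 <- adversarial_loss(real, fake, feats, labs, phi = 30, xi = 0.35, seed = 9)
  X <- feats / pmax(sqrt(rowSums(feats^2)), 1e-12)
  cs <- c(sliced_wasserstein(X[labs == "V", ], X[labs == "E", ], 64, seed = 9),
          sliced_wasserstein(X[labs == "V", ], X[labs == "NV", ], 64, seed = 9),
          sliced_wasserstein(X[labs == "E", ], X[labs == "NV", ], 64, seed = 9))
  w <- 30 * mean(cs) + 0.35
  expect_equal(r3$E_adv, -mean(log(real)) - mean(w * log(1 - fake)),
               tolerance = 1e-6)
  expect_warning(class_transport_cost(feats[1:3, ], rep("V", 3)), "single class")
  expect_error(adversarial_loss(c(0.5, 1), fake, c = 0), "strictly")
})

test_that("weight divergence is cosine similarity with degenerate-case flags", {
  Wb <- matrix(c(0, 1, 1, 0), 2); Ww <- matrix(c(0, 0, 0, 0), 2)
  z <- weight_divergence(Wb, Ww)
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "flag"), "zero_matrix")
  expect_equal(weight_divergence(Wb, Wb), 1)
  # binary disjoint within/between graphs give identically zero
  fx <- random_labeled_points(12, seed = 11)
  Ww2 <- build_within_graph(fx$X, 2, labels = fx$labels, quiet = TRUE)
  Wb2 <- build_between_graph(fx$X, 2, labels = fx$labels, quiet = TRUE)
  expect_equal(weight_divergence(Wb2, Ww2), 0)
  # soft-weighted variants against a hand cosine
  Ws1 <- soften_adjacency(Ww2, fx$X); Ws2 <- soften_adjacency(Wb2 + Ww2, fx$X)
  ref <- sum(Ws1 * Ws2) / (sqrt(sum(Ws1^2)) * sqrt(sum(Ws2^2)))
  expect_equal(weight_divergence(Ws2, Ws1), ref, tolerance = 1e-12)
  expect_error(weight_divergence(Wb, matrix(0, 3, 3)), "shape")
})

test_that("batch-hard triplet loss: separated clusters, coincident fixture, FD gradient", {
  # clusters separated by more than the margin: zero loss
  X <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2), matrix(rnorm(10, 5, 0.01), 5, 2))
  labs <- rep(c("V", "NV"), each = 5)
  expect_equal(triplet_loss(X, labs, margin = 0.3), 0)
  # anchor/positive coincident and negative coincident with anchor: loss = margin
  X2 <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_equal(triplet_loss(X2, c("V", "V", "NV"), margin = 0.3), 0.3)
  expect_warning(triplet_loss(X2, c("V", "V", "V"), margin = 0.3), "unmineable")
  # finite-difference check of the analytic gradient
  set.seed(17)
  X3 <- matrix(rnorm(12), 6, 2)
  l3 <- sample(c("V", "E", "NV"), 6, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  g <- triplet_loss(X3, l3, 0.3, grad = TRUE, quiet = TRUE)
  eps <- 1e-6
  for (ii in sample(length(X3), 4)) {
    Xp <- X3; Xp[ii] <- Xp[ii] + eps
    Xm <- X3; Xm[ii] <- Xm[ii] - eps
    fd <- (triplet_loss(Xp, l3, 0.3, quiet = TRUE) -
           triplet_loss(Xm, l3, 0.3, quiet = TRUE)) / (2 * eps)
    expect_equal(g$grad[ii], fd, tolerance = 1e-5)
  }
})

test_that("overall loss composes the printed weighted sum", {
  expect_equal(overall_loss()$E_overall, 0)
  r <- overall_loss(E_tumor = 1.5, E_weight = 0.4, E_adv = 2,
                    lambda_w = 0, lambda_a = 0)
  expect_equal(r$E_triplet_global, 1.5)
  r2 <- overall_loss(E_tumor = 1, E_weight = 0.5, E_adv = 2, E_triplet_t = 0.3,
                     E_triplet_s = 0.2, E_softmax = 0.7)
  expect_equal(r2$E_triplet_global, 1 + 0.2 * 0.5 + 0.5 * 2, tolerance = 1e-12)
  expect_equal(r2$E_overall, r2$E_triplet_global + 0.3 + 0.2 + 0.7, tolerance = 1e-12)
  expect_error(overall_loss(E_tumor = NaN), "non-finite")
})
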