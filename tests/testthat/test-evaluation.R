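test_that("Dice: identities, disjoint masks and hand arithmetic", {
  m1 <- array(0, c(4, 4, 2)); m1[1:2, 1:2, 1] <- 1
  expect_equal(dice_coefficient(m1, m1), 100, ignore_attr = TRUE)
  m2 <- array(0, c(4, 4, 2)); m2[3:4, 3:4, 2] <- 1
  expect_equal(dice_coefficient(m1, m2), 0)
  # |A| = 4, |B| = 4, |A n B| = 2 -> 50
  a <- array(0, c(4, 4, 1)); a[1:4, 1, 1] <- 1
  b <- array(0, c(4, 4, 1)); b[3:4, 1, 1] <- 1; b[1:2, 2, 1] <- 1
  expect_equal(dice_coefficient(a, b), 50)
  z <- dice_coefficient(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)))
  expect_equal(as.numeric(z), 100)
  expect_equal(attr(z, "flag"), "both_empty")
  expect_error(dice_coefficient(m1, array(0, c(2, 2, 2))), "mismatch")
})

test_that("Hausdorff distance respects physical spacing and equals a brute-force oracle", {
  m1 <- array(0, c(8, 8, 4)); m1[2, 2, 2] <- 1
  expect_equal(hausdorff_distance(m1, m1, c(2, 2, 2)), 0)
  m2 <- array(0, c(8, 8, 4)); m2[5, 2, 2] <- 1   # 3 voxels apart, 2 mm spacing
  expect_equal(hausdorff_distance(m1, m2, c(2, 2, 2)), 6)
  expect_error(hausdorff_distance(m1, array(0, c(8, 8, 4))), "empty")
  # random blobs vs O(n^2) all-pairs surface oracle
  set.seed(21)
  for (r in 1:3) {
    A <- array(runif(8 * 8 * 4) < 0.3, c(8, 8, 4)) * 1
    B <- array(runif(8 * 8 * 4) < 0.3, c(8, 8, 4)) * 1
    if (sum(A) == 0 || sum(B) == 0) next
    sp <- c(1.5, 1.5, 2.5)
    # independent surface extraction + all-pairs max-min
    surf <- function(M) {
      idx <- which(M != 0, arr.ind = TRUE)
      keep <- logical(nrow(idx))
      d <- dim(M)
      for (q in seq_len(nrow(idx))) {
        v <- idx[q, ]
        nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                    v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
        on_edge <- any(nb < 1) || any(t(nb) > d)
        bgn <- FALSE
        for (w in seq_len(6)) {
          p <- nb[w, ]
          if (all(p >= 1) && all(p <= d) && M[p[1], p[2], p[3]] == 0) bgn <- TRUE
        }
        keep[q] <- on_edge || bgn
      }
      idx[keep, , drop = FALSE]
    }
    dmax <- function(P1, P2) {
      best <- 0
      for (q in seq_len(nrow(P1))) {
        dd <- Inf
        for (w in seq_len(nrow(P2)))
          dd <- min(dd, sqrt(sum(((P1[q, ] - P2[w, ]) * sp)^2)))
        best <- max(best, dd)
      }
      best
    }
    sa <- surf(A); sb <- surf(B)
    expect_equal(hausdorff_distance(A, B, sp), max(dmax(sa, sb), dmax(sb, sa)),
                 tolerance = 1e-12)
  }
})

test_that("surface distance metrics are symmetric", {
  set.seed(4)
  A <- array(0, c(8, 8, 4)); A[2:4, 2:4, 2:3] <- 1
  B <- array(0, c(8, 8, 4)); B[3:6, 3:5, 2:3] <- 1
  sp <- c(1.9, 1.9, 2.5)
  expect_equal(hausdorff_distance(A, B, sp), hausdorff_distance(B, A, sp))
  expect_equal(surface_mse(A, B, sp), surface_mse(B, A, sp))
  expect_equal(dice_coefficient(A, B), dice_coefficient(B, A))
})

test_that("classification report: confusion structure, accuracy, AUC pair-count oracle", {
  lab <- c("V", "V", "E", "E", "NV", "NV")
  r <- classification_report(lab, lab)
  expect_equal(sum(diag(r$confusion)), 6)
  expect_equal(r$accuracy, 100)
  expect_equal(sum(r$confusion), 6)
  # constant predictor on a balanced set
  r2 <- classification_report(rep("V", 6), lab)
  expect_equal(r2$accuracy, 100 / 3, tolerance = 1e-9)
  expect_error(classification_report(c("V", "Q"), c("V", "V")), "unseen")
  # AUC equals the exhaustive positive/negative pair count
  set.seed(31)
  n <- 10
  truth <- sample(c("V", "E", "NV"), n, replace = TRUE)
  while (length(unique(truth)) < 3) truth <- sample(c("V", "E", "NV"), n, replace = TRUE)
  sc <- matrix(runif(3 * n), n, 3)
  r3 <- classification_report(rep("V", n), truth, sc)
  for (k in 1:3) {
    cl <- c("V", "E", "NV")[k]
    pos <- which(truth == cl); neg <- which(truth != cl)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (sc[i, k] > sc[j, k]) + 0.5 * (sc[i, k] == sc[j, k])
    expect_equal(unname(r3$per_class_auc[k]), tot / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_equal(r3$auc, mean(r3$per_class_auc), tolerance = 1e-12)
})

test_that("paired Wilcoxon matches the exact sign-flip enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(paired_wilcoxon(x, x)$p_value, 1)
  expect_true("all_differences_zero" %in% paired_wilcoxon(x, x)$flags)
  set.seed(41)
  a <- rnorm(20); b <- a + 5 + rnorm(20, sd = 0.1)
  expect_lt(paired_wilcoxon(a, b)$p_value, 0.001)
  # exact-distribution oracle: enumerate all 2^n sign assignments (n = 10)
  set.seed(42)
  d <- round(rnorm(10, 0.4, 1), 3)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  Wall <- grid %*% r
  p_exact <- mean(abs(Wall - n * (n + 1) / 4) >= abs(W - n * (n + 1) / 4) - 1e-9)
  res <- paired_wilcoxon(d, rep(0, n))
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)
})

test_that("metrics are invariant to case-order permutation", {
  set.seed(8)
  lab <- sample(c("V", "E", "NV"), 12, replace = TRUE)
  pred <- sample(c("V", "E", "NV"), 12, replace = TRUE)
  sc <- matrix(runif(36), 12, 3)
  perm <- sample(12)
  r1 <- classification_report(pred, lab, sc)
  r2 <- classification_report(pred[perm], lab[perm], sc[perm, ])
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$confusion, r2$confusion)
})
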