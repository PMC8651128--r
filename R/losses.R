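# Training objectives: tumor cross-entropy, sliced-Wasserstein distance and
# the transport-weighted adversarial loss, graph-weight cosine divergence,
# batch-hard triplet losses and the overall combination
#   E_triplet_global = E_tumor + lambda_w * E_weight + lambda_a * E_adv
#   E_overall        = E_triplet_global + E_triplet_t + E_triplet_s + E_softmax

EPS_LOG <- 1e-12

#' Tumor overlap / class cross-entropy loss
#'
#' Weighted multi-class cross-entropy of predictions against targets, summed
#' over samples. Two target forms are supported: class labels against an
#' `n x 3` probability matrix (classes V, E, NV), or voxel tumor masks
#' against per-voxel foreground probabilities (mean voxel binary
#' cross-entropy per sample). `weights` plays the role of the per-sample
#' baseline weighting.
#'
#' @param pred `n x 3` class probability matrix, or a list of per-voxel
#'   foreground-probability vectors.
#' @param target integer/character class labels, or a list of binary masks.
#' @param weights per-sample nonnegative weights (default 1).
#' @return scalar loss (sum over samples).
#' @export
tumor_loss <- function(pred, target, weights = NULL) {
  if (is.list(pred)) {
    n <- length(pred)
    if (is.null(weights)) weights <- rep(1, n)
    tot <- 0
    for (i in seq_len(n)) {
      p <- pmin(pmax(as.numeric(pred[[i]]), EPS_LOG), 1 - EPS_LOG)
      m <- as.numeric(target[[i]]) != 0
      tot <- tot + weights[i] * -mean(ifelse(m, log(p), log(1 - p)))
    }
    tot
  } else {
    pred <- as.matrix(pred)
    n <- nrow(pred)
    if (is.null(weights)) weights <- rep(1, n)
    li <- if (is.character(target) || is.factor(target))
      match(as.character(target), CLASS_LEVELS) else as.integer(target)
    p <- pmax(pred[cbind(seq_len(n), li)], EPS_LOG)
    sum(weights * -log(p))
  }
}

#' Sliced 2-Wasserstein distance between point sets
#'
#' Mean over random unit projections of the exact 1-D 2-Wasserstein distance
#' between the projected, sorted samples. Symmetric; zero for identical
#' sets. For unequal sample sizes the empirical quantile functions are
#' compared on a midpoint grid of size `max(n_a, n_b)`.
#'
#' @param a,b numeric matrices (rows = points) or vectors (1-D point sets).
#' @param n_projections number of random projection directions.
#' @param seed seed for the projection draw (deterministic given seed).
#' @return nonnegative scalar distance.
#' @export
sliced_wasserstein <- function(a, b, n_projections = 64L, seed = 1L) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty point set")
  d <- ncol(a)
  if (ncol(b) != d) stop("dimension mismatch")
  if (d == 1L) {
    proj <- matrix(1, 1, 1)
    n_projections <- 1L
  } else {
    set.seed(derive_seed(seed, "swd_projections"))
    proj <- matrix(stats::rnorm(d * n_projections), d, n_projections)
    proj <- sweep(proj, 2, sqrt(colSums(proj^2)), `/`)
  }
  pa <- a %*% proj
  pb <- b %*% proj
  na <- nrow(a); nb <- nrow(b)
  w <- numeric(n_projections)
  for (j in seq_len(n_projections)) {
    sa <- sort(pa[, j]); sb <- sort(pb[, j])
    if (na == nb) {
      w[j] <- sqrt(mean((sa - sb)^2))
    } else {
      m <- max(na, nb)
      q <- (seq_len(m) - 0.5) / m
      qa <- stats::quantile(sa, q, type = 1, names = FALSE)
      qb <- stats::quantile(sb, q, type = 1, names = FALSE)
      w[j] <- sqrt(mean((qa - qb)^2))
    }
  }
  mean(w)
}

#' Class-transport cost: mean pairwise sliced-Wasserstein distance
#'
#' The optimal-transport weight `c` of the adversarial loss: the mean
#' pairwise sliced-Wasserstein distance among the class-conditional feature
#' distributions present in a batch. Rows of `features` are L2-normalized
#' first so `c` is scale-free. With a single class present, 0 (warning).
#'
#' @param features `n x d` feature matrix.
#' @param labels per-row class labels.
#' @param n_projections,seed passed to [sliced_wasserstein()].
#' @param quiet suppress the single-class warning.
#' @return nonnegative scalar.
#' @export
class_transport_cost <- function(features, labels, n_projections = 64L,
                                 seed = 1L, quiet = FALSE) {
  labels <- as.character(labels)
  present <- unique(labels)
  if (length(present) < 2L) {
    if (!quiet) warning("single class in batch; transport cost c = 0")
    return(0)
  }
  nf <- sqrt(rowSums(features^2))
  X <- features / pmax(nf, 1e-12)
  pairs <- utils::combn(present, 2)
  d <- apply(pairs, 2, function(pr)
    sliced_wasserstein(X[labels == pr[1], , drop = FALSE],
                       X[labels == pr[2], , drop = FALSE],
                       n_projections = n_projections, seed = seed))
  mean(d)
}

#' Transport-weighted adversarial loss
#'
#' `E_adv = -mean(log real) - mean((phi*c + xi) * log(1 - fake))` with `c`
#' the class-transport cost of the batch features. With `phi = 0, xi = 1`
#' this reduces to the standard adversarial loss.
#'
#' @param real_scores,fake_scores discriminator outputs in (0,1).
#' @param features,labels batch features and labels defining `c`, or pass a
#'   precomputed `c`.
#' @param phi,xi transport weighting and self-stabilizing terms.
#' @param c optional precomputed transport cost.
#' @param n_projections,seed for the sliced-Wasserstein estimate.
#' @return list with `E_adv`, `c`, `fake_weight` (= phi*c + xi).
#' @export
adversarial_loss <- function(real_scores, fake_scores, features = NULL,
                             labels = NULL, phi = 30, xi = 0.35, c = NULL,
                             n_projections = 64L, seed = 1L) {
  if (any(real_scores <= 0 | real_scores >= 1) ||
      any(fake_scores <= 0 | fake_scores >= 1))
    stop("scores must lie strictly in (0,1)")
  if (is.null(c))
    c <- class_transport_cost(features, labels, n_projections = n_projections,
                              seed = seed, quiet = TRUE)
  wfake <- phi * c + xi
  E <- -mean(log(pmax(real_scores, EPS_LOG))) -
    mean(wfake * log(pmax(1 - fake_scores, EPS_LOG)))
  list(E_adv = E, c = c, fake_weight = wfake)
}

#' Graph-weight cosine divergence
#'
#' Cosine similarity of the flattened between- and within-class adjacencies,
#' `(Wb . Ww) / (||Wb|| ||Ww||)`; in `[0, 1]` for nonnegative matrices and
#' identically 0 for binary graphs with disjoint edge sets (the within/
#' between partition guarantees disjointness, so this term only acts on
#' soft-weighted graph variants). A zero matrix yields 0 with a flag.
#'
#' @param W_b,W_w adjacency matrices of one shape.
#' @return scalar with attribute `flag` when degenerate.
#' @export
weight_divergence <- function(W_b, W_w) {
  if (!all(dim(W_b) == dim(W_w))) stop("shape mismatch")
  nb <- sqrt(sum(W_b^2)); nw <- sqrt(sum(W_w^2))
  if (nb == 0 || nw == 0) {
    out <- 0
    attr(out, "flag") <- "zero_matrix"
    return(out)
  }
  sum(W_b * W_w) / (nb * nw)
}

#' Batch-hard triplet loss
#'
#' Per anchor, the hardest positive (maximal same-class squared Euclidean
#' distance) and hardest negative (minimal other-class squared distance);
#' the loss is the mean over mineable anchors of
#' `max(0, d_pos - d_neg + margin)`. Anchors without a positive or negative
#' are skipped; an unmineable batch returns 0 with a warning.
#'
#' @param features `n x d` matrix.
#' @param labels per-row labels.
#' @param margin triplet margin (squared-distance scale).
#' @param grad if `TRUE` also return the gradient wrt `features`.
#' @param quiet suppress the unmineable warning.
#' @return scalar loss, or list(`loss`, `grad`) when `grad = TRUE`.
#' @export
triplet_loss <- function(features, labels, margin = 0.3, grad = FALSE,
                         quiet = FALSE) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(X)
  sq <- rowSums(X^2)
  D <- outer(sq, sq, `+`) - 2 * (X %*% t(X))
  D[D < 0] <- 0
  same <- outer(labels, labels, `==`)
  diag(same) <- NA
  loss_i <- numeric(0)
  G <- if (grad) matrix(0, n, ncol(X)) else NULL
  active <- 0L
  terms <- list()
  for (i in seq_len(n)) {
    pos <- which(same[i, ] %in% TRUE)
    neg <- which(same[i, ] %in% FALSE)
    if (length(pos) == 0 || length(neg) == 0) next
    jp <- pos[which.max(D[i, pos])]
    jn <- neg[which.min(D[i, neg])]
    l <- D[i, jp] - D[i, jn] + margin
    active <- active + 1L
    if (l > 0) terms[[length(terms) + 1L]] <- c(i, jp, jn)
    loss_i <- c(loss_i, max(l, 0))
  }
  if (active == 0L) {
    if (!quiet) warning("unmineable batch; triplet loss = 0")
    loss <- 0
  } else loss <- mean(loss_i)
  if (!grad) return(loss)
  if (active > 0L) for (tr in terms) {
    i <- tr[1]; jp <- tr[2]; jn <- tr[3]
    # d/dx_i (|x_i-x_p|^2 - |x_i-x_n|^2) = 2 (x_n - x_p), etc.
    G[i, ]  <- G[i, ]  + 2 * (X[jn, ] - X[jp, ]) / active
    G[jp, ] <- G[jp, ] - 2 * (X[i, ] - X[jp, ]) / active
    G[jn, ] <- G[jn, ] + 2 * (X[i, ] - X[jn, ]) / active
  }
  list(loss = loss, grad = G)
}

#' Combine loss components into the overall objective
#'
#' `E_triplet_global = E_tumor + lambda_w * E_weight + lambda_a * E_adv`;
#' `E_overall = E_triplet_global + E_triplet_t + E_triplet_s + E_softmax`.
#'
#' @param E_tumor,E_weight,E_adv,E_triplet_t,E_triplet_s,E_softmax parts.
#' @param lambda_w,lambda_a loss weights.
#' @return named list of class `loss_report` with all parts plus
#'   `E_triplet_global` and `E_overall`.
#' @export
overall_loss <- function(E_tumor = 0, E_weight = 0, E_adv = 0,
                         E_triplet_t = 0, E_triplet_s = 0, E_softmax = 0,
                         lambda_w = 0.2, lambda_a = 0.5) {
  parts <- c(E_tumor = E_tumor, E_weight = as.numeric(E_weight), E_adv = E_adv,
             E_triplet_t = E_triplet_t, E_triplet_s = E_triplet_s,
             E_softmax = E_softmax)
  if (any(!is.finite(parts))) stop("non-finite loss component")
  etg <- E_tumor + lambda_w * as.numeric(E_weight) + lambda_a * E_adv
  structure(as.list(c(parts, E_triplet_global = etg,
                      E_overall = etg + E_triplet_t + E_triplet_s + E_softmax)),
            class = "loss_report")
}
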