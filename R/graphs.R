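# Discriminant graph construction: pooled patch features, within-class and
# between-class k-NN adjacencies, their symmetric normalizations and the
# graph Laplacian.

#' Average-pool a feature map into a grid of patch feature vectors
#'
#' Partitions an `h x w x n x c` feature map into `prod(P_grid)` 3D blocks
#' and averages each block channelwise, yielding one pooled feature vector
#' per patch. When the grid does not divide an axis evenly, block boundaries
#' follow `floor(i * dim / grid)` (remainder spread over the blocks).
#'
#' @param feature_map 4D array (`h x w x n x c`) or 3D array (treated as c=1).
#' @param P_grid integer length-3 per-axis partition counts.
#' @return `prod(P_grid) x c` matrix; patch order is column-major over the
#'   grid (first axis fastest), matching `patch_index` elsewhere.
#' @export
extract_patch_features <- function(feature_map, P_grid) {
  if (length(dim(feature_map)) == 3L)
    dim(feature_map) <- c(dim(feature_map), 1L)
  d <- dim(feature_map)
  P_grid <- as.integer(P_grid)
  if (any(P_grid > d[1:3])) stop("patch grid larger than feature map")
  bounds <- lapply(1:3, function(ax) floor(seq(0, d[ax], length.out = P_grid[ax] + 1)))
  P <- prod(P_grid)
  out <- matrix(0, P, d[4])
  p <- 1L
  for (k in seq_len(P_grid[3])) for (j in seq_len(P_grid[2])) for (i in seq_len(P_grid[1])) {
    xs <- (bounds[[1]][i] + 1):bounds[[1]][i + 1]
    ys <- (bounds[[2]][j] + 1):bounds[[2]][j + 1]
    zs <- (bounds[[3]][k] + 1):bounds[[3]][k + 1]
    blk <- feature_map[xs, ys, zs, , drop = FALSE]
    out[p, ] <- colMeans(matrix(blk, ncol = d[4]))
    # patch index p runs i fastest, then j, then k
    p <- p + 1L
  }
  out
}

#' Assemble a patch feature set from per-volume feature matrices
#'
#' @param per_volume_feats list of T `P x d` matrices (one per phase).
#' @param class_label single viability label replicated to all patches, or NA.
#' @param source_id sequence identifier.
#' @return list of class `patch_feature_set` with `features` (N x d,
#'   N = T*P), `time_index`, `patch_index`, `class_label`, `source_id`.
#' @export
patch_feature_set <- function(per_volume_feats, class_label = NA_character_,
                              source_id = "seq") {
  T <- length(per_volume_feats)
  P <- nrow(per_volume_feats[[1]])
  feats <- do.call(rbind, per_volume_feats)
  if (!all(is.finite(feats))) stop("non-finite patch features")
  structure(list(features = feats,
                 time_index = rep(seq_len(T) - 1L, each = P),
                 patch_index = rep(seq_len(P) - 1L, times = T),
                 class_label = rep(as.character(class_label), T * P),
                 source_id = source_id, T = T, P = P),
            class = "patch_feature_set")
}

# full squared-distance matrix (Euclidean in feature space)
pairwise_sqdist <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D2
}

# deterministic k-NN from a precomputed distance row; ties broken by lower index
knn_from_row <- function(d2row, candidates, k) {
  if (length(candidates) == 0) return(integer(0))
  ord <- order(d2row[candidates], candidates)
  candidates[ord][seq_len(min(k, length(candidates)))]
}

#' Within-class k-nearest-neighbor adjacency
#'
#' `W_w[i,j] = 1` iff i and j share a class and j is among i's `k_w` nearest
#' same-class neighbors or vice versa (symmetric OR). Distances are Euclidean
#' in feature space; neighbor ties are broken by lower node index. Classes
#' with fewer than 2 members yield isolated nodes (with a warning).
#'
#' @param feats `patch_feature_set`, or a plain feature matrix (then supply
#'   `labels`).
#' @param k_w neighbors per node.
#' @param labels optional label vector overriding `feats$class_label`.
#' @param quiet suppress the small-class warning.
#' @return N x N binary symmetric adjacency with zero diagonal.
#' @export
build_within_graph <- function(feats, k_w = 5L, labels = NULL, quiet = FALSE) {
  X <- if (inherits(feats, "patch_feature_set")) feats$features else as.matrix(feats)
  if (is.null(labels))
    labels <- if (inherits(feats, "patch_feature_set")) feats$class_label
              else stop("labels required")
  stopifnot(k_w >= 1)
  n <- nrow(X)
  W <- matrix(0, n, n)
  D2 <- pairwise_sqdist(X)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < 2L) {
      if (!quiet) warning(sprintf("class '%s' has < 2 samples; nodes isolated", cl))
      next
    }
    for (i in members) {
      nb <- knn_from_row(D2[i, ], setdiff(members, i), k_w)
      W[i, nb] <- 1; W[nb, i] <- 1
    }
  }
  diag(W) <- 0
  W
}

#' Between-class k-nearest-neighbor adjacency
#'
#' `W_b[i,j] = 1` iff i and j have different classes and j is among i's
#' `k_b` nearest other-class neighbors or vice versa (symmetric OR). With a
#' single class present the zero matrix is returned with a warning. By
#' construction `W_w * W_b = 0` elementwise.
#'
#' @inheritParams build_within_graph
#' @param k_b cross-class neighbors per node.
#' @return N x N binary symmetric adjacency with zero diagonal.
#' @export
build_between_graph <- function(feats, k_b = 3L, labels = NULL, quiet = FALSE) {
  X <- if (inherits(feats, "patch_feature_set")) feats$features else as.matrix(feats)
  if (is.null(labels))
    labels <- if (inherits(feats, "patch_feature_set")) feats$class_label
              else stop("labels required")
  stopifnot(k_b >= 1)
  n <- nrow(X)
  W <- matrix(0, n, n)
  if (length(unique(labels)) < 2L) {
    if (!quiet) warning("single class present; between-class graph is empty")
    return(W)
  }
  D2 <- pairwise_sqdist(X)
  for (i in seq_len(n)) {
    others <- which(labels != labels[i])
    nb <- knn_from_row(D2[i, ], others, k_b)
    W[i, nb] <- 1; W[nb, i] <- 1
  }
  diag(W) <- 0
  W
}

#' Soft-weighted variant of a binary adjacency
#'
#' Replaces unit edge weights by a Gaussian kernel of the feature distance,
#' `exp(-d_ij^2 / sigma^2)` with `sigma` the median edge distance. Used by
#' the graph-weight cosine divergence, which is identically zero on strictly
#' binary disjoint within/between graphs.
#'
#' @param W binary adjacency.
#' @param X feature matrix the graph was built on.
#' @return real-valued symmetric adjacency with the same sparsity pattern.
#' @export
soften_adjacency <- function(W, X) {
  idx <- which(W != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(W)
  d2 <- rowSums((X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE])^2)
  sig2 <- max(stats::median(d2), 1e-12)
  Ws <- W
  Ws[idx] <- exp(-d2 / sig2)
  Ws
}

#' Symmetric degree normalization with self-loops
#'
#' `W_hat = D^(-1/2) (W + I) D^(-1/2)` with `D` the degree matrix of
#' `W + I`. Symmetric, spectral radius <= 1; isolated nodes are handled by
#' the self-loop.
#'
#' @param W symmetric nonnegative adjacency.
#' @return normalized adjacency of the same dimension.
#' @export
normalize_adjacency <- function(W) {
  if (any(W < 0)) stop("W must be nonnegative")
  n <- nrow(W)
  Wi <- W + diag(n)
  dinv <- 1 / sqrt(rowSums(Wi))
  Wi * outer(dinv, dinv)
}

#' Graph Laplacian L = Diag - W
#'
#' @param W symmetric adjacency; `Diag(i,i) = sum_j W[i,j]`.
#' @return Laplacian matrix (rows sum to 0, positive semidefinite).
#' @export
laplacian_matrix <- function(W) {
  diag(rowSums(W)) - W
}

#' Build the full discriminant graph bundle for a feature set
#'
#' @param feats a `patch_feature_set` (or matrix with `labels`).
#' @param k_w,k_b neighbor counts.
#' @param labels optional labels.
#' @param quiet passed through to the builders.
#' @return list of class `discriminant_graph`: `W_w`, `W_b`, `W_w_hat`,
#'   `W_b_hat`, `L` (Laplacian of `W_w`).
#' @export
discriminant_graph <- function(feats, k_w = 5L, k_b = 3L, labels = NULL,
                               quiet = FALSE) {
  W_w <- build_within_graph(feats, k_w, labels = labels, quiet = quiet)
  W_b <- build_between_graph(feats, k_b, labels = labels, quiet = quiet)
  structure(list(W_w = W_w, W_b = W_b,
                 W_w_hat = normalize_adjacency(W_w),
                 W_b_hat = normalize_adjacency(W_b),
                 L = laplacian_matrix(W_w)),
            class = "discriminant_graph")
}

#' Serialize a (sparse) adjacency as an i,j,w triplet table
#' @param W adjacency matrix.
#' @param path optional CSV destination; when NULL the data.frame is returned.
#' @return data.frame with columns `i`, `j`, `w` (upper triangle only).
#' @export
graph_triplets <- function(W, path = NULL) {
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
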