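# shared fixtures: tiny sequences, labeled point sets and a small model

tiny_volume <- function(shape = c(8, 8, 4), value = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(value)) array(rnorm(prod(shape), 100, 5), dim = shape)
  else array(value, dim = shape)
}

tiny_sequence <- function(T = 3, shape = c(8, 8, 4), seed = 1, label = "V") {
  set.seed(seed)
  vols <- lapply(seq_len(T), function(i) array(rnorm(prod(shape), 100, 5), dim = shape))
  mask <- array(0, shape); mask[3:5, 3:5, 2:3] <- 1
  dce_sequence(vols, times = seq(10, by = 50, length.out = T), mask = mask,
               label = label, spacing = c(1.9, 1.9, 2.5))
}

# random labeled feature set for graph tests
random_labeled_points <- function(n, d = 2, n_classes = 3, seed = 1) {
  set.seed(seed)
  list(X = matrix(rnorm(n * d), n, d),
       labels = sample(c("V", "E", "NV")[seq_len(n_classes)], n, replace = TRUE))
}

# brute-force within/between adjacency (independent oracle):
# symmetric OR of k-nearest neighbours by sorted pairwise distance,
# ties broken by lower index
brute_knn_graph <- function(X, labels, k, within = TRUE) {
  n <- nrow(X)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      ok <- if (within) labels[j] == labels[i] else labels[j] != labels[i]
      if (ok) cand <- c(cand, j)
    }
    if (length(cand) == 0) next
    d <- sapply(cand, function(j) sqrt(sum((X[i, ] - X[j, ])^2)))
    ord <- order(d, cand)
    nb <- cand[ord][seq_len(min(k, length(cand)))]
    W[i, nb] <- 1
    W[nb, i] <- 1
  }
  diag(W) <- 0
  W
}

# tiny trainable model geometry (volume = 8 x patch grid)
tiny_model <- function(seed = 5) {
  cfg <- desk_config(seed)
  cfg$patch_grid <- c(2L, 2L, 1L); cfg$T_sample <- 2L
  cfg$d_k <- 8L; cfg$d_m <- 8L; cfg$backbone_channels <- 4L
  cfg$decoder_channels <- 4L; cfg$disc_channels <- c(4L, 4L, 8L, 8L, 8L)
  stdgnn_model(cfg, volume_shape = c(16L, 16L, 8L), n_phases = 3L,
               times = c(10, 60, 100), seed = seed)
}

tiny_cohort <- function(n_per_class = 2, seed = 21) {
  base <- phantom_spec(volume_shape = c(16L, 16L, 8L), n_timepoints = 3L,
                       times = c(10, 60, 100), radius = 3, noise_sigma = 1)
  generate_cohort(n_per_class, base, seed = seed,
                  center_jitter = c(1, 1, 0.5), radius_range = c(2.5, 3.5))
}

tiny_train_config <- function(seed = 5) {
  cfg <- desk_config(seed)
  cfg$patch_grid <- c(2L, 2L, 1L); cfg$T_sample <- 2L
  cfg$d_k <- 8L; cfg$d_m <- 8L; cfg$backbone_channels <- 4L
  cfg$decoder_channels <- 4L; cfg$disc_channels <- c(4L, 4L, 8L, 8L, 8L)
  cfg$batch_size <- 4L
  cfg
}
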