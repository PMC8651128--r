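# The STDGNN forward model: a small convolutional backbone feature
# extractor, discriminant-graph temporal and structural GCN branches, a
# global generator projection, a convolutional discriminator and a decoder
# producing the follow-up sequence + tumor mask + viability class.
#
# Layer algebra of the GCN branches (between-minus-within propagation):
#   X^(k) = W_b_hat X^(k-1) B_k - W_w_hat X^(k-1) B_k
#         = (W_b_hat - W_w_hat) X^(k-1) B_k
# followed by (non-affine) BatchNorm and LeakyReLU, with residual shortcuts
# X^(k) <- X^(k) + X^(k-1) for 2 <= k <= K in the temporal branch.

CLASS_LEVELS <- c("V", "E", "NV")

# ---- model construction -----------------------------------------------------

#' Initialize an STDGNN model
#'
#' Builds all weight tensors and geometry caches for a given input geometry.
#' The backbone is a fixed (seeded, untrained) 3-layer convolutional encoder
#' playing the role of a frozen pretrained feature extractor; the trainable
#' parts are the branch projections, the graph-convolution weights, the
#' classifier head, the generator projection, the decoder and the
#' discriminator.
#'
#' @param config an `stdgnn_config` (see [desk_config()]).
#' @param volume_shape input volume shape in voxels.
#' @param n_phases number of phases T of the fixed acquisition grid.
#' @param times acquisition times of the phase grid (s).
#' @param seed integer; fans out to init seeds via [derive_seed()].
#' @return list of class `stdgnn_model`.
#' @export
stdgnn_model <- function(config = desk_config(), volume_shape = c(48L, 48L, 16L),
                         n_phases = 5L, times = c(10, 60, 100, 145, 320),
                         seed = config$seed) {
  cfg <- config
  vs <- as.integer(volume_shape)
  cb <- cfg$backbone_channels
  kb <- cfg$backbone_kernel

  set.seed(derive_seed(seed, "init", "backbone"))
  backbone <- list(conv = list(), idx = list(), dims = list())
  dims <- vs
  cin <- 1L
  for (l in seq_len(cfg$backbone_layers)) {
    idx <- make_conv_index(dims, kb, stride = 1L)
    W <- he_init(prod(kb) * cin, cb, fan_in = prod(kb) * cin)
    backbone$conv[[l]] <- list(W = W, b = numeric(cb))
    backbone$idx[[l]] <- idx
    backbone$dims[[l]] <- dims
    if (l <= 2L) dims <- dims %/% 2L   # two max-pool stages
    cin <- cb
  }
  backbone$out_dims <- dims            # feature-map grid after pools
  backbone$channels <- cb

  P_grid <- cfg$patch_grid
  if (any(P_grid > dims)) stop("patch grid larger than backbone feature map")
  P <- prod(P_grid)
  d0 <- cb + 1L   # conv channels + pooled raw-intensity skip channel
  dk <- cfg$d_k
  # structural widths: d_m halved per layer, floored at d_m / 2^M
  s_dims <- c(cfg$d_m, pmax(cfg$d_m %/% (2^(seq_len(cfg$M))), cfg$d_m %/% (2^cfg$M)))
  cg <- cfg$global_channels
  # fused vector = [f_global, f_t, f_s, f_roi]: position-invariant pooled
  # generator summaries (global mean + ROI-weighted mean of the per-phase
  # patch projections), the two branch vectors, and the ROI-weighted
  # per-phase feature summary of the annotated baseline tumor.  The decoder
  # additionally receives the spatially resolved map [per-phase patch
  # projections, patch tumor occupancy]; keeping that map out of the
  # classification path avoids handing the classifier a per-case
  # fingerprint it could memorize.
  f_global_len <- 2L * cg * cfg$T_sample
  # + d0*T ROI-weighted patch summary + T exact ROI enhancement samples
  # + 6 non-parametric enhancement descriptors of the input ROI curve
  # (T0, TTP, PER, nMITR, wash-in, wash-out)
  fused_dim <- f_global_len + dk + cfg$T_sample * s_dims[length(s_dims)] +
    d0 * cfg$T_sample + cfg$T_sample + 6L
  spatial_len <- P * cg * cfg$T_sample + P

  set.seed(derive_seed(seed, "init", "branches"))
  params <- list(t_proj = he_init(d0, dk))
  for (k in seq_len(cfg$K)) params[[paste0("t_B", k)]] <- he_init(dk, dk)
  params$s_proj <- he_init(d0, s_dims[1])
  for (m in seq_len(cfg$M))
    params[[paste0("s_B", m)]] <- he_init(s_dims[m], s_dims[m + 1])
  params$g_proj <- he_init(d0, cg)
  params$cls_W <- he_init(fused_dim, 3) * 0.1
  params$cls_b <- numeric(3)

  # decoder: fc -> grid, 2 upsampling convs, 1x1 head (4 conv layers total)
  set.seed(derive_seed(seed, "init", "decoder"))
  cd <- cfg$decoder_channels
  g1 <- P_grid                               # coarse grid = patch grid
  dec_geom <- list(g1 = g1, g2 = g1 * 2L, g3 = g1 * 4L, g4 = g1 * 8L)
  if (any(dec_geom$g4 != vs))
    stop("volume shape must equal 8x the patch grid (three x2 decoder upsamplings)")
  # grid channels: learned mixing of the fused vector + spatially aligned
  # conditioning channels (per-phase patch projections and tumor occupancy)
  cd_grid <- cd + cg * cfg$T_sample + 1L
  params$dec_fc_W <- he_init(fused_dim, prod(g1) * cd) * 0.5
  params$dec_fc_b <- numeric(prod(g1) * cd)
  cd2 <- max(cd %/% 2L, 2L)
  params$dec_c1_W <- he_init(27 * cd_grid, cd2)
  params$dec_c1_b <- numeric(cd2)
  params$dec_c2_W <- he_init(27 * cd2, cd2)
  params$dec_c2_b <- numeric(cd2)
  n_out <- n_phases + 2L                     # T intensity channels + 2 mask logits
  # head sees the conv features + the normalized internal distance map of
  # the baseline tumor annotation (full resolution conditioning channel);
  # the mask logits start from the "shrunken baseline tumor" prior
  # sigmoid(6*dist - 2.4), which the conv features then modulate per case
  params$dec_h_W <- he_init(cd2 + 1L, n_out) * 0.1
  params$dec_h_W[cd2 + 1L, n_phases + 1L] <- 3
  params$dec_h_W[cd2 + 1L, n_phases + 2L] <- -3
  params$dec_h_b <- numeric(n_out)
  params$dec_h_b[n_phases + 1L] <- -1.2
  params$dec_h_b[n_phases + 2L] <- 1.2

  dec_cache <- list(
    U1 = make_upsample2(dec_geom$g1),
    U2 = make_upsample2(dec_geom$g2),
    U3 = make_upsample2(dec_geom$g3),
    idx1 = make_conv_index(dec_geom$g2, c(3L, 3L, 3L)),
    idx2 = make_conv_index(dec_geom$g3, c(3L, 3L, 3L)))

  # discriminator: 5 conv layers, 4x4(x3) kernels, stride 2, on a centered crop
  set.seed(derive_seed(seed, "init", "disc"))
  crop <- pmin(c(32L, 32L, 8L), vs)
  dch <- cfg$disc_channels
  disc <- list(idx = list(), dims = list())
  ddims <- crop
  cin <- n_phases
  for (l in seq_len(5L)) {
    # 4x4 in-plane kernels while the plane allows, 3 once a dim collapses
    ks <- c(ifelse(ddims[1] >= 2L, 4L, 3L), ifelse(ddims[2] >= 2L, 4L, 3L), 3L)
    idx <- make_conv_index(ddims, ks, stride = 2L, pad = c(1L, 1L, 1L))
    params[[paste0("disc_W", l)]] <- he_init(prod(ks) * cin, dch[l])
    params[[paste0("disc_b", l)]] <- numeric(dch[l])
    disc$idx[[l]] <- idx
    disc$dims[[l]] <- ddims
    ddims <- attr(idx, "out_dims")
    cin <- dch[l]
  }
  params$disc_fc_W <- he_init(prod(ddims) * dch[5], 1) * 0.1
  params$disc_fc_b <- 0
  disc$out_dims <- ddims
  disc$crop <- crop

  bn <- list()
  for (k in seq_len(cfg$K)) bn[[paste0("t", k)]] <- bn_state(dk)
  for (m in seq_len(cfg$M)) bn[[paste0("s", m)]] <- bn_state(s_dims[m + 1])

  fused_center <- numeric(fused_dim)
  fused_scale <- rep(1, fused_dim)

  structure(list(config = cfg, volume_shape = vs, n_phases = as.integer(n_phases),
                 times = times, backbone = backbone, params = params, bn = bn,
                 P_grid = P_grid, P = P, d0 = d0, s_dims = s_dims,
                 fused_dim = fused_dim, f_global_len = f_global_len,
                 fused_center = fused_center, fused_scale = fused_scale,
                 spatial_len = spatial_len, cd_grid = cd_grid,
                 dec_geom = dec_geom, dec_cache = dec_cache,
                 disc_geom = disc, intensity_scale = 100, seed = seed),
            class = "stdgnn_model")
}

#' @export
print.stdgnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<stdgnn_model> volumes %s, T=%d, P=%d patches (%s grid), %d trainable parameters\n",
              paste(x$volume_shape, collapse = "x"), x$n_phases, x$P,
              paste(x$P_grid, collapse = "x"), np))
  invisible(x)
}

# normalized intensity: enhancement relative to the nominal baseline
normalize_volume <- function(v, scale) v / scale - 1
denormalize_volume <- function(v, scale) (v + 1) * scale

# ---- backbone ---------------------------------------------------------------

#' Backbone feature maps for each volume of a sequence
#'
#' Applies the fixed convolutional stack (3 conv layers with LeakyReLU, two
#' 2x2x2 max-pool stages) to each phase, returning one
#' `h' x w' x n' x c` feature map per volume. Deterministic given weights.
#'
#' @param seq a [dce_sequence()] or a single 3D array.
#' @param model an [stdgnn_model()].
#' @return list of 4D feature-map arrays (one per phase).
#' @export
backbone_features <- function(seq, model) {
  vols <- if (inherits(seq, "dce_sequence")) seq$volumes else list(seq)
  bb <- model$backbone
  lapply(vols, function(v) {
    if (any(dim(v) != model$volume_shape))
      stop("volume geometry does not match the model")
    x <- matrix(normalize_volume(as.numeric(v), model$intensity_scale), ncol = 1)
    dims <- model$volume_shape
    for (l in seq_along(bb$conv)) {
      cv <- conv3d_forward(x, bb$idx[[l]], bb$conv[[l]]$W, bb$conv[[l]]$b)
      x <- lrelu_forward(cv$y)$y
      if (l <= 2L) {
        mp <- maxpool2(x, dims)
        x <- mp$y; dims <- mp$out_dims
      }
    }
    array(x, dim = c(dims, bb$channels))
  })
}

#' Per-volume pooled patch features of a sequence
#'
#' Backbone features followed by [extract_patch_features()] on the patch
#' grid, plus a raw-intensity skip channel (the patchwise mean of the
#' normalized input volume); this is the node-feature front end of both
#' GCN branches.
#'
#' @param seq a [dce_sequence()].
#' @param model an [stdgnn_model()].
#' @return list of T `P x d0` matrices (d0 = conv channels + 1).
#' @export
sequence_patch_features <- function(seq, model) {
  vols <- if (inherits(seq, "dce_sequence")) seq$volumes else list(seq)
  fmaps <- backbone_features(seq, model)
  lapply(seq_along(fmaps), function(i) {
    conv_p <- extract_patch_features(fmaps[[i]], P_grid = model$P_grid)
    raw <- normalize_volume(vols[[i]], model$intensity_scale)
    raw_p <- extract_patch_features(array(raw, c(dim(vols[[i]]), 1L)),
                                    P_grid = model$P_grid)
    cbind(conv_p, raw_p)
  })
}

# ---- branches ---------------------------------------------------------------

#' Temporal branch forward pass
#'
#' K graph-convolution layers with between-minus-within propagation over the
#' temporal discriminant graph spanning all N = T*P patch nodes, BatchNorm +
#' LeakyReLU after each layer, residual shortcuts from layer 2 on, and a
#' final max-pool over nodes giving `f_t` of width `d_k`.
#'
#' @param X0 `N x d0` node feature matrix.
#' @param Wb_hat,Ww_hat normalized between/within adjacencies (N x N).
#' @param model an [stdgnn_model()] (weights `t_proj`, `t_B1..t_BK`).
#' @param training logical; batch-norm mode.
#' @return list with `f_t`, `cache` (for backward), `bn` (updated states).
#' @export
temporal_branch <- function(X0, Wb_hat, Ww_hat, model, training = FALSE) {
  p <- model$params; cfg <- model$config
  A <- Wb_hat - Ww_hat
  H <- X0 %*% p$t_proj
  cache <- list(X0 = X0, A = A, layers = list(), H0 = H)
  bn <- model$bn
  for (k in seq_len(cfg$K)) {
    AH <- A %*% H
    Z <- AH %*% p[[paste0("t_B", k)]]
    bf <- bn_forward(Z, bn[[paste0("t", k)]], training)
    bn[[paste0("t", k)]] <- bf$state
    lr <- lrelu_forward(bf$y)
    Hnew <- if (k >= 2L) lr$y + H else lr$y
    cache$layers[[k]] <- list(AH = AH, bn = bf$cache, lr = lr, H_in = H)
    H <- Hnew
  }
  amax <- apply(H, 2, which.max)
  f_t <- H[cbind(amax, seq_len(ncol(H)))]
  cache$H_out <- H; cache$amax <- amax
  list(f_t = f_t, cache = cache, bn = bn)
}

temporal_branch_backward <- function(df_t, cache, model) {
  p <- model$params; cfg <- model$config
  H <- cache$H_out
  dH <- matrix(0, nrow(H), ncol(H))
  dH[cbind(cache$amax, seq_len(ncol(H)))] <- df_t
  grads <- list()
  A <- cache$A
  for (k in rev(seq_len(cfg$K))) {
    ly <- cache$layers[[k]]
    dpost <- dH
    dres <- if (k >= 2L) dH else 0
    dz <- lrelu_backward(dpost, ly$lr)
    dz <- bn_backward(dz, ly$bn)
    grads[[paste0("t_B", k)]] <- crossprod(ly$AH, dz)
    dH <- A %*% (dz %*% t(p[[paste0("t_B", k)]]))
    if (k >= 2L) dH <- dH + dres
  }
  grads$t_proj <- crossprod(cache$X0, dH)
  grads
}

#' Structural branch forward pass
#'
#' One M-layer graph convolution per volume over the per-volume structural
#' discriminant graph (P patch nodes), widths halved per layer, max-pool to
#' the structural width, concatenated across volumes into `f_s`. Weights are
#' shared across volumes.
#'
#' @param pv_feats list of `P x d0` per-volume feature matrices.
#' @param graphs list of per-volume lists with `Wb_hat`, `Ww_hat`.
#' @param model an [stdgnn_model()].
#' @param training batch-norm mode.
#' @return list with `f_s`, `cache`, `bn`.
#' @export
structural_branch <- function(pv_feats, graphs, model, training = FALSE) {
  p <- model$params; cfg <- model$config
  bn <- model$bn
  caches <- vector("list", length(pv_feats))
  fs <- vector("list", length(pv_feats))
  for (v in seq_along(pv_feats)) {
    A <- graphs[[v]]$Wb_hat - graphs[[v]]$Ww_hat
    G <- pv_feats[[v]] %*% p$s_proj
    cache <- list(X0 = pv_feats[[v]], A = A, layers = list())
    for (m in seq_len(cfg$M)) {
      AG <- A %*% G
      Z <- AG %*% p[[paste0("s_B", m)]]
      bf <- bn_forward(Z, bn[[paste0("s", m)]], training)
      bn[[paste0("s", m)]] <- bf$state
      lr <- lrelu_forward(bf$y)
      cache$layers[[m]] <- list(AG = AG, bn = bf$cache, lr = lr)
      G <- lr$y
    }
    amax <- apply(G, 2, which.max)
    fs[[v]] <- G[cbind(amax, seq_len(ncol(G)))]
    cache$amax <- amax; cache$G_out <- G
    caches[[v]] <- cache
  }
  list(f_s = unlist(fs), cache = caches, bn = bn)
}

structural_branch_backward <- function(df_s, caches, model) {
  p <- model$params; cfg <- model$config
  nw <- length(caches)
  dper <- split(df_s, rep(seq_len(nw), each = length(df_s) / nw))
  grads <- NULL
  for (v in seq_len(nw)) {
    cache <- caches[[v]]
    G <- cache$G_out
    dG <- matrix(0, nrow(G), ncol(G))
    dG[cbind(cache$amax, seq_len(ncol(G)))] <- dper[[v]]
    g <- list()
    for (m in rev(seq_len(cfg$M))) {
      ly <- cache$layers[[m]]
      dz <- lrelu_backward(dG, ly$lr)
      dz <- bn_backward(dz, ly$bn)
      g[[paste0("s_B", m)]] <- crossprod(ly$AG, dz)
      dG <- cache$A %*% (dz %*% t(p[[paste0("s_B", m)]]))
    }
    g$s_proj <- crossprod(cache$X0, dG)
    grads <- if (is.null(grads)) g else acc_grads(grads, g)
  }
  grads
}

# ---- discriminator ----------------------------------------------------------

crop_volume_stack <- function(vol_mat, model) {
  vs <- model$volume_shape; crop <- model$disc_geom$crop
  lo <- pmax((vs - crop) %/% 2L, 0L)
  a <- array(vol_mat, dim = c(vs, ncol(vol_mat)))
  a <- a[lo[1] + seq_len(crop[1]), lo[2] + seq_len(crop[2]),
         lo[3] + seq_len(crop[3]), , drop = FALSE]
  matrix(a, prod(crop), ncol(vol_mat))
}

uncrop_gradient <- function(dcrop, model) {
  vs <- model$volume_shape; crop <- model$disc_geom$crop
  lo <- pmax((vs - crop) %/% 2L, 0L)
  a <- array(0, dim = c(vs, ncol(dcrop)))
  a[lo[1] + seq_len(crop[1]), lo[2] + seq_len(crop[2]),
    lo[3] + seq_len(crop[3]), ] <- array(dcrop, dim = c(crop, ncol(dcrop)))
  matrix(a, prod(vs), ncol(dcrop))
}

#' Discriminator score for a (real or generated) phase stack
#'
#' 5 convolutional layers with 4x4(x3) kernels, stride 2, ReLU, channel
#' widths from `config$disc_channels`, followed by a linear unit and a
#' sigmoid, applied to the centered tumor-region crop of the normalized
#' T-phase volume stack.
#'
#' @param vol_mat `V x T` matrix of normalized phase volumes (or a
#'   [dce_sequence()], normalized internally).
#' @param model an [stdgnn_model()].
#' @return list with `score` in (0,1) and `cache`.
#' @export
discriminator <- function(vol_mat, model, cropped = FALSE) {
  if (inherits(vol_mat, "dce_sequence"))
    vol_mat <- vapply(vol_mat$volumes,
                      function(v) normalize_volume(as.numeric(v), model$intensity_scale),
                      numeric(prod(model$volume_shape)))
  p <- model$params; dg <- model$disc_geom
  if (cropped) {
    x <- vol_mat
  } else {
    if (nrow(vol_mat) != prod(model$volume_shape) ||
        ncol(vol_mat) != model$n_phases)
      stop("discriminator input geometry mismatch")
    x <- crop_volume_stack(vol_mat, model)
  }
  cache <- list(layers = list(), x_in = x)
  for (l in seq_len(5L)) {
    cv <- conv3d_forward(x, dg$idx[[l]], p[[paste0("disc_W", l)]],
                         p[[paste0("disc_b", l)]])
    rl <- relu_forward(cv$y)
    cache$layers[[l]] <- list(cols = cv$cols, rl = rl, Vin = nrow(x))
    x <- rl$y
  }
  feat <- as.numeric(x)
  z <- sum(feat * p$disc_fc_W) + p$disc_fc_b
  s <- sigmoid(z)
  cache$feat <- feat; cache$z <- z
  list(score = s, cache = cache)
}

# dz: gradient wrt the pre-sigmoid logit. Returns weight grads and (optionally)
# gradient wrt the full-volume input stack.
discriminator_backward <- function(dz, cache, model, need_dx = FALSE) {
  p <- model$params; dg <- model$disc_geom
  grads <- list(disc_fc_W = matrix(cache$feat * dz, ncol = 1), disc_fc_b = dz)
  dx <- matrix(p$disc_fc_W * dz, ncol = model$config$disc_channels[5])
  for (l in rev(seq_len(5L))) {
    ly <- cache$layers[[l]]
    dx <- relu_backward(dx, ly$rl)
    cin <- if (l == 1L) model$n_phases else model$config$disc_channels[l - 1]
    need <- l > 1L || need_dx
    cb <- conv3d_backward(dx, ly$cols, dg$idx[[l]], p[[paste0("disc_W", l)]],
                          Cin = cin, need_dx = need, Vin = ly$Vin)
    grads[[paste0("disc_W", l)]] <- cb$dW
    grads[[paste0("disc_b", l)]] <- cb$db
    dx <- cb$dx
  }
  dx_full <- if (need_dx) uncrop_gradient(dx, model) else NULL
  list(grads = grads, dx = dx_full)
}

# ---- decoder ----------------------------------------------------------------

#' Decoder: fused features to follow-up sequence, mask and class
#'
#' Four convolutional stages (a linear stage mapping the fused vector onto
#' the coarse patch grid, two 3x3x3 convolutions each preceded by trilinear
#' x2 upsampling, and a 1x1 head after a final upsampling) produce T
#' normalized intensity volumes and a 2-channel voxel softmax tumor mask;
#' the viability softmax comes from the classifier head on the fused vector.
#' Spatially aligned conditioning channels (the per-phase patch projections
#' and the baseline tumor occupancy) are concatenated onto the coarse grid
#' so the decoder sees lesion location and local enhancement directly.
#'
#' @param fused fused feature vector
#'   `[f_global, f_t, f_s, f_roi, roi_curve, roi_metrics]`.
#' @param grid_cond `P x (cg*T + 1)` matrix of conditioning channels on the
#'   patch grid (per-phase projections and occupancy); zeros when absent.
#' @param model an [stdgnn_model()].
#' @return list with `intensity` (V x T, normalized), `mask_logits` (V x 2),
#'   `mask_prob` (V), `cache`.
#' @export
decoder <- function(fused, model, grid_cond = NULL, head_cond = NULL) {
  if (length(fused) != model$fused_dim) stop("fused dimension mismatch")
  p <- model$params; dc <- model$dec_cache
  cd <- model$config$decoder_channels
  P1 <- prod(model$dec_geom$g1)
  if (is.null(grid_cond)) grid_cond <- matrix(0, P1, model$cd_grid - cd)
  h0 <- as.numeric(fused %*% p$dec_fc_W) + p$dec_fc_b
  h0m <- matrix(h0, P1, cd)
  l0 <- lrelu_forward(h0m)
  g0 <- cbind(l0$y, grid_cond)
  u1 <- upsample_forward(g0, dc$U1)
  c1 <- conv3d_forward(u1, dc$idx1, p$dec_c1_W, p$dec_c1_b)
  l1 <- lrelu_forward(c1$y)
  u2 <- upsample_forward(l1$y, dc$U2)
  c2 <- conv3d_forward(u2, dc$idx2, p$dec_c2_W, p$dec_c2_b)
  l2 <- lrelu_forward(c2$y)
  u3 <- upsample_forward(l2$y, dc$U3)
  if (is.null(head_cond)) head_cond <- numeric(nrow(u3))
  u3 <- cbind(u3, head_cond)
  out <- sweep_add_rowvec(u3 %*% p$dec_h_W, p$dec_h_b)
  Tn <- model$n_phases
  ml <- out[, Tn + (1:2), drop = FALSE]
  # two-channel voxel softmax == sigmoid of the logit difference
  p1 <- sigmoid(ml[, 1] - ml[, 2])
  mp <- cbind(p1, 1 - p1)
  cache <- list(fused = fused, l0 = l0, u1 = u1, c1 = c1, l1 = l1,
                u2 = u2, c2 = c2, l2 = l2, u3 = u3, mask_prob2 = mp)
  list(intensity = out[, seq_len(Tn), drop = FALSE],
       mask_logits = ml, mask_prob = mp[, 1], cache = cache)
}

# dint: V x T gradient on intensity; dml: V x 2 gradient on mask logits.
# Returns weight grads, dfused, and dgrid (gradient on the conditioning
# channels: per-phase patch projections first, occupancy last).
decoder_backward <- function(dint, dml, cache, model) {
  p <- model$params; dc <- model$dec_cache
  dout <- cbind(dint, dml)
  grads <- list(dec_h_W = crossprod(cache$u3, dout), dec_h_b = colSums(dout))
  du3 <- dout %*% t(p$dec_h_W)
  du3 <- du3[, -ncol(du3), drop = FALSE]   # head conditioning channel ends here
  dl2 <- upsample_backward(du3, dc$U3)
  dz2 <- lrelu_backward(dl2, cache$l2)
  cd <- model$config$decoder_channels
  cd2 <- max(cd %/% 2L, 2L)
  cb2 <- conv3d_backward(dz2, cache$c2$cols, dc$idx2, p$dec_c2_W, Cin = cd2,
                         need_dx = TRUE, Vin = nrow(cache$u2))
  grads$dec_c2_W <- cb2$dW; grads$dec_c2_b <- cb2$db
  dl1 <- upsample_backward(cb2$dx, dc$U2)
  dz1 <- lrelu_backward(dl1, cache$l1)
  cb1 <- conv3d_backward(dz1, cache$c1$cols, dc$idx1, p$dec_c1_W,
                         Cin = model$cd_grid, need_dx = TRUE,
                         Vin = nrow(cache$u1))
  grads$dec_c1_W <- cb1$dW; grads$dec_c1_b <- cb1$db
  dg0 <- upsample_backward(cb1$dx, dc$U1)
  dh0 <- lrelu_backward(dg0[, seq_len(cd), drop = FALSE], cache$l0)
  dgrid <- dg0[, -seq_len(cd), drop = FALSE]
  dh0v <- as.numeric(dh0)
  grads$dec_fc_W <- outer(cache$fused, dh0v)
  grads$dec_fc_b <- dh0v
  dfused <- as.numeric(p$dec_fc_W %*% dh0v)
  list(grads = grads, dfused = dfused, dgrid = dgrid)
}

# ---- full forward -----------------------------------------------------------

# normalized internal distance map of a binary mask: 6-neighborhood BFS
# depth from the background, scaled to [0, 1] by its maximum; 0 outside
mask_distance_norm <- function(mask) {
  m <- array(as.numeric(mask != 0), dim = dim(mask))
  d <- dim(m)
  dist <- array(0, d)
  cur <- m
  lev <- 0
  repeat {
    # erode: voxels whose 6-neighbors (with background padding) are all fg
    pad <- array(0, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cur
    er <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] *
          pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] *
          pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] *
          pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] *
          pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] *
          pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)] * cur
    lev <- lev + 1
    dist <- dist + cur      # depth accumulates once per surviving level
    if (sum(er) == 0 || lev > max(d)) break
    cur <- er
  }
  mx <- max(dist)
  if (mx > 0) dist / mx else dist
}

#' Non-parametric descriptor vector of a sequence's tumor ROI curve
#'
#' Convenience wrapper: the mean ROI intensity curve of the annotated tumor
#' summarized by [nonparametric_metrics()], returned as
#' `c(T0, TTP, PER, nMITR, wash_in, wash_out)` — the clean, scale-free
#' enhancement evidence that feeds the viability classifier.
#'
#' @param seq a [dce_sequence()] with a mask.
#' @return named numeric vector of length 6.
#' @export
roi_descriptors <- function(seq) {
  rc <- roi_curve(seq, seq$mask)
  np <- nonparametric_metrics(rc$curve, rc$times)
  c(T0 = np$T0, TTP = np$TTP, PER = np$PER, nMITR = np$nMITR,
    wash_in = np$wash_in, wash_out = np$wash_out)
}

# fraction of tumor voxels per patch cell (baseline annotation, volume grid)
patch_occupancy <- function(mask, model) {
  as.numeric(extract_patch_features(array(as.numeric(mask),
                                          dim = c(dim(mask), 1L)),
                                    model$P_grid))
}

# ROI-weighted per-phase patch-feature means (position-invariant lesion
# enhancement summary); zeros when no annotation is present
roi_feature_summary <- function(pv_feats, occ) {
  s <- sum(occ)
  w <- if (s > 0) occ / s else occ
  as.numeric(vapply(pv_feats, function(X) as.numeric(crossprod(X, w)),
                    numeric(ncol(pv_feats[[1]]))))
}

# generator-branch features: per-phase patch projections, their pooled
# position-invariant summaries (global + ROI-weighted means), the spatial
# decoder map and the ROI feature summary
global_features <- function(pv, occ, model) {
  cg <- model$config$global_channels
  w_roi <- if (sum(occ) > 0) occ / sum(occ) else occ
  Fg <- lapply(pv, function(X) X %*% model$params$g_proj)
  f_global <- as.numeric(vapply(Fg, function(M)
    c(colMeans(M), as.numeric(crossprod(M, w_roi))), numeric(2L * cg)))
  grid_cond <- cbind(do.call(cbind, Fg), occ)
  roi <- roi_feature_summary(pv, occ)
  list(Fg = Fg, f_global = f_global, grid_cond = grid_cond, roi = roi,
       w_roi = w_roi)
}

# Build the temporal graph and per-volume structural graphs for a set of
# per-volume patch features (single sequence => single class, so the
# between-class adjacency is empty and enters through its self-loop
# normalization).
sequence_graphs <- function(pv_feats, label, k_w, k_b) {
  X0 <- do.call(rbind, pv_feats)
  n <- nrow(X0)
  labs <- rep(as.character(label), n)
  Ww <- build_within_graph(X0, k_w, labels = labs, quiet = TRUE)
  Wb <- build_between_graph(X0, k_b, labels = labs, quiet = TRUE)
  tg <- list(Ww_hat = normalize_adjacency(Ww), Wb_hat = normalize_adjacency(Wb))
  sg <- lapply(pv_feats, function(Xv) {
    lv <- rep("x", nrow(Xv))
    Wwv <- build_within_graph(Xv, k_w, labels = lv, quiet = TRUE)
    Wbv <- build_between_graph(Xv, k_b, labels = lv, quiet = TRUE)
    list(Ww_hat = normalize_adjacency(Wwv), Wb_hat = normalize_adjacency(Wbv))
  })
  list(temporal = tg, structural = sg)
}

#' Full STDGNN forward pass for one sequence
#'
#' Runs backbone (or uses cached patch features), builds the discriminant
#' graphs, evaluates the three branches and the classifier, and optionally
#' decodes the follow-up prediction.
#'
#' @param model an [stdgnn_model()].
#' @param pv_feats list of per-volume `P x d0` patch feature matrices for
#'   the frames used (e.g. from [sequence_patch_features()], subsampled).
#' @param label viability label used for graph construction (predicted label
#'   at test time; graphs here are per-sequence so it only tags nodes).
#' @param mask optional baseline tumor mask (3D array at volume resolution);
#'   when given, the ROI-weighted feature summary and patch occupancy enter
#'   the fused vector (zeros otherwise).
#' @param roi_curve optional normalized ROI mean-enhancement samples for the
#'   frames used (exact masked means of the input volumes); zeros otherwise.
#' @param roi_metrics optional length-6 vector of non-parametric enhancement
#'   descriptors of the input ROI curve (`c(T0, TTP, PER, nMITR, wash_in,
#'   wash_out)`, see [roi_descriptors()]); zeros otherwise.
#' @param training batch-norm mode.
#' @param decode if `TRUE` run the decoder.
#' @return list with `f_t`, `f_s`, `f_global`, `fused`, `logits`, `probs`,
#'   decoder outputs when requested, and `cache`/`bn` for training.
#' @export
stdgnn_forward <- function(model, pv_feats, label = NA, mask = NULL,
                           roi_curve = NULL, roi_metrics = NULL,
                           training = FALSE, decode = TRUE) {
  cfg <- model$config
  g <- sequence_graphs(pv_feats, label, cfg$k_w, cfg$k_b)
  X0 <- do.call(rbind, pv_feats)
  tb <- temporal_branch(X0, g$temporal$Wb_hat, g$temporal$Ww_hat, model,
                        training = training)
  model$bn <- tb$bn
  sb <- structural_branch(pv_feats, g$structural, model, training = training)
  model$bn <- sb$bn
  occ <- if (is.null(mask)) rep(0, model$P) else patch_occupancy(mask, model)
  gf <- global_features(pv_feats, occ, model)
  if (is.null(roi_curve)) roi_curve <- rep(0, length(pv_feats))
  if (is.null(roi_metrics)) roi_metrics <- rep(0, 6)
  fused <- c(gf$f_global, tb$f_t, sb$f_s, gf$roi, roi_curve, roi_metrics)
  fused_std <- (fused - model$fused_center) / model$fused_scale
  logits <- as.numeric(fused_std %*% model$params$cls_W) + model$params$cls_b
  probs <- as.numeric(softmax_rows(matrix(logits, 1)))
  names(probs) <- CLASS_LEVELS
  head_cond <- if (is.null(mask)) NULL else as.numeric(mask_distance_norm(mask))
  dec <- if (decode) decoder(fused, model, grid_cond = gf$grid_cond,
                             head_cond = head_cond) else NULL
  list(f_t = tb$f_t, f_s = sb$f_s, f_global = gf$f_global, fused = fused,
       fused_std = fused_std, logits = logits, probs = probs, decoder = dec,
       cache = list(tb = tb$cache, sb = sb$cache, pv = pv_feats, X0 = X0,
                    gf = gf),
       bn = model$bn)
}
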