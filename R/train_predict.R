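# Training loop (alternating generator/branches and discriminator steps),
# frame sampling, nonlinear-warp augmentation, checkpointing and end-to-end
# inference.

#' Randomly subsample frames of a sequence, preserving time order
#'
#' @param seq a [dce_sequence()].
#' @param T_sample frames to draw without replacement.
#' @param seed integer seed (deterministic draw).
#' @return a [dce_sequence()] with `T_sample` phases; the chosen indices are
#'   attached as attribute `"indices"`.
#' @export
sample_frames <- function(seq, T_sample, seed = 1L) {
  Tn <- length(seq$volumes)
  if (T_sample > Tn) stop("T_sample exceeds number of frames")
  set.seed(seed)
  idx <- sort(sample.int(Tn, T_sample))
  out <- dce_sequence(seq$volumes[idx], seq$times[idx], spacing = seq$spacing,
                      mask = seq$mask, label = seq$label,
                      phase_of = seq$phase_of, id = seq$id)
  attr(out, "indices") <- idx
  out
}

sample_frame_indices <- function(Tn, T_sample, seed) {
  set.seed(seed)
  sort(sample.int(Tn, T_sample))
}

even_frame_indices <- function(Tn, T_sample) {
  unique(round(seq(1, Tn, length.out = T_sample)))
}

# trilinear sampling of a volume at displaced coordinates
warp_volume <- function(vol, disp, nearest = FALSE) {
  d <- dim(vol)
  gx <- rep.int(seq_len(d[1]), times = d[2] * d[3])
  gy <- rep.int(rep(seq_len(d[2]), each = d[1]), times = d[3])
  gz <- rep(seq_len(d[3]), each = d[1] * d[2])
  xs <- pmin(pmax(gx + disp[, 1], 1), d[1])
  ys <- pmin(pmax(gy + disp[, 2], 1), d[2])
  zs <- pmin(pmax(gz + disp[, 3], 1), d[3])
  if (nearest) {
    lin <- round(xs) + d[1] * (round(ys) - 1) + d[1] * d[2] * (round(zs) - 1)
    return(array(vol[lin], dim = d))
  }
  x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(xi, yi, zi) vol[xi + d[1] * (yi - 1) + d[1] * d[2] * (zi - 1)]
  out <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
         fx * (1 - fy) * (1 - fz) * at(x1, y0, z0) +
         (1 - fx) * fy * (1 - fz) * at(x0, y1, z0) +
         fx * fy * (1 - fz) * at(x1, y1, z0) +
         (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
         fx * (1 - fy) * fz * at(x1, y0, z1) +
         (1 - fx) * fy * fz * at(x0, y1, z1) +
         fx * fy * fz * at(x1, y1, z1)
  array(out, dim = d)
}

#' Nonlinear-warp augmentation
#'
#' Applies a smooth random displacement field (Gaussian-smoothed white
#' noise, rescaled so the maximum displacement is at most `max_disp` voxels)
#' with trilinear interpolation; masks are warped with nearest-neighbor
#' interpolation so they stay binary.
#'
#' @param volume 3D array.
#' @param seed integer seed for the field.
#' @param max_disp maximum displacement (voxels).
#' @param sigma smoothing s.d. of the field (voxels).
#' @param mask optional binary mask warped with the same field.
#' @return warped volume, or `list(volume, mask)` when a mask is given.
#' @export
augment <- function(volume, seed = 1L, max_disp = 3, sigma = 4, mask = NULL) {
  d <- dim(volume)
  set.seed(seed)
  disp <- matrix(0, prod(d), 3)
  if (max_disp > 0) {
    for (ax in 1:3) {
      f <- gauss_smooth3(array(stats::rnorm(prod(d)), dim = d), sigma)
      mx <- max(abs(f))
      if (mx > 0) f <- f / mx * max_disp
      disp[, ax] <- as.numeric(f)
    }
  }
  wv <- warp_volume(volume, disp)
  if (is.null(mask)) return(wv)
  list(volume = wv, mask = warp_volume(mask, disp, nearest = TRUE))
}

# ---- encodings --------------------------------------------------------------

# Precompute everything that does not depend on trainable weights:
# per-volume patch features (frozen backbone), per-volume structural graphs,
# normalized post-sequence targets and the post-mask target.
prepare_encodings <- function(cohort, model, verbose = FALSE) {
  cfg <- model$config
  enc <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    smp <- cohort[[i]]
    pv <- sequence_patch_features(smp$pre, model)
    sg <- lapply(pv, function(Xv) {
      lv <- rep("x", nrow(Xv))
      Wwv <- build_within_graph(Xv, cfg$k_w, labels = lv, quiet = TRUE)
      Wbv <- build_between_graph(Xv, cfg$k_b, labels = lv, quiet = TRUE)
      list(Ww_hat = normalize_adjacency(Wwv), Wb_hat = normalize_adjacency(Wbv))
    })
    y_int <- vapply(smp$post$volumes,
                    function(v) normalize_volume(as.numeric(v), model$intensity_scale),
                    numeric(prod(model$volume_shape)))
    roi_c <- vapply(smp$pre$volumes, function(v)
      mean(normalize_volume(v[smp$pre$mask != 0], model$intensity_scale)),
      numeric(1))
    enc[[i]] <- list(pv = pv, sgraphs = sg,
                     occ = patch_occupancy(smp$pre$mask, model),
                     roi_curve = roi_c,
                     roi_np = as.numeric(roi_descriptors(smp$pre)),
                     dist = as.numeric(mask_distance_norm(smp$pre$mask)),
                     label = smp$pre$label,
                     y_int = y_int,
                     y_crop = crop_volume_stack(y_int, model),
                     y_mask = as.numeric(smp$post$mask),
                     pre_mask = as.numeric(smp$pre$mask),
                     id = smp$pre$id,
                     tg_cache = new.env(parent = emptyenv()))
    if (verbose && i %% 10 == 0) message(sprintf("  encoded %d/%d", i, length(cohort)))
  }
  enc
}

# branch + classifier forward from a cached encoding; optional train-time
# feature jitter (noise_sd > 0 disables the cached clean-feature graphs)
encoding_forward <- function(model, enc_i, frame_idx, training, decode = TRUE,
                             noise_sd = NULL) {
  cfg <- model$config
  pv <- enc_i$pv[frame_idx]
  if (!is.null(noise_sd) && any(noise_sd > 0)) {
    # jitter node features; graph topology stays that of the clean encoding
    pv <- lapply(pv, function(X)
      X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) *
        matrix(noise_sd, nrow(X), ncol(X), byrow = TRUE))
  }
  X0 <- do.call(rbind, pv)
  key <- paste(frame_idx, collapse = "_")
  if (!is.null(enc_i$tg_cache) && !is.null(enc_i$tg_cache[[key]])) {
    tg <- enc_i$tg_cache[[key]]
    Ww <- tg$Ww; Wb <- tg$Wb; Ww_hat <- tg$Ww_hat; Wb_hat <- tg$Wb_hat
  } else {
    X0c <- do.call(rbind, enc_i$pv[frame_idx])   # graphs from clean features
    lv <- rep("x", nrow(X0c))
    Ww <- build_within_graph(X0c, cfg$k_w, labels = lv, quiet = TRUE)
    Wb <- build_between_graph(X0c, cfg$k_b, labels = lv, quiet = TRUE)
    Ww_hat <- normalize_adjacency(Ww); Wb_hat <- normalize_adjacency(Wb)
    if (!is.null(enc_i$tg_cache))
      enc_i$tg_cache[[key]] <- list(Ww = Ww, Wb = Wb, Ww_hat = Ww_hat,
                                    Wb_hat = Wb_hat)
  }
  tb <- temporal_branch(X0, Wb_hat, Ww_hat, model, training = training)
  model$bn <- tb$bn
  sb <- structural_branch(pv, enc_i$sgraphs[frame_idx], model,
                          training = training)
  model$bn <- sb$bn
  occ <- if (is.null(enc_i$occ)) rep(0, model$P) else enc_i$occ
  gf <- global_features(pv, occ, model)
  roi_c <- if (is.null(enc_i$roi_curve)) rep(0, length(frame_idx))
           else enc_i$roi_curve[frame_idx]
  roi_np <- if (is.null(enc_i$roi_np)) rep(0, 6) else enc_i$roi_np
  fused <- c(gf$f_global, tb$f_t, sb$f_s, gf$roi, roi_c, roi_np)
  fused_std <- (fused - model$fused_center) / model$fused_scale
  logits <- as.numeric(fused_std %*% model$params$cls_W) + model$params$cls_b
  probs <- as.numeric(softmax_rows(matrix(logits, 1)))
  dec <- if (decode) decoder(fused, model, grid_cond = gf$grid_cond,
                             head_cond = enc_i$dist) else NULL
  list(f_t = tb$f_t, f_s = sb$f_s, f_global = gf$f_global, fused = fused,
       fused_std = fused_std, logits = logits, probs = probs, dec = dec,
       tb_cache = tb$cache, sb_cache = sb$cache, pv = pv, gf = gf,
       Ww = Ww, Wb = Wb, bn = model$bn)
}

# gradient wrt the fused vector (and optionally the decoder's spatial map)
# -> all branch/projection weight grads
fused_backward <- function(model, fwd, dfused, dspatial = NULL,
                           df_t_extra = NULL, df_s_extra = NULL) {
  P <- model$P; cg <- model$config$global_channels
  dk <- model$config$d_k
  Tn <- length(fwd$pv)
  ng <- 2L * cg * Tn
  ns <- Tn * model$s_dims[length(model$s_dims)]
  df_global <- dfused[seq_len(ng)]
  df_t <- dfused[ng + seq_len(dk)]
  df_s <- dfused[ng + dk + seq_len(ns)]
  # the trailing ROI-summary segment has no trainable upstream (the
  # annotation is an input); its gradient ends here
  if (!is.null(df_t_extra)) df_t <- df_t + df_t_extra
  if (!is.null(df_s_extra)) df_s <- df_s + df_s_extra
  g <- temporal_branch_backward(df_t, fwd$tb_cache, model)
  gs <- structural_branch_backward(df_s, fwd$sb_cache, model)
  g <- acc_grads_init(g, gs)
  # generator projection: pooled summaries + (optional) spatial map
  w_roi <- fwd$gf$w_roi
  dglob <- matrix(df_global, 2L * cg, Tn)
  g$g_proj <- matrix(0, model$d0, cg)
  for (tt in seq_len(Tn)) {
    dFg <- matrix(0, P, cg)
    dmean <- dglob[seq_len(cg), tt]
    droi <- dglob[cg + seq_len(cg), tt]
    dFg <- dFg + matrix(dmean / P, P, cg, byrow = TRUE)
    dFg <- dFg + outer(w_roi, droi)
    if (!is.null(dspatial))
      dFg <- dFg + matrix(dspatial[(tt - 1L) * P * cg + seq_len(P * cg)], P, cg)
    g$g_proj <- g$g_proj + crossprod(fwd$pv[[tt]], dFg)
  }
  # occupancy tail of dspatial has no trainable upstream
  g
}

# L2 row normalization with exact gradient pull-back:
# for fhat = f/|f|, df = (G - fhat (fhat . G)) / |f|
l2_rows <- function(F) {
  nr <- sqrt(rowSums(F^2))
  list(Y = F / pmax(nr, 1e-12), nr = pmax(nr, 1e-12))
}
l2_rows_backward <- function(G, Y, nr) {
  (G - Y * rowSums(G * Y)) / nr
}

acc_grads_init <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

stratified_batches <- function(labels, batch_size, seed) {
  set.seed(seed)
  byc <- split(seq_along(labels), labels)
  byc <- lapply(byc, function(v) v[sample.int(length(v))])
  order_rr <- integer(0)
  while (any(lengths(byc) > 0)) {
    for (cl in names(byc)) {
      if (length(byc[[cl]]) > 0) {
        order_rr <- c(order_rr, byc[[cl]][1])
        byc[[cl]] <- byc[[cl]][-1]
      }
    }
  }
  split(order_rr, ceiling(seq_along(order_rr) / batch_size))
}

# ---- training ---------------------------------------------------------------

#' Train the STDGNN on a phantom (or real) cohort
#'
#' Alternates a generator/branches step (classification softmax, batch-hard
#' triplet losses on the temporal and structural features, tumor-mask
#' cross-entropy through the decoder, and the transport-weighted adversarial
#' term) with a discriminator step, once each per batch. All loss components
#' are logged per step; training aborts on non-finite loss. The best
#' checkpoint by validation Dice is retained.
#'
#' @param cohort list of `list(pre, post, truth)` as from [generate_cohort()];
#'   all three viability classes must be present.
#' @param config an `stdgnn_config`; `config$seed` drives all randomness.
#' @param epochs number of epochs (defaults to `config$epochs`).
#' @param val_frac stratified validation fraction.
#' @param state optional `stdgnn_train_state` to resume from.
#' @param checkpoint_path optional RDS path for the rolling checkpoint.
#' @param val_every validation cadence (epochs).
#' @param adv_weight_cap numerical cap on the transport fake-term weight used
#'   in the gradient steps (the logged `E_adv` uses the uncapped weight).
#' @param clip_norm global gradient-norm clip for both optimizer steps.
#' @param adv_start_frac fraction of the schedule trained before the
#'   adversarial phase starts (supervised/metric warm-up, then adversarial
#'   fine-tuning; `E_adv` is logged as 0 during the warm-up).
#' @param ablate character vector for ablation studies: `"adv"` disables the
#'   adversarial branch (discriminator untrained, E_adv logged as 0),
#'   `"triplet"` disables the branch triplet losses.
#' @param verbose print progress lines.
#' @return an `stdgnn_train_state`.
#' @export
train_stdgnn <- function(cohort, config = desk_config(), epochs = config$epochs,
                         val_frac = 0.2, state = NULL, checkpoint_path = NULL,
                         val_every = 5L, adv_weight_cap = 2, clip_norm = 5,
                         adv_start_frac = 0.8, ablate = character(0),
                         verbose = TRUE) {
  labels <- vapply(cohort, function(s) s$pre$label, character(1))
  if (length(unique(labels)) < 3L) stop("cohort must contain all three classes")
  t0 <- proc.time()[3]

  if (is.null(state)) {
    smp1 <- cohort[[1]]$pre
    model <- stdgnn_model(config, volume_shape = dim(smp1$volumes[[1]]),
                          n_phases = length(smp1$volumes), times = smp1$times,
                          seed = config$seed)
    # stratified train/validation split
    set.seed(derive_seed(config$seed, "split"))
    val_idx <- unlist(lapply(split(seq_along(labels), labels), function(v)
      sample(v, max(1L, round(length(v) * val_frac)))))
    gen_names <- names(model$params)[!startsWith(names(model$params), "disc_")]
    dsc_names <- setdiff(names(model$params), gen_names)
    state <- structure(list(
      model = model, epoch = 0L,
      opt_gen = adam_state(model$params[gen_names]),
      opt_disc = adam_state(model$params[dsc_names]),
      gen_names = gen_names, disc_names = dsc_names,
      history = NULL, val_history = NULL,
      val_idx = sort(val_idx), config = config,
      config_hash = digest_config(config),
      best = NULL, seed = config$seed), class = "stdgnn_train_state")
  } else {
    if (!identical(state$config_hash, digest_config(config)))
      warning("config differs from the checkpointed config; using checkpoint's")
    config <- state$config
  }
  model <- state$model
  cfg <- config
  enc <- prepare_encodings(cohort, model, verbose = verbose)
  # per-channel feature scale for the train-time jitter
  feat_sd <- NULL
  if (!is.null(cfg$feature_noise) && cfg$feature_noise > 0) {
    allf <- do.call(rbind, lapply(enc, function(e) do.call(rbind, e$pv)))
    feat_sd <- cfg$feature_noise * apply(allf, 2, stats::sd)
  }
  train_idx <- setdiff(seq_along(cohort), state$val_idx)
  # fused-feature standardization for the sparse classifier head (fixed
  # affine map estimated once from the initial encodings)
  if (state$epoch == 0L) {
    fidx0 <- even_frame_indices(model$n_phases, cfg$T_sample)
    FS <- t(vapply(train_idx, function(i)
      encoding_forward(model, enc[[i]], fidx0, training = FALSE,
                       decode = FALSE)$fused, numeric(model$fused_dim)))
    model$fused_center <- colMeans(FS)
    sds <- apply(FS, 2, stats::sd)
    model$fused_scale <- ifelse(sds > 1e-8, sds, 1)
    state$model <- model
  }
  beta1 <- if (isTRUE(cfg$use_momentum_as_beta1)) cfg$momentum else 0.9
  hist_rows <- list()
  val_rows <- list()
  Vvox <- prod(model$volume_shape)

  for (ep in (state$epoch + 1L):epochs) {
    lr_ep <- cfg$lr * if (ep > cfg$lr_decay_after)
      cfg$lr_decay_factor^ceiling((ep - cfg$lr_decay_after) / cfg$lr_decay_every) else 1
    batches <- stratified_batches(labels[train_idx], cfg$batch_size,
                                  derive_seed(cfg$seed, "shuffle", ep))
    step <- 0L
    for (bi in seq_along(batches)) {
      batch <- train_idx[batches[[bi]]]
      B <- length(batch)
      step <- step + 1L
      # decoder/adversarial work runs on a seeded half-batch each step
      set.seed(derive_seed(cfg$seed, "advsub", ep, step))
      adv_set <- sort(sample.int(B, min(B, max(2L, ceiling(B / 2)))))
      fwds <- vector("list", B)
      for (j in seq_len(B)) {
        i <- batch[j]
        fidx <- sample_frame_indices(model$n_phases, cfg$T_sample,
                                     derive_seed(cfg$seed, "frames", ep, i))
        set.seed(derive_seed(cfg$seed, "fjit", ep, i))
        fwds[[j]] <- encoding_forward(model, enc[[i]], fidx, training = TRUE,
                                      decode = j %in% adv_set,
                                      noise_sd = feat_sd)
        model$bn <- fwds[[j]]$bn
      }
      y_lab <- match(labels[batch], CLASS_LEVELS)

      # running standardization of the fused vector (tracks the drifting
      # branch features; the classifier always sees ~unit-scale inputs)
      Fb <- t(vapply(fwds, `[[`, numeric(model$fused_dim), "fused"))
      if (B >= 2L) {
        mom_f <- 0.05
        model$fused_center <- (1 - mom_f) * model$fused_center + mom_f * colMeans(Fb)
        sd_b <- apply(Fb, 2, stats::sd)
        ok <- is.finite(sd_b) & sd_b > 1e-8
        model$fused_scale[ok] <- (1 - mom_f) * model$fused_scale[ok] +
          mom_f * sd_b[ok]
      }

      # ---- losses on the batch
      # classification with block dropout on the branch features: the
      # classifier cannot rely on any individual temporal/structural
      # embedding dimension, which biases it toward the stable ROI blocks
      FSd <- t(vapply(fwds, `[[`, numeric(model$fused_dim), "fused_std"))
      drop_mask <- matrix(1, B, model$fused_dim)
      pdrop <- cfg$cls_branch_dropout
      if (!is.null(pdrop) && pdrop > 0) {
        ng0 <- model$f_global_len
        nb <- cfg$d_k + cfg$T_sample * model$s_dims[length(model$s_dims)]
        bidx <- ng0 + seq_len(nb)
        set.seed(derive_seed(cfg$seed, "clsdrop", ep, step))
        drop_mask[, bidx] <- matrix(stats::rbinom(B * nb, 1, 1 - pdrop),
                                    B) / (1 - pdrop)
        FSd <- FSd * drop_mask
      }
      logits <- sweep_add_rowvec(FSd %*% model$params$cls_W,
                                 model$params$cls_b)
      pcls <- softmax_rows(logits)
      E_softmax <- -mean(log(pmax(pcls[cbind(seq_len(B), y_lab)], EPS_LOG)))
      dlogits <- (pcls - diag(3)[y_lab, , drop = FALSE]) / B

      # batch-hard triplets on L2-normalized embeddings (margin on the
      # unit sphere); gradients pulled back through the normalization
      Ft <- t(vapply(fwds, `[[`, numeric(cfg$d_k), "f_t"))
      Fs <- t(vapply(fwds, `[[`, numeric(length(fwds[[1]]$f_s)), "f_s"))
      if ("triplet" %in% ablate) {
        trt <- list(loss = 0, grad = NULL); trs <- list(loss = 0, grad = NULL)
      } else {
        nt <- l2_rows(Ft); ns <- l2_rows(Fs)
        trt <- triplet_loss(nt$Y, labels[batch], cfg$triplet_margin, grad = TRUE, quiet = TRUE)
        trs <- triplet_loss(ns$Y, labels[batch], cfg$triplet_margin, grad = TRUE, quiet = TRUE)
        trt$grad <- l2_rows_backward(trt$grad, nt$Y, nt$nr)
        trs$grad <- l2_rows_backward(trs$grad, ns$Y, ns$nr)
      }

      Fg <- t(vapply(fwds, `[[`, numeric(model$f_global_len), "f_global"))
      cc <- class_transport_cost(Fg, labels[batch],
                                 n_projections = cfg$n_projections,
                                 seed = derive_seed(cfg$seed, "swd", ep, step),
                                 quiet = TRUE)
      wfake_full <- cfg$phi * cc + cfg$xi
      wfake <- min(wfake_full, adv_weight_cap)

      # discriminator forwards (adversarial subset only, fine-tuning phase)
      adv_on <- !("adv" %in% ablate) && ep > round(adv_start_frac * epochs)
      nA <- length(adv_set)
      dreal <- vector("list", nA); dfake <- vector("list", nA)
      s_real <- numeric(nA); s_fake <- numeric(nA)
      if (adv_on) {
        for (a in seq_len(nA)) {
          j <- adv_set[a]; i <- batch[j]
          dreal[[a]] <- discriminator(enc[[i]]$y_crop, model, cropped = TRUE)
          dfake[[a]] <- discriminator(fwds[[j]]$dec$intensity, model)
          s_real[a] <- dreal[[a]]$score; s_fake[a] <- dfake[[a]]$score
        }
        s_real <- pmin(pmax(s_real, 1e-7), 1 - 1e-7)
        s_fake <- pmin(pmax(s_fake, 1e-7), 1 - 1e-7)
        E_adv <- -mean(log(s_real)) - mean(wfake_full * log(1 - s_fake))
      } else E_adv <- 0

      # unit-gradient discriminator backward per fake; weight/input grads
      # scale linearly with the scalar logit gradient, so each backward is
      # computed once and rescaled for the generator and discriminator steps
      db_fake <- if (adv_on) lapply(seq_len(nA), function(a)
        discriminator_backward(1, dfake[[a]]$cache, model, need_dx = TRUE))

      E_tumor <- 0
      gen_grads <- zero_like(model$params[state$gen_names])
      for (j in seq_len(B)) {
        a <- match(j, adv_set)
        dfused <- 0
        dspatial <- NULL
        if (!is.na(a)) {
          i <- batch[j]
          mp <- pmin(pmax(fwds[[j]]$dec$mask_prob, EPS_LOG), 1 - EPS_LOG)
          m <- enc[[i]]$y_mask
          # baseline weighting: foreground voxels reweighted toward the
          # background contribution; the cap keeps over-segmentation of
          # small (non-viable) targets from becoming free
          wpos <- min(max((Vvox - sum(m)) / max(sum(m), 1), 1), 10)
          wv <- 1 + (wpos - 1) * m
          sw <- sum(wv)
          E_tumor <- E_tumor + -sum(wv * (m * log(mp) + (1 - m) * log(1 - mp))) / sw / nA
          # mask-softmax gradient (2 channels, channel 1 = foreground)
          mp2 <- fwds[[j]]$dec$cache$mask_prob2
          dml <- wv * (mp2 - cbind(m, 1 - m)) / (sw * nA)
          # supervised mask gradient flows everywhere; the adversarial
          # generator gradient (non-saturating -w log D(fake)) updates the
          # decoder only, not the shared encoder (co-training stabilizer) --
          # decoder_backward is linear in its output gradients, so the two
          # contributions are separated by a second backward pass
          dd <- decoder_backward(matrix(0, Vvox, model$n_phases), dml,
                                 fwds[[j]]$dec$cache, model)
          gen_grads <- acc_grads(gen_grads, dd$grads)
          if (adv_on) {
            dz_gen <- cfg$lambda_a * wfake * (s_fake[a] - 1) / nA
            dint <- db_fake[[a]]$dx * dz_gen
            dd_adv <- decoder_backward(dint, matrix(0, Vvox, 2),
                                       fwds[[j]]$dec$cache, model)
            gen_grads <- acc_grads(gen_grads, dd_adv$grads)
          }
          ncg <- ncol(dd$dgrid) - 1L
          dspatial <- as.numeric(dd$dgrid[, seq_len(ncg), drop = FALSE])
          dfused <- dd$dfused
        }
        dfused_cls <- drop_mask[j, ] *
          as.numeric(model$params$cls_W %*% dlogits[j, ]) / model$fused_scale
        gb <- fused_backward(model, fwds[[j]], dfused + dfused_cls,
                             dspatial = dspatial,
                             df_t_extra = if (is.matrix(trt$grad)) trt$grad[j, ] else NULL,
                             df_s_extra = if (is.matrix(trs$grad)) trs$grad[j, ] else NULL)
        gen_grads <- acc_grads(gen_grads, gb)
      }
      gen_grads$cls_W <- crossprod(FSd, dlogits) +
        cfg$cls_l1 * sign(model$params$cls_W)
      gen_grads$cls_b <- colSums(dlogits)

      E_triplet_t <- if (is.list(trt)) trt$loss else trt
      E_triplet_s <- if (is.list(trs)) trs$loss else trs
      E_weight <- weight_divergence(fwds[[1]]$Wb, fwds[[1]]$Ww)
      rep_loss <- overall_loss(E_tumor = E_tumor, E_weight = E_weight,
                               E_adv = E_adv, E_triplet_t = E_triplet_t,
                               E_triplet_s = E_triplet_s, E_softmax = E_softmax,
                               lambda_w = cfg$lambda_w, lambda_a = cfg$lambda_a)
      if (!is.finite(rep_loss$E_overall))
        stop(sprintf("NaN/Inf loss at epoch %d step %d: %s", ep, step,
                     paste(names(rep_loss), unlist(rep_loss), collapse = ", ")))

      gen_grads <- clip_grads(gen_grads, clip_norm)
      # the sparse classifier head and the decoder train at 5x the base rate
      st <- adam_step(model$params[state$gen_names], gen_grads, state$opt_gen,
                      lr = lr_ep, beta1 = beta1,
                      weight_decay = cfg$weight_decay,
                      lr_scale = list(cls_W = 5, cls_b = 5,
                                      dec_fc_W = 5, dec_fc_b = 5,
                                      dec_c1_W = 5, dec_c1_b = 5,
                                      dec_c2_W = 5, dec_c2_b = 5,
                                      dec_h_W = 5, dec_h_b = 5))
      model$params[state$gen_names] <- st$params
      state$opt_gen <- st$state

      # ---- discriminator step (fakes detached; reuse forward caches)
      disc_grads <- zero_like(model$params[state$disc_names])
      if (adv_on) for (a in seq_len(nA)) {
        dz_r <- (s_real[a] - 1) / nA
        gr <- discriminator_backward(dz_r, dreal[[a]]$cache, model)$grads
        dz_f <- wfake * s_fake[a] / nA
        gf <- scale_grads(db_fake[[a]]$grads, dz_f)
        disc_grads <- acc_grads(disc_grads, gr)
        disc_grads <- acc_grads(disc_grads, gf)
      }
      disc_grads <- clip_grads(disc_grads, clip_norm)
      # discriminator stepped at half the generator rate (stability)
      if (adv_on) {
      st <- adam_step(model$params[state$disc_names], disc_grads, state$opt_disc,
                      lr = 0.5 * lr_ep, beta1 = beta1,
                      weight_decay = cfg$weight_decay)
      model$params[state$disc_names] <- st$params
      state$opt_disc <- st$state
      }

      hist_rows[[length(hist_rows) + 1L]] <-
        data.frame(epoch = ep, step = step, as.data.frame(unclass(rep_loss)),
                   c_transport = cc)
    }

    state$model <- model
    state$epoch <- ep
    if (ep %% val_every == 0L || ep == epochs) {
      vs <- validate_state(state, enc, labels, Vvox)
      vm <- vs$metrics
      val_rows[[length(val_rows) + 1L]] <- data.frame(epoch = ep, vm)
      score <- vm$accuracy + vm$dice   # joint classification/segmentation score
      if (is.null(state$best) || score >= state$best$score) {
        best_params <- model$params
        best_params$cls_b <- vs$cls_b   # keep the recalibrated bias
        state$best <- list(params = best_params, bn = model$bn, epoch = ep,
                           dice = vm$dice, accuracy = vm$accuracy,
                           fused_center = model$fused_center,
                           fused_scale = model$fused_scale,
                           mask_threshold = vs$mask_threshold,
                           score = score)
      }
      if (verbose)
        message(sprintf("epoch %3d | E_overall %.3f | val dice %.3f acc %.2f | %.0fs",
                        ep, utils::tail(hist_rows, 1)[[1]]$E_overall,
                        vm$dice, vm$accuracy, proc.time()[3] - t0))
      if (!is.null(checkpoint_path)) save_checkpoint(state, checkpoint_path)
    }
  }
  state$history <- rbind(state$history, do.call(rbind, hist_rows))
  state$val_history <- rbind(state$val_history, do.call(rbind, val_rows))
  state$model <- model
  if (!is.null(checkpoint_path)) save_checkpoint(state, checkpoint_path)
  state
}

# validation metrics; the classifier bias is recalibrated on the clean
# training features first (prior/threshold calibration — the dropout-trained
# head ranks classes well before its argmax boundaries settle)
validate_state <- function(state, enc, labels, Vvox) {
  model <- state$model
  idx <- state$val_idx
  if (length(idx) == 0)
    return(list(metrics = data.frame(dice = NA_real_, accuracy = NA_real_),
                cls_b = state$model$params$cls_b))
  fidx <- even_frame_indices(model$n_phases, model$config$T_sample)
  tr_idx <- setdiff(seq_along(enc), idx)
  FS <- t(vapply(tr_idx, function(i)
    encoding_forward(model, enc[[i]], fidx, training = FALSE,
                     decode = FALSE)$fused_std, numeric(model$fused_dim)))
  ytr <- match(labels[tr_idx], CLASS_LEVELS)
  W <- model$params$cls_W
  b <- model$params$cls_b
  for (it in 1:200) {
    Z <- sweep_add_rowvec(FS %*% W, b)
    P <- softmax_rows(Z)
    b <- b - 0.5 * colSums(P - diag(3)[ytr, , drop = FALSE]) / length(tr_idx)
  }
  # mask operating point chosen on the validation split alongside the
  # checkpoint itself
  thresholds <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  dmat <- matrix(0, length(idx), length(thresholds))
  hits <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fwd <- encoding_forward(model, enc[[i]], fidx, training = FALSE)
    truth <- enc[[i]]$y_mask > 0
    for (tt in seq_along(thresholds))
      dmat[k, tt] <- dice_coefficient(fwd$dec$mask_prob > thresholds[tt],
                                      truth) / 100
    z <- as.numeric(fwd$fused_std %*% W) + b
    hits[k] <- CLASS_LEVELS[which.max(z)] == labels[i]
  }
  best_t <- which.max(colMeans(dmat))
  list(metrics = data.frame(dice = mean(dmat[, best_t]), accuracy = mean(hits)),
       cls_b = b, mask_threshold = thresholds[best_t])
}

digest_config <- function(cfg) {
  paste(vapply(cfg[order(names(cfg))], function(x) paste(format(x), collapse = ","),
               character(1)), collapse = ";")
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry weights, optimizer state, batch-norm statistics, the
#' loss history and the config hash; saving and resuming reproduces the
#' subsequent loss trajectory bit-exact in deterministic mode.
#'
#' @param state an `stdgnn_train_state`.
#' @param path RDS file path.
#' @return `path` (save) or the restored state (load).
#' @export
save_checkpoint <- function(state, path) { saveRDS(state, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# ---- inference --------------------------------------------------------------

#' Predict the follow-up sequence, tumor mask and viability class
#'
#' Embeds the pre-treatment sequence (deterministic evenly-spaced frame
#' subsample, batch-norm in eval mode), infers the viability class and
#' decodes the post-treatment phase volumes and probabilistic tumor mask.
#'
#' @param seq a pre-treatment [dce_sequence()].
#' @param state a trained `stdgnn_train_state` (or an [stdgnn_model()]).
#' @param use_best use the best validation checkpoint when available.
#' @return list of class `stdgnn_prediction`: `post_sequence`
#'   ([dce_sequence()]), `post_mask` (probability array), `viability_class`,
#'   `class_probabilities`.
#' @export
predict_sequence <- function(seq, state, use_best = TRUE) {
  model <- if (inherits(state, "stdgnn_train_state")) state$model else state
  if (inherits(state, "stdgnn_train_state") && use_best && !is.null(state$best)) {
    model$params <- state$best$params
    model$bn <- state$best$bn
    if (!is.null(state$best$fused_center)) {
      model$fused_center <- state$best$fused_center
      model$fused_scale <- state$best$fused_scale
    }
  }
  if (any(dim(seq$volumes[[1]]) != model$volume_shape))
    stop("sequence geometry does not match the trained model")
  if (length(seq$volumes) != model$n_phases)
    stop("phase count does not match the trained model")
  pv <- sequence_patch_features(seq, model)
  fidx <- even_frame_indices(model$n_phases, model$config$T_sample)
  enc_i <- list(pv = pv,
                occ = if (is.null(seq$mask)) NULL
                      else patch_occupancy(seq$mask, model),
                roi_curve = if (is.null(seq$mask)) NULL
                  else vapply(seq$volumes, function(v)
                    mean(normalize_volume(v[seq$mask != 0], model$intensity_scale)),
                    numeric(1)),
                roi_np = if (is.null(seq$mask)) NULL
                         else as.numeric(roi_descriptors(seq)),
                dist = if (is.null(seq$mask)) NULL
                       else as.numeric(mask_distance_norm(seq$mask)),
                sgraphs = lapply(pv, function(Xv) {
    lv <- rep("x", nrow(Xv))
    Wwv <- build_within_graph(Xv, model$config$k_w, labels = lv, quiet = TRUE)
    Wbv <- build_between_graph(Xv, model$config$k_b, labels = lv, quiet = TRUE)
    list(Ww_hat = normalize_adjacency(Wwv), Wb_hat = normalize_adjacency(Wbv))
  }))
  fwd <- encoding_forward(model, enc_i, fidx, training = FALSE)
  vs <- model$volume_shape
  vols <- lapply(seq_len(model$n_phases), function(tt)
    array(denormalize_volume(fwd$dec$intensity[, tt], model$intensity_scale), dim = vs))
  thr <- 0.5
  if (inherits(state, "stdgnn_train_state") && use_best &&
      !is.null(state$best$mask_threshold)) thr <- state$best$mask_threshold
  mask_prob <- array(fwd$dec$mask_prob, dim = vs)
  mask_bin <- array(as.numeric(mask_prob > thr), dim = vs)
  post <- dce_sequence(vols, seq$times, spacing = seq$spacing,
                       mask = if (sum(mask_bin) >= 1) mask_bin else NULL,
                       phase_of = "post", id = paste0(seq$id, "_pred"))
  probs <- fwd$probs; names(probs) <- CLASS_LEVELS
  structure(list(post_sequence = post, post_mask = mask_prob,
                 post_mask_binary = mask_bin,
                 viability_class = CLASS_LEVELS[which.max(probs)],
                 class_probabilities = probs),
            class = "stdgnn_prediction")
}

#' Evaluate a trained model on held-out cohort samples
#'
#' @param state trained `stdgnn_train_state`.
#' @param cohort the full cohort list.
#' @param idx sample indices to evaluate (default: the validation split).
#' @return list with the per-case table and cohort summary (see
#'   [evaluation_report()]).
#' @export
holdout_evaluation <- function(state, cohort, idx = state$val_idx) {
  preds <- lapply(idx, function(i) predict_sequence(cohort[[i]]$pre, state))
  truths <- lapply(idx, function(i) cohort[[i]])
  evaluation_report(preds, truths)
}
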