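# Segmentation and classification metrics: Dice, Hausdorff and mean squared
# surface distance in physical units, voxel-intensity MSE, confusion matrix,
# accuracy, macro one-vs-rest AUC, and paired Wilcoxon tests.

#' Dice similarity coefficient (percent)
#'
#' `100 * 2|A n B| / (|A| + |B|)`; defined as 100 (with a flag) when both
#' masks are empty.
#'
#' @param mask_a,mask_b aligned binary masks (arrays or vectors).
#' @return Dice in `[0, 100]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("mask shape mismatch")
  a <- as.logical(mask_a != 0); b <- as.logical(mask_b != 0)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    out <- 100
    attr(out, "flag") <- "both_empty"
    return(out)
  }
  100 * 2 * sum(a & b) / (sa + sb)
}

# surface voxels: foreground with at least one 6-neighbor background (or on
# the volume boundary)
surface_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- which(core & !nb)
  arrayInd(surf, d)
}

# directed min distances (mm) from each point of A's surface to B's surface
surface_min_dists <- function(pa, pb, spacing) {
  A <- sweep(pa, 2, spacing, `*`)
  B <- sweep(pb, 2, spacing, `*`)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * (A %*% t(B))
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Hausdorff distance between mask surfaces (mm)
#'
#' Maximum of the two directed surface-voxel Hausdorff distances in
#' physical units.
#'
#' @param mask_a,mask_b nonempty binary 3D masks.
#' @param spacing voxel spacing (mm).
#' @return distance in mm.
#' @export
hausdorff_distance <- function(mask_a, mask_b, spacing = c(1, 1, 1)) {
  if (any(dim(mask_a) != dim(mask_b))) stop("mask shape mismatch")
  if (sum(mask_a != 0) == 0 || sum(mask_b != 0) == 0) stop("empty mask")
  pa <- surface_voxels(mask_a); pb <- surface_voxels(mask_b)
  max(max(surface_min_dists(pa, pb, spacing)),
      max(surface_min_dists(pb, pa, spacing)))
}

#' Mean squared symmetric surface distance (mm^2-rooted scale, reported mm)
#'
#' The mean over both surfaces of squared nearest-surface distances, with
#' the square root taken so the value is in mm.
#'
#' @inheritParams hausdorff_distance
#' @return RMS symmetric surface distance in mm.
#' @export
surface_mse <- function(mask_a, mask_b, spacing = c(1, 1, 1)) {
  if (sum(mask_a != 0) == 0 || sum(mask_b != 0) == 0) stop("empty mask")
  pa <- surface_voxels(mask_a); pb <- surface_voxels(mask_b)
  dab <- surface_min_dists(pa, pb, spacing)
  dba <- surface_min_dists(pb, pa, spacing)
  sqrt(mean(c(dab^2, dba^2)))
}

#' Classification report: confusion matrix, accuracy, macro OVR AUC
#'
#' Confusion matrix with fixed class order (V, E, NV), accuracy as
#' trace / n, and macro-averaged one-vs-rest AUC computed from per-class
#' scores via the Mann-Whitney rank statistic (ties get half credit).
#'
#' @param pred_labels,true_labels equal-length label vectors in
#'   `c("V","E","NV")`.
#' @param class_scores optional `n x 3` score matrix (columns V, E, NV).
#' @return list with `confusion` (3x3), `accuracy` (percent), `auc`
#'   (macro OVR, or NA without scores), `per_class_auc`.
#' @export
classification_report <- function(pred_labels, true_labels, class_scores = NULL) {
  if (length(pred_labels) != length(true_labels)) stop("length mismatch")
  if (!all(pred_labels %in% CLASS_LEVELS) || !all(true_labels %in% CLASS_LEVELS))
    stop("unseen label; classes must be V, E, NV")
  pf <- factor(pred_labels, levels = CLASS_LEVELS)
  tf <- factor(true_labels, levels = CLASS_LEVELS)
  confusion <- table(truth = tf, predicted = pf)
  acc <- 100 * sum(diag(confusion)) / length(tf)
  aucs <- rep(NA_real_, 3); names(aucs) <- CLASS_LEVELS
  if (!is.null(class_scores)) {
    class_scores <- as.matrix(class_scores)
    for (k in seq_along(CLASS_LEVELS)) {
      pos <- tf == CLASS_LEVELS[k]
      if (any(pos) && any(!pos)) aucs[k] <- auc_mw(class_scores[, k], pos)
    }
  }
  list(confusion = confusion, accuracy = acc,
       auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE),
       per_class_auc = aucs)
}

# Mann-Whitney AUC with tie correction
auc_mw <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are excluded (signed-rank convention); if all
#' differences are zero the p-value is 1 with a flag. Uses the exact
#' distribution when possible (small n, no ties), the normal approximation
#' otherwise.
#'
#' @param values_a,values_b equal-length paired samples, n >= 5.
#' @return list with `p_value`, `statistic`, `n_effective`, `flags`.
#' @export
paired_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("length mismatch")
  if (length(values_a) < 5L) stop("need n >= 5 pairs")
  d <- values_a - values_b
  if (all(d == 0))
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                flags = "all_differences_zero"))
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, paired = TRUE,
                                            exact = NULL))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_effective = sum(d != 0), flags = character(0))
}

#' Cohort evaluation report for follow-up predictions
#'
#' Per case: Dice (%), Hausdorff (mm), RMS surface distance (mm),
#' voxel-intensity MSE (on normalized intensity), predicted and true class,
#' predicted/true post tumor volumes. Cohort level: confusion matrix,
#' accuracy, macro one-vs-rest AUC and paired Wilcoxon p-values for the
#' intensity agreement.
#'
#' @param predictions list of `stdgnn_prediction`s.
#' @param truths matching list of cohort samples (`list(pre, post, truth)`).
#' @return list with `per_case` (data.frame) and `summary`.
#' @export
evaluation_report <- function(predictions, truths) {
  n <- length(predictions)
  rows <- vector("list", n)
  scores <- matrix(NA_real_, n, 3, dimnames = list(NULL, CLASS_LEVELS))
  for (i in seq_len(n)) {
    pr <- predictions[[i]]; tr <- truths[[i]]
    pm <- pr$post_mask_binary
    tm <- tr$post$mask
    sp <- tr$post$spacing
    dsc <- dice_coefficient(pm, tm)
    hd <- if (sum(pm) > 0) hausdorff_distance(pm, tm, sp) else NA_real_
    sm <- if (sum(pm) > 0) surface_mse(pm, tm, sp) else NA_real_
    iv_pred <- vapply(pr$post_sequence$volumes, as.numeric,
                      numeric(length(tm)))
    iv_true <- vapply(tr$post$volumes, as.numeric, numeric(length(tm)))
    scale <- 100
    imse <- mean(((iv_pred - iv_true) / scale)^2)
    scores[i, ] <- pr$class_probabilities
    rows[[i]] <- data.frame(
      case = i, dice = as.numeric(dsc), hausdorff = hd, surface_rms = sm,
      intensity_mse = imse,
      predicted_class = pr$viability_class, true_class = tr$pre$label,
      pred_volume = sum(pm), true_post_volume = sum(tm),
      input_volume = sum(tr$pre$mask))
  }
  per_case <- do.call(rbind, rows)
  cls <- classification_report(per_case$predicted_class, per_case$true_class,
                               scores)
  nv <- per_case$true_class == "NV"
  summary <- list(
    mean_dice = mean(per_case$dice),
    mean_hausdorff = mean(per_case$hausdorff, na.rm = TRUE),
    mean_intensity_mse = mean(per_case$intensity_mse),
    accuracy = cls$accuracy, auc = cls$auc, confusion = cls$confusion,
    nv_shrink_fraction = if (any(nv))
      mean(per_case$pred_volume[nv] < per_case$input_volume[nv]) else NA_real_)
  list(per_case = per_case, summary = summary)
}
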