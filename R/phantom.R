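# Synthetic 4D DCE-MRI phantoms with known viability class, known
# dual-input single-compartment kinetics and a known pre->post transformation.

#' Phantom specification
#'
#' Describes one synthetic pre/post DCE-MRI pair: volume geometry, the
#' spherical tumor, per-tissue kinetic parameters of the dual-input
#' single-compartment model (all in s^-1, at the 1e-3 s^-1 scale typical of
#' hepatic perfusion), the noise level and the class-specific post-treatment
#' effect (radius scale, enhancement scale).
#'
#' Default class kinetics encode the physiological premise that pre-treatment
#' enhancement carries the response signal: viable tumors are strongly
#' arterialized (high Ka), non-viable ones hypovascular; the post effect
#' applies devascularization + shrinkage for NV, partial change for E, growth
#' with preserved enhancement for V.
#'
#' @param class_label `"V"`, `"E"` or `"NV"`.
#' @param volume_shape integer length-3 volume shape in voxels.
#' @param n_timepoints number of phases.
#' @param times acquisition times (s post-injection).
#' @param spacing voxel spacing in mm.
#' @param center tumor center (voxels); default volume center.
#' @param radius tumor radius (voxels), must be >= 2.
#' @param kinetic_params named list with `tumor`, `parenchyma` entries, each
#'   `c(Ka=, Kp=, K2=)` in s^-1; default depends on `class_label`.
#' @param noise_sigma additive noise s.d. (intensity units; baseline is 100).
#' @param rician if `TRUE` use Rician-like magnitude noise instead of Gaussian.
#' @param texture_amp amplitude of the smooth multiplicative spatial texture.
#' @param post_effect named list mapping class to `c(radius_scale=, enh_scale=)`.
#' @param s0 baseline signal intensity; `signal_scale` converts concentration
#'   to enhancement (S = s0 * (1 + signal_scale * C)).
#' @param seed integer seed for all random draws of this phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = "V",
                         volume_shape = c(48L, 48L, 16L),
                         n_timepoints = 5L,
                         times = c(10, 60, 100, 145, 320),
                         spacing = c(1.9, 1.9, 2.5),
                         center = NULL,
                         radius = 6,
                         kinetic_params = NULL,
                         noise_sigma = 2,
                         rician = FALSE,
                         texture_amp = 0.05,
                         post_effect = NULL,
                         s0 = 100, signal_scale = 1.5,
                         seed = 1L) {
  class_label <- match.arg(class_label, c("V", "E", "NV"))
  volume_shape <- as.integer(volume_shape)
  if (is.null(center)) center <- (volume_shape + 1) / 2
  if (radius < 2) stop("tumor radius must be >= 2 voxels")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(kinetic_params)) {
    tum <- switch(class_label,
                  V  = c(Ka = 0.030, Kp = 0.004, K2 = 0.012),
                  E  = c(Ka = 0.018, Kp = 0.008, K2 = 0.010),
                  NV = c(Ka = 0.008, Kp = 0.012, K2 = 0.008))
    kinetic_params <- list(tumor = tum,
                           parenchyma = c(Ka = 0.004, Kp = 0.020, K2 = 0.015))
  }
  for (tis in kinetic_params)
    if (any(tis < 0)) stop("kinetic params must be >= 0")
  if (is.null(post_effect))
    post_effect <- list(V  = c(radius_scale = 1.15, enh_scale = 1.00),
                        E  = c(radius_scale = 0.80, enh_scale = 0.60),
                        NV = c(radius_scale = 0.55, enh_scale = 0.25))
  for (pe in post_effect)
    if (pe[["enh_scale"]] < 0 || pe[["enh_scale"]] > 2)
      stop("enhancement scale must lie in [0, 2]")
  if (length(times) != n_timepoints) stop("times must have n_timepoints entries")
  structure(list(class_label = class_label, volume_shape = volume_shape,
                 n_timepoints = as.integer(n_timepoints), times = as.numeric(times),
                 spacing = spacing, center = center, radius = radius,
                 kinetic_params = kinetic_params, noise_sigma = noise_sigma,
                 rician = rician, texture_amp = texture_amp,
                 post_effect = post_effect, s0 = s0, signal_scale = signal_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Arterial and portal-venous input functions
#'
#' Returns the two vascular input curves feeding the kinetic model: the
#' arterial input function (AIF) as a sharp gamma-variate bolus and the
#' portal input function (PIF) as a delayed, dispersed version of it. Both
#' are zero before their arrival times. Returned as closures of time (s)
#' together with samples at `times`.
#'
#' @param times acquisition times (s), increasing.
#' @param aif_t0,pif_t0 arrival times (s).
#' @param aif_alpha,aif_beta gamma-variate shape/scale of the AIF.
#' @param pif_alpha,pif_beta shape/scale of the PIF.
#' @param amplitude peak AIF concentration (a.u.); 0 gives flat zero curves.
#' @param seed unused placeholder kept for interface stability (the input
#'   functions are deterministic); present so cohort code can thread seeds.
#' @return list with `aif`, `pif` (functions), `aif_samples`, `pif_samples`.
#' @export
make_input_functions <- function(times, aif_t0 = 6, pif_t0 = 16,
                                 aif_alpha = 2.5, aif_beta = 9,
                                 pif_alpha = 2.2, pif_beta = 28,
                                 amplitude = 1, seed = NULL) {
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be increasing")
  gv <- function(t, t0, a, b) {
    out <- numeric(length(t))
    u <- (t - t0) / b
    pos <- u > 0
    out[pos] <- (u[pos]^a) * exp(a * (1 - u[pos]))  # peak-normalized gamma-variate
    out
  }
  aif <- function(t) amplitude * gv(t, aif_t0, aif_alpha, aif_beta)
  pif <- function(t) 0.85 * amplitude * gv(t, pif_t0, pif_alpha, pif_beta)
  list(aif = aif, pif = pif,
       aif_samples = aif(times), pif_samples = pif(times), times = times)
}

#' Simulate a tissue concentration curve (dual-input single-compartment)
#'
#' Solves dC/dt = Ka*AIF(t) + Kp*PIF(t) - K2*C(t), C(0) = 0, on a fine
#' internal grid with an exponential trapezoidal integrator (exact for
#' piecewise-linear inputs up to second order), and samples at `times`.
#'
#' @param Ka,Kp,K2 transfer constants (s^-1), all >= 0.
#' @param aif,pif input functions of time, or numeric vectors sampled at
#'   `times` (linearly interpolated internally).
#' @param times output sample times (s).
#' @param fine_dt internal integration step (s).
#' @return numeric concentration curve at `times` (nonnegative).
#' @export
simulate_tissue_curve <- function(Ka, Kp, K2, aif, pif, times, fine_dt = 0.25) {
  if (Ka < 0 || Kp < 0 || K2 < 0) stop("kinetic params must be >= 0")
  t_end <- max(times)
  tg <- seq(0, t_end, by = fine_dt)
  if (tg[length(tg)] < t_end) tg <- c(tg, t_end)
  ev <- function(f) {
    if (is.function(f)) f(tg)
    else stats::approx(times, f, xout = tg, rule = 2)$y
  }
  u <- Ka * ev(aif) + Kp * ev(pif)
  dt <- diff(tg)
  if (length(unique(round(dt, 12))) == 1L) {
    h <- dt[1]
    E <- exp(-K2 * h)
    # C_{n+1} = C_n E + h/2 (u_{n+1} + E u_n)
    b <- (h / 2) * (u[-1] + E * u[-length(u)])
    C <- c(0, as.numeric(stats::filter(b, E, method = "recursive")))
  } else {
    C <- numeric(length(tg))
    for (n in seq_len(length(tg) - 1L)) {
      E <- exp(-K2 * dt[n])
      C[n + 1] <- C[n] * E + (dt[n] / 2) * (u[n + 1] + E * u[n])
    }
  }
  pmax(stats::approx(tg, C, xout = times, rule = 2)$y, 0)
}

# smooth random field in [1-amp, 1+amp], separable Gaussian smoothing
smooth_texture <- function(shape, amp, sigma = 2.5) {
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  x <- gauss_smooth3(x, sigma)
  x <- (x - mean(x)) / max(stats::sd(x), 1e-12)
  1 + amp * x
}

gauss_smooth3 <- function(x, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  sm_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dim(ap)[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate borders
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    ap <- array(out, dim = dim(ap))
    aperm(ap, order(perm))
  }
  for (ax in 1:3) x <- sm_axis(x, ax)
  x
}

sphere_mask <- function(shape, center, radius) {
  dx <- (seq_len(shape[1]) - center[1])^2
  dy <- (seq_len(shape[2]) - center[2])^2
  dz <- (seq_len(shape[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, `+`), dz, `+`)
  array(as.numeric(d2 <= radius^2), dim = shape)
}

#' Generate a pre/post phantom pair with ground truth
#'
#' The pre sequence is parenchymal background plus a spherical tumor whose
#' voxel time-courses follow the dual-input single-compartment model with the
#' class-specific kinetics, modulated by a smooth spatial texture, plus two
#' small vessel boxes carrying the AIF and PIF signals, plus noise. The post
#' sequence applies the class-specific post effect (radius scale and
#' enhancement scale) in the pre frame (perfect registration).
#'
#' @param spec a [phantom_spec()].
#' @return list with `pre`, `post` ([dce_sequence()]s) and `truth` (masks,
#'   class, kinetic parameters, noiseless tissue curves, input functions).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$volume_shape
  if (any(spec$center - spec$radius < 1) || any(spec$center + spec$radius > shp))
    stop("tumor exceeds volume bounds")
  set.seed(derive_seed(spec$seed, "phantom"))
  times <- spec$times
  inp <- make_input_functions(times)
  curve_of <- function(p) simulate_tissue_curve(p[["Ka"]], p[["Kp"]], p[["K2"]],
                                                inp$aif, inp$pif, times)
  c_tum <- curve_of(spec$kinetic_params$tumor)
  c_par <- curve_of(spec$kinetic_params$parenchyma)
  pe <- spec$post_effect[[spec$class_label]]
  r_post <- max(spec$radius * pe[["radius_scale"]], 1.5)
  mask_pre  <- sphere_mask(shp, spec$center, spec$radius)
  mask_post <- sphere_mask(shp, spec$center, r_post)
  tex <- smooth_texture(shp, spec$texture_amp)
  # vessel ROIs: small boxes in a corner carrying the raw input signals
  ves_a <- array(0, shp); ves_a[2:4, 2:4, 2:3] <- 1
  ves_p <- array(0, shp); ves_p[2:4, 6:8, 2:3] <- 1
  bg <- 1 - pmax(mask_pre, pmax(ves_a, ves_p))
  bg_post <- 1 - pmax(mask_post, pmax(ves_a, ves_p))

  build <- function(mask_t, c_t_scale, bg_mask) {
    vols <- vector("list", length(times))
    for (i in seq_along(times)) {
      enh <- bg_mask * c_par[i] + mask_t * c_t_scale[i] +
        ves_a * inp$aif_samples[i] * 2 + ves_p * inp$pif_samples[i] * 2
      s <- spec$s0 * tex * (1 + spec$signal_scale * enh)
      if (spec$noise_sigma > 0) {
        if (isTRUE(spec$rician)) {
          n1 <- array(stats::rnorm(prod(shp), sd = spec$noise_sigma), shp)
          n2 <- array(stats::rnorm(prod(shp), sd = spec$noise_sigma), shp)
          s <- sqrt((s + n1)^2 + n2^2)
        } else {
          s <- s + array(stats::rnorm(prod(shp), sd = spec$noise_sigma), shp)
        }
      }
      vols[[i]] <- s
    }
    vols
  }
  pre_vols  <- build(mask_pre, c_tum, bg)
  post_vols <- build(mask_post, c_tum * pe[["enh_scale"]], bg_post)
  pre <- dce_sequence(pre_vols, times, spacing = spec$spacing, mask = mask_pre,
                      label = spec$class_label, phase_of = "pre",
                      id = sprintf("phantom_%s_%d", spec$class_label, spec$seed))
  post <- dce_sequence(post_vols, times, spacing = spec$spacing, mask = mask_post,
                       label = spec$class_label, phase_of = "post",
                       id = paste0(pre$id, "_post"))
  truth <- list(class = spec$class_label, center = spec$center,
                radius_pre = spec$radius, radius_post = r_post,
                mask_pre = mask_pre, mask_post = mask_post,
                kinetic_params = spec$kinetic_params,
                tumor_curve_pre = c_tum,
                tumor_curve_post = c_tum * pe[["enh_scale"]],
                parenchyma_curve = c_par,
                aif = inp$aif_samples, pif = inp$pif_samples,
                input_functions = inp, spec = spec)
  list(pre = pre, post = post, truth = truth)
}

#' Generate a cohort of phantom pairs
#'
#' Per-sample jitter: tumor center uniform +/- `center_jitter` voxels per
#' axis, radius uniform in `radius_range`, kinetic parameters multiplied by
#' exp(U(-`kinetic_jitter`, `kinetic_jitter`)). Deterministic under `seed`.
#'
#' @param n_per_class samples per viability class (classes V, E, NV).
#' @param base_spec template [phantom_spec()]; class and seed fields are
#'   overridden per sample.
#' @param seed cohort seed.
#' @param center_jitter,radius_range,kinetic_jitter jitter controls.
#' @return list of `list(pre, post, truth)` with classes interleaved.
#' @export
generate_cohort <- function(n_per_class, base_spec = phantom_spec(), seed = 1L,
                            center_jitter = c(4, 4, 1.5),
                            radius_range = c(4.5, 6.5),
                            kinetic_jitter = 0.15) {
  center_jitter <- rep(center_jitter, length.out = 3)
  stopifnot(n_per_class >= 1)
  classes <- c("V", "E", "NV")
  out <- vector("list", 3L * n_per_class)
  idx <- 1L
  for (i in seq_len(n_per_class)) {
    for (cl in classes) {
      sd_i <- derive_seed(seed, "cohort", i, cl)
      set.seed(sd_i)
      sp <- phantom_spec(class_label = cl,
                         volume_shape = base_spec$volume_shape,
                         n_timepoints = base_spec$n_timepoints,
                         times = base_spec$times,
                         spacing = base_spec$spacing,
                         noise_sigma = base_spec$noise_sigma,
                         rician = base_spec$rician,
                         texture_amp = base_spec$texture_amp,
                         post_effect = base_spec$post_effect,
                         s0 = base_spec$s0, signal_scale = base_spec$signal_scale,
                         seed = sd_i)
      ctr <- sp$center + stats::runif(3, -center_jitter, center_jitter)
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      # keep the sphere inside the volume whatever the jitter drew
      rad <- min(rad, min(ctr - 1.5), min(sp$volume_shape - ctr - 0.5))
      kp <- lapply(sp$kinetic_params, function(p)
        p * exp(stats::runif(length(p), -kinetic_jitter, kinetic_jitter)))
      sp$center <- ctr; sp$radius <- rad; sp$kinetic_params <- kp
      out[[idx]] <- generate_pair(sp)
      idx <- idx + 1L
    }
  }
  out
}
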