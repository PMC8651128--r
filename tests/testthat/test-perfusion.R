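test_that("roi_curve averages the ROI voxels per phase", {
  shape <- c(8, 8, 4)
  vols <- lapply(c(1, 2, 3), function(v) array(v, shape))
  seq <- dce_sequence(vols, times = c(0, 10, 20))
  roi <- array(1, shape)
  expect_equal(roi_curve(seq, roi)$curve, c(1, 2, 3))
  # single-voxel ROI returns that voxel's time course
  set.seed(4)
  vols2 <- lapply(1:3, function(i) array(rnorm(prod(shape)), shape))
  seq2 <- dce_sequence(vols2, times = c(0, 10, 20))
  roi1 <- array(0, shape); roi1[3, 5, 2] <- 1
  expect_equal(roi_curve(seq2, roi1)$curve,
               sapply(vols2, function(v) v[3, 5, 2]))
  expect_error(roi_curve(seq2, array(0, shape)), "empty")
})

test_that("non-parametric metrics reproduce hand arithmetic", {
  m <- nonparametric_metrics(c(100, 100, 200, 150), c(0, 10, 20, 30), kappa = 0)
  expect_equal(m$delta_S, 100)
  expect_equal(m$PER, 1.0)
  expect_equal(m$TTP, 20)
  expect_equal(m$wash_out, (50 / 100) / 10)
  expect_equal(m$nMITR, 1.0 / 20)
  # monotone increasing curve: wash-out 0 and flagged
  m2 <- nonparametric_metrics(c(100, 120, 150, 200), c(0, 10, 20, 30))
  expect_equal(m2$wash_out, 0)
  expect_true("monotone_increasing" %in% m2$flags)
  # flat zero curve: all zero with flag
  m3 <- nonparametric_metrics(c(0, 0, 0), c(0, 10, 20))
  expect_equal(m3$delta_S, 0)
  expect_true("flat_zero_curve" %in% m3$flags)
})

test_that("non-parametric metrics agree with an independent re-implementation", {
  # straight-line oracle written directly from the definitions
  oracle <- function(s, t, kappa = 3) {
    s0 <- s[1]; thr <- s0 + kappa * sd(s[1:2])
    ipk <- which.max(s); smax <- s[ipk]; ttp <- t[ipk]
    cand <- which(s > thr); cand <- cand[cand <= ipk]
    t0 <- if (length(cand)) t[cand[1]] else ttp
    ds <- smax - s0; per <- ds / s0
    wi <- if (ttp > t0) per / (ttp - t0) else per / (t[ipk] - t[ipk - 1])
    wo <- if (ipk == length(s)) 0 else ((smax - s[length(s)]) / s0) / (t[length(t)] - ttp)
    c(T0 = t0, TTP = ttp, delta_S = ds, PER = per, nMITR = per / ttp,
      wash_in = wi, wash_out = wo)
  }
  times <- c(10, 60, 100, 145, 320)
  inp <- make_input_functions(times)
  set.seed(8)
  for (r in 1:20) {
    p <- exp(runif(3, log(0.002), log(0.03)))
    C <- simulate_tissue_curve(p[1], p[2], p[3], inp$aif, inp$pif, times)
    s <- 100 * (1 + 1.5 * C)
    m <- nonparametric_metrics(s, times)
    o <- oracle(s, times)
    for (nm in names(o)) expect_equal(m[[nm]], unname(o[nm]), tolerance = 1e-12)
    expect_gte(m$TTP, m$T0)
  }
})

test_that("ratio metrics are invariant to affine intensity rescaling", {
  times <- c(10, 60, 100, 145, 320)
  s <- c(100, 180, 220, 200, 160)
  m1 <- nonparametric_metrics(s, times)
  m2 <- nonparametric_metrics(3.7 * s, times)
  for (nm in c("PER", "nMITR", "wash_in", "wash_out")) {
    expect_equal(m1[[nm]], m2[[nm]], tolerance = 1e-12)
  }
  expect_equal(m2$delta_S, 3.7 * m1$delta_S, tolerance = 1e-12)
})

test_that("kinetic parameters are recovered from noiseless curves", {
  times <- c(seq(5, 150, by = 10), seq(170, 320, by = 30))
  inp <- make_input_functions(times)
  C <- simulate_tissue_curve(0.005, 0.010, 0.008, inp$aif, inp$pif, times)
  fit <- fit_dual_input_model(C, inp$aif, inp$pif, times)
  expect_lt(abs(fit$Ka - 0.005) / 0.005, 0.02)
  expect_lt(abs(fit$Kp - 0.010) / 0.010, 0.02)
  expect_lt(abs(fit$K2 - 0.008) / 0.008, 0.02)
  expect_lt(abs(fit$ART - 1 / 3) / (1 / 3), 0.02)
  expect_lt(abs(fit$DV - 100 * 0.015 / 0.008) / (100 * 0.015 / 0.008), 0.02)
  # portal-only tissue: fitted arterial fraction near zero
  C0 <- simulate_tissue_curve(0, 0.012, 0.01, inp$aif, inp$pif, times)
  fit0 <- fit_dual_input_model(C0, inp$aif, inp$pif, times)
  expect_lt(fit0$ART, 0.05)
  expect_error(fit_dual_input_model(C, rep(0, length(times)),
                                    rep(0, length(times)), times), "degenerate")
})

test_that("collinear inputs flag Ka/Kp unidentifiability but preserve their sum", {
  times <- c(seq(5, 150, by = 10), seq(170, 320, by = 30))
  inp <- make_input_functions(times)
  C <- simulate_tissue_curve(0.004, 0.008, 0.01, inp$aif, inp$aif, times)
  fit <- fit_dual_input_model(C, inp$aif, inp$aif, times)
  expect_true("ka_kp_unidentifiable" %in% fit$flags)
  expect_lt(abs((fit$Ka + fit$Kp) - 0.012) / 0.012, 0.02)
})

test_that("phantom tumor ROI curve matches the ground-truth simulation", {
  sp <- phantom_spec("V", noise_sigma = 0, texture_amp = 0, seed = 6)
  pr <- generate_pair(sp)
  rc <- roi_curve(pr$pre, pr$truth$mask_pre)
  expected <- sp$s0 * (1 + sp$signal_scale * pr$truth$tumor_curve_pre)
  expect_equal(rc$curve, expected, tolerance = 1e-8)
})
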