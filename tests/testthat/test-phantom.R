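test_that("input functions: sharp early arterial bolus, delayed dispersed portal curve", {
  times <- seq(0, 300, by = 1)
  inp <- make_input_functions(times)
  expect_true(all(inp$aif_samples >= 0) && all(inp$pif_samples >= 0))
  expect_lt(times[which.max(inp$aif_samples)], times[which.max(inp$pif_samples)])
  expect_true(all(inp$aif(seq(0, 6, 0.5)) == 0))   # zero before arrival
  expect_true(all(inp$pif(seq(0, 16, 0.5)) == 0))
  z <- make_input_functions(times, amplitude = 0)
  expect_true(all(z$aif_samples == 0) && all(z$pif_samples == 0))
  expect_identical(inp$aif_samples, make_input_functions(times)$aif_samples)
})

test_that("tissue curve solves the dual-input one-compartment ODE", {
  times <- c(10, 60, 100, 145, 320)
  inp <- make_input_functions(seq(0, 320))
  # no input -> identically zero
  expect_equal(simulate_tissue_curve(0, 0, 0.01, inp$aif, inp$pif, times),
               rep(0, 5))
  # K2 = 0, constant AIF = a, Kp = 0 -> C(t) = Ka * a * t
  aif_const <- function(t) rep(2, length(t))
  pif_zero <- function(t) rep(0, length(t))
  C <- simulate_tissue_curve(0.01, 0, 0, aif_const, pif_zero, times)
  expect_equal(C, 0.01 * 2 * times, tolerance = 1e-8)
  expect_error(simulate_tissue_curve(-0.01, 0, 0, aif_const, pif_zero, times),
               ">= 0")
})

test_that("tissue curve matches a fine-step explicit-Euler oracle within 0.1%", {
  times <- seq(5, 320, by = 5)
  inp <- make_input_functions(times)
  params <- list(c(0.005, 0.010, 0.008), c(0.03, 0.004, 0.012), c(0.008, 0.02, 0.02))
  for (p in params) {
    C <- simulate_tissue_curve(p[1], p[2], p[3], inp$aif, inp$pif, times)
    # independent oracle: explicit Euler at a 1000x finer step than the samples
    dt <- 0.005
    tg <- seq(0, 320, by = dt)
    u <- p[1] * inp$aif(tg) + p[2] * inp$pif(tg)
    Ce <- numeric(length(tg))
    for (n in seq_len(length(tg) - 1))
      Ce[n + 1] <- Ce[n] + dt * (u[n] - p[3] * Ce[n])
    Co <- approx(tg, Ce, xout = times)$y
    expect_lt(max(abs(C - Co)) / max(Co), 1e-3)
  }
})

test_that("steady state under constant inputs is (Ka*a + Kp*p)/K2", {
  a <- 1.5; pp <- 0.8
  aif <- function(t) rep(a, length(t)); pif <- function(t) rep(pp, length(t))
  Ka <- 0.004; Kp <- 0.011; K2 <- 0.02
  C <- simulate_tissue_curve(Ka, Kp, K2, aif, pif, times = c(1000, 2000))
  expect_equal(C[2], (Ka * a + Kp * pp) / K2, tolerance = 1e-3)
})

test_that("phantom pairs encode the class-specific post-treatment effect", {
  pr_nv <- generate_pair(phantom_spec("NV", seed = 2))
  expect_lt(sum(pr_nv$post$mask), sum(pr_nv$pre$mask))
  pr_v <- generate_pair(phantom_spec("V", seed = 2))
  expect_gte(sum(pr_v$post$mask), sum(pr_v$pre$mask))
  # class-conditional post-treatment peak enhancement ordering NV < E < V
  pk <- sapply(c("NV", "E", "V"), function(cl)
    max(generate_pair(phantom_spec(cl, seed = 7))$truth$tumor_curve_post))
  expect_true(pk["NV"] < pk["E"] && pk["E"] < pk["V"])
  # zero noise + identity post effect -> voxelwise equality
  ident <- list(V = c(radius_scale = 1, enh_scale = 1),
                E = c(radius_scale = 1, enh_scale = 1),
                NV = c(radius_scale = 1, enh_scale = 1))
  pr <- generate_pair(phantom_spec("E", noise_sigma = 0, post_effect = ident, seed = 3))
  for (i in seq_along(pr$pre$volumes))
    expect_equal(pr$pre$volumes[[i]], pr$post$volumes[[i]])
  expect_error(generate_pair(phantom_spec("V", center = c(2, 2, 2), radius = 6)),
               "bounds")
})

test_that("cohorts are reproducible and class-balanced; zero jitter collapses to the base spec", {
  co <- generate_cohort(2, phantom_spec(volume_shape = c(16L, 16L, 8L),
                                        radius = 3, n_timepoints = 3L,
                                        times = c(10, 60, 100)),
                        seed = 9, center_jitter = 0, radius_range = c(3, 3),
                        kinetic_jitter = 0)
  expect_length(co, 6)
  labs <- sapply(co, function(s) s$pre$label)
  expect_equal(sort(table(labs)), sort(table(c("V", "V", "E", "E", "NV", "NV"))),
               ignore_attr = TRUE)
  co2 <- generate_cohort(2, phantom_spec(volume_shape = c(16L, 16L, 8L),
                                         radius = 3, n_timepoints = 3L,
                                         times = c(10, 60, 100)),
                         seed = 9, center_jitter = 0, radius_range = c(3, 3),
                         kinetic_jitter = 0)
  expect_identical(co[[1]]$pre$volumes, co2[[1]]$pre$volumes)
  # zero jitter: same-class samples share the ground-truth curve exactly
  v_idx <- which(labs == "V")
  expect_equal(co[[v_idx[1]]]$truth$tumor_curve_pre,
               co[[v_idx[2]]]$truth$tumor_curve_pre)
})

test_that("phantom classes are separable by a linear probe on true mean curves", {
  co <- generate_cohort(10, phantom_spec(), seed = 31)
  curves <- t(sapply(co, function(s) s$truth$tumor_curve_pre))
  labs <- factor(sapply(co, function(s) s$truth$class))
  fit <- MASS::lda(curves, grouping = labs)
  acc <- mean(predict(fit)$class == labs)
  expect_gt(acc, 0.9)
})
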