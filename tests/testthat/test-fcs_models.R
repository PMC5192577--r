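test_that("diffusion ACF model has the standard structure and limits", {
  foc <- focus_model(200, 1000)
  tau <- 10^seq(-5, 0, by = 0.25)
  # no blinking: prefactor is exactly 1/N
  g <- diffusion_acf(tau, N = 4, tau_D = 1e-3, focus = foc)
  expect_equal(diffusion_acf(0, N = 4, tau_D = 1e-3, focus = foc), 1 / 4)
  expect_true(all(diff(g) < 0))
  # blinking factor multiplies in
  gb <- diffusion_acf(tau, N = 4, tau_D = 1e-3, theta_T = 0.2,
                      tau_T = 1e-4, focus = foc)
  blink <- 1 - 0.2 + 0.2 * exp(-tau / 1e-4)
  expect_equal(gb, g * blink, tolerance = 1e-12)
  expect_error(diffusion_acf(tau, N = 1, tau_D = 1e-3, alpha = 3))
})

test_that("noiseless diffusion curves are recovered to high precision", {
  foc <- focus_model(200, 1000)
  tau <- lag_grid(1e-5, 0.1)
  g <- diffusion_acf(tau, N = 2, tau_D = 5e-4, alpha = 1, focus = foc)
  fit <- fit_diffusion(make_cf(tau, g, dt = 1e-5), foc)
  expect_equal(coef(fit)$N, 2, tolerance = 1e-6)
  expect_equal(coef(fit)$tau_D, 5e-4, tolerance = 1e-6)
  expect_equal(coef(fit)$alpha, 1, tolerance = 1e-6)
  expect_equal(coef(fit)$D, (0.2)^2 / (4 * 5e-4), tolerance = 1e-6)
})

test_that("every relaxation term is positive at zero, monotone, and vanishing", {
  foc <- focus_model(200, 1000)
  sp <- mode_spectrum(297)
  tau <- c(0, 10^seq(-4, 1, by = 0.1), 1e4)
  for (p in c(1L, 5L, 20L)) {
    one <- chromodyn:::.relax_term(tau, sp$tau_p[p], sp$a_p[p], foc$w_0,
                                   foc$kappa)
    expect_gt(one[1], 0)
    expect_true(all(diff(one) <= 1e-15))
    expect_lt(abs(one[length(one)]), 1e-12)
  }
  g <- relaxation_acf(tau, sp, foc)
  expect_gt(g[1], 0)
  expect_true(all(diff(g) <= 1e-15))
  expect_lt(abs(g[length(g)]), 1e-12)
})

test_that("noiseless composite curves are recovered exactly", {
  foc <- focus_model(200, 1000); env <- physical_environment()
  sp <- mode_spectrum(rg_from_relaxation(0.161, env = env)$R_g, env = env)
  tau <- lag_grid(2e-4, 2)
  g <- 0.08 * diffusion_acf(tau, 1, 8e-4, 1, focus = foc) +
    0.5 * relaxation_acf(tau, sp, foc)
  fit <- fit_relaxation(make_cf(tau, g, dt = 2e-4), focus = foc, env = env,
                        baseline = "none")
  expect_equal(coef(fit)$tau_1, 0.161, tolerance = 1e-6)
  expect_equal(fit$R_g, 297, tolerance = 1e-3)
  expect_equal(coef(fit)$B, 0.5, tolerance = 1e-5)
  expect_equal(coef(fit)$A_D, 0.08, tolerance = 1e-4)
  # halving the mode truncation changes tau_1 by < 2%
  fit_half <- fit_relaxation(make_cf(tau, g, dt = 2e-4), focus = foc,
                             env = env, p_max = 16, baseline = "none")
  expect_lt(abs(coef(fit_half)$tau_1 - coef(fit)$tau_1) /
              coef(fit)$tau_1, 0.02)
})

test_that("the fitted spectrum yields the segment MSD", {
  foc <- focus_model(200, 1000); env <- physical_environment()
  sp <- mode_spectrum(rg_from_relaxation(0.161, env = env)$R_g, env = env)
  tau <- lag_grid(2e-4, 2)
  g <- 0.4 * relaxation_acf(tau, sp, foc)
  fit <- fit_relaxation(make_cf(tau, g, dt = 2e-4), focus = foc, env = env,
                        include_diffusion = FALSE, baseline = "none")
  msd <- msd_from_fit(fit, c(0, 0.01, 0.1, 1))
  expect_equal(msd$msd[1], 0)
  expect_equal(msd$plateau, 2 * sum(fit$spectrum$a_p), tolerance = 1e-9)
  # matches the directly computed MSD of the generating spectrum
  truth <- segment_msd(sp, c(0, 0.01, 0.1, 1))
  expect_equal(msd$msd, truth$msd, tolerance = 0.01)
})

test_that("simulated free diffusion at the cytoplasmic mobility is recovered", {
  foc <- focus_model(200, 1000)
  tr <- simulate_diffusion_trace(D = 20, focus = foc, concentration = 10,
                                 duration = 30, seed = 5)
  fit <- fit_diffusion(correlate(tr, window = 1), foc)
  expect_lt(abs(coef(fit)$D - 20) / 20, 0.10)
})

test_that("end-to-end OU recovery holds over relaxation times and seeds", {
  # generate -> correlate -> window scan -> fit for tau_1 in {80, 160,
  # 300} ms on 60-s traces. A single trace of length T carries limited
  # information about a correlation time tau_1 (relative sd of order
  # sqrt(tau_1/T) ~ 10-13% here), so the per-trace distribution is
  # checked at its noise floor — median error under 15%, at least 80% of
  # QC-valid traces within ~25% — while the acceptance suite checks the
  # repeated-measurement mean at 15%.
  foc <- focus_model(200, 1000); env <- physical_environment()
  errs <- c()
  for (tau_1 in c(0.08, 0.16, 0.30)) {
    R_g <- rg_from_relaxation(tau_1, env = env)$R_g
    sp <- mode_spectrum(R_g, env = env, p_max = 8)
    for (s in 1:2) {
      tr <- simulate_ou_trace(sp, foc, n_emitters = 2000,
                              brightness = 4e3, duration = 60,
                              seed = 400 + s)
      sc <- window_scan(tr, c(1, 2, 3, 5, 8, 12), "relaxation",
                        focus = foc, env = env, p_max = 8,
                        include_diffusion = FALSE)
      if (!sc$valid) next
      errs <- c(errs, abs(coef(sc$fit)$tau_1 - tau_1) / tau_1)
    }
  }
  expect_gte(length(errs), 5)
  expect_lt(median(errs), 0.15)
  expect_gte(mean(errs < 0.26), 0.8)
})

test_that("co-moving dual labels cross-correlate; independent ones do not", {
  foc <- focus_model(200, 1000)
  sp <- mode_spectrum(250, p_max = 4)
  tr <- simulate_ou_trace(sp, foc, duration = 30, seed = 61, channels = 2)
  g11 <- correlate(tr, 3, channels = c(1L, 1L))
  g22 <- correlate(tr, 3, channels = c(2L, 2L))
  g12 <- correlate(tr, 3, channels = c(1L, 2L))
  small <- g12$lags <= 0.05
  expect_true(all(g12$G[small] >
                    0.5 * sqrt(g11$G[small] * g22$G[small])))
  # two independent traces: no cross-correlation
  tr_a <- simulate_ou_trace(sp, foc, duration = 30, seed = 62)
  tr_b <- simulate_ou_trace(sp, foc, duration = 30, seed = 63)
  tri <- fcs_trace(cbind(tr_a$counts, tr_b$counts), tr_a$dt)
  gx <- correlate(tri, 3, channels = c(1L, 2L))
  expect_true(all(abs(gx$G[gx$lags <= 0.05]) <
                    0.5 * sqrt(g11$G[small] * g22$G[small])))
})
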