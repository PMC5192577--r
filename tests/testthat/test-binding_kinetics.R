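test_that("steady-state rate algebra reproduces the published rate table", {
  het <- het_binding()
  expect_equal(het$k_on, 3.3, tolerance = 0.1 / 3.3)
  expect_equal(het$k_switch, 33e-3, tolerance = 0.05)
  eu <- eu_binding()
  expect_equal(eu$k_on, 4.0, tolerance = 0.1 / 4.0)
  expect_equal(eu$k_switch, 16e-3, tolerance = 0.05)
  # no long-lived state -> no switching
  none <- steady_state_rates(0.2, 0.8, 0, 1, 0.01)
  expect_equal(none$k_switch, 0)
  expect_error(steady_state_rates(0, 0.5, 0.5, 1, 0.01))
})

test_that("steady-state rates are the exact stationary point of the scheme ODEs", {
  skip_if_not_installed("deSolve")
  for (bp in list(het_binding(), eu_binding())) {
    rhs <- function(t, y, p) {
      with(as.list(c(y, p)), list(c(
        free = -k_on * free + k_off1 * short + k_off2 * long,
        short = k_on * free - (k_off1 + k_switch) * short,
        long = k_switch * short - k_off2 * long)))
    }
    y0 <- c(free = bp$f_free, short = bp$f_short, long = bp$f_long)
    out <- deSolve::ode(y0, c(0, 500, 1000), rhs,
                        p = unlist(bp[c("k_on", "k_off1", "k_switch",
                                        "k_off2")]),
                        rtol = 1e-12, atol = 1e-14)
    final <- out[nrow(out), c("free", "short", "long")]
    expect_equal(as.numeric(final), as.numeric(y0), tolerance = 1e-10)
  }
})

test_that("residence times match the published scales and limits", {
  het <- het_binding()
  rt <- residence_times(het)
  expect_equal(rt$t_short, 1 / 1.05, tolerance = 1e-12)       # ~1 s
  expect_equal(1 / 8.8e-3, 113.6, tolerance = 1e-3)           # ~2 min
  # untreated eu/het average of the mean bound time is ~4 s
  t_mean_avg <- mean(c(residence_times(het)$t_mean,
                       residence_times(eu_binding())$t_mean))
  expect_equal(t_mean_avg, 4, tolerance = 0.25)
  # k_switch -> 0: t_mean -> t_short
  b0 <- binding_params(0.1, 0.9, 0, k_off1 = 1, k_switch = 0,
                       k_off2 = 0.01)
  expect_equal(residence_times(b0)$t_mean, 1)
  # k_switch >> k_off1: t_mean -> 1/(k_off1+k_switch) + t_long
  b1 <- binding_params(0.1, 0.1, 0.8, k_off1 = 1e-6, k_switch = 1e3,
                       k_off2 = 0.01)
  expect_equal(residence_times(b1)$t_mean, 1e-3 + 100, tolerance = 1e-6)
  expect_error(residence_times(binding_params(1, 0, 0, k_off1 = 0,
                                              k_switch = 0, k_off2 = 0)))
})

test_that("strip-profile regression returns slope/2 with faithful noiseless limit", {
  truth_D <- 0.01
  ser <- simulate_frap("strip", het_binding(), D_app = truth_D, seed = 71,
                       noise_sd = 0)
  fit <- fit_strip_profiles(ser)
  expect_equal(fit$D_app, truth_D, tolerance = 1e-4)
  # D = 0 gives a flat width series and zero slope
  ser0 <- simulate_frap("strip", het_binding(), D_app = 0, seed = 72,
                        noise_sd = 0)
  expect_lt(abs(fit_strip_profiles(ser0)$D_app), 1e-8)
  expect_true(all(abs(apply(ser0$profiles, 2, which.min) -
                        which.min(abs(ser0$positions))) <= 1))
})

test_that("strip-FRAP regression CI covers the truth for typical noise", {
  hits <- vapply(1:10, function(s) {
    ser <- simulate_frap("strip", het_binding(), D_app = 0.01,
                         seed = 700 + s, noise_sd = 0.01)
    ci <- fit_strip_profiles(ser)$ci
    ci[1] <= 0.01 && 0.01 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("integrated recovery fit identifies fractions and slow dissociation", {
  bp <- het_binding()
  ser <- simulate_frap("strip", bp, D_app = 0.01, seed = 73,
                       times = seq(0, 300, by = 2), noise_sd = 0)
  fit <- fit_recovery(ser$recovery, h = ser$h, sigma_0 = ser$sigma_0)
  cfs <- coef(fit)
  expect_equal(cfs$f_slow, bp$f_long, tolerance = 1e-3)
  expect_equal(cfs$f_mobile, bp$f_short, tolerance = 1e-3)
  expect_equal(cfs$k_off2, bp$k_off2, tolerance = 1e-3)
  # noisy recovery: free fraction and k_off2 within 20%
  bp2 <- steady_state_rates(6, 18, 76, 1.05, 8.8e-3)
  ser2 <- simulate_frap("strip", bp2, D_app = 0.01, seed = 74,
                        times = seq(0, 600, by = 2), noise_sd = 0.005)
  cf2 <- coef(fit_recovery(ser2$recovery, h = ser2$h,
                           sigma_0 = ser2$sigma_0))
  expect_lt(abs(cf2$f_free - 0.06) / 0.06, 0.2)
  expect_lt(abs(cf2$k_off2 - 8.8e-3) / 8.8e-3, 0.2)
  # all-free molecules: flat unity recovery
  free_only <- list(times = seq(0, 10, by = 0.5),
                    intensity = rep(1, 21))
  expect_equal(
    chromodyn:::.recovery_model(free_only$times, B = 1, f_slow = 0,
                                f_mobile = 0, D_app = 0.01,
                                k_off2 = 0.01, h = 1, sigma_0 = 0.5),
    rep(1, 21))
})

test_that("CP fitting separates the two binding states", {
  bp <- het_binding()
  # k_b = 0: no bleaching, flat curve
  flat <- chromodyn:::.cp_model(seq(0, 100, 1), bp$f_free, bp$f_short,
                                bp$f_long, bp$k_off1, bp$k_off2, 0)
  expect_true(all(abs(flat - 1) < 1e-12))
  # long-time asymptote
  t_inf <- chromodyn:::.cp_model(1e8, bp$f_free, bp$f_short, bp$f_long,
                                 bp$k_off1, bp$k_off2, k_b = 0.5)
  expect_equal(t_inf,
               bp$f_free + bp$f_short * bp$k_off1 / (bp$k_off1 + 0.5) +
                 bp$f_long * bp$k_off2 / (bp$k_off2 + 0.5),
               tolerance = 1e-12)
  # noisy round trip: heterochromatin k_off1 within 20% (sampling must
  # resolve the ~1/s state, so the early decay is recorded densely)
  bp3 <- steady_state_rates(6, 18, 76, 1.05, 8e-3)
  cp <- simulate_cp(bp3, k_b = 0.5, seed = 75,
                    times = c(seq(0, 20, by = 0.02),
                              seq(20.5, 600, by = 0.5)),
                    noise_sd = 0.003)
  fit <- fit_cp(cp, k_b = 0.5)
  expect_lt(abs(coef(fit)$k_off1 - 1.05) / 1.05, 0.2)
  expect_lt(abs(coef(fit)$k_off2 - 8e-3) / 8e-3, 0.35)
})

test_that("global point-FRAP fit shares rates across bleach durations", {
  bp <- steady_state_rates(6, 31, 63, 0.83, 8.2e-3)
  curves <- simulate_frap("point", bp, seed = 76,
                          times = seq(0, 400, by = 1),
                          bleach_durations = c(0.1, 0.3, 1, 3),
                          noise_sd = 0.004)
  fit <- fit_point_frap(curves)
  expect_lt(abs(fit$k_fast - 0.83) / 0.83, 0.25)
  expect_lt(abs(fit$k_slow - 8.2e-3) / 8.2e-3, 0.25)
  expect_equal(nrow(fit$amplitudes), 4L)
  expect_error(fit_point_frap(curves[1:2]), "3")
  # zero-duration bleach produces a flat curve that is handled
  curves0 <- simulate_frap("point", bp, seed = 77,
                           bleach_durations = c(0, 1, 3), noise_sd = 0)
  expect_true(all(abs(curves0[[1]]$intensity - 1) < 1e-9))
  expect_s3_class(fit_point_frap(curves0), "point_frap_fit")
})
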