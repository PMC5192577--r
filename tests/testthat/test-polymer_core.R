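test_that("gyration radius follows the closed forms of all four conformations", {
  expect_equal(gyration_radius(polymer_params("blob", L = 600, l_p = 2)), 20)
  # a one-loop theta rosette halves the squared blob size
  expect_equal(
    gyration_radius(polymer_params("loop_rosette", L = 600, l_p = 2, f = 1)),
    20 / sqrt(2))
  expect_equal(
    gyration_radius(polymer_params("loop_rosette", L = 12800, l_p = 100,
                                   f = 9)),
    sqrt(12800 * 100 / 6 * 17 / 81), tolerance = 1e-12)
  expect_equal(
    gyration_radius(polymer_params("globule", L = 1000, l_p = 50)),
    sqrt(1000^(2 / 3) * 50^(4 / 3) / 1.76))
  expect_equal(
    gyration_radius(polymer_params("loop_rosette", L = 1000, l_p = 50,
                                   f = 3, solvent = "good")),
    sqrt(1000^(6 / 5) * 50^(4 / 5) / 9.59 * (1.92 * 3 - 0.92) /
           3^(11 / 5)))
  expect_error(polymer_params("loop_rosette", L = -1, l_p = 2))
  expect_error(polymer_params("loop_rosette", L = 1, l_p = 2, f = 0))
})

test_that("theta-rosette gyration radius matches sampled ideal Gaussian rosettes", {
  # oracle: f Gaussian loops (Brownian bridges with segment variance
  # 2 l_p * contour) sharing a common base
  L <- 12800; l_p <- 100; f <- 9
  set.seed(101)
  m <- 60
  ell <- L / f
  rg2 <- replicate(600, {
    pts <- do.call(rbind, lapply(seq_len(f), function(k) {
      g <- matrix(rnorm(3 * m, sd = sqrt(2 * l_p * ell / (3 * m))), m, 3)
      w <- apply(g, 2, cumsum)
      w - outer(seq_len(m) / m, colSums(g))   # bridge back to the base
    }))
    mean(rowSums(sweep(pts, 2, colMeans(pts))^2))
  })
  expect_equal(mean(rg2),
               gyration_radius(polymer_params("loop_rosette", L = L,
                                              l_p = l_p, f = f))^2,
               tolerance = 0.05)
})

test_that("mode spectra obey the printed prefactors and power laws", {
  env <- physical_environment()
  sp <- mode_spectrum(297, "loop_rosette", "theta", env)
  expect_equal(sp$tau_p[2] / sp$tau_p[1], 2^(-3 / 2))
  expect_equal(sp$a_p[1], 0.152 * 297^2)
  expect_equal(sp$a_p / sp$a_p[1], (seq_len(sp$p_max))^-2, tolerance = 1e-12)
  expect_true(all(diff(sp$tau_p) < 0) && all(diff(sp$a_p) < 0))
  # globule: tau_p = tau_1 / p
  spg <- mode_spectrum(297, "globule", env = env)
  expect_equal(spg$tau_p[3], spg$tau_p[1] / 3)
  # good solvent exponents
  spq <- mode_spectrum(297, "loop_rosette", "good", env)
  expect_equal(spq$tau_p / spq$tau_p[1], seq_len(spq$p_max)^(-17 / 20),
               tolerance = 1e-12)
  expect_equal(spq$a_p / spq$a_p[1], seq_len(spq$p_max)^(-9 / 4),
               tolerance = 1e-12)
  # default truncation: smallest p with a_p/a_1 < 1e-3, capped at 50
  expect_equal(sp$p_max, 32L)
  expect_equal(mode_spectrum(297, "globule", env = env)$p_max, 50L)
  expect_error(mode_spectrum(297, p_max = 0))
})

test_that("relaxation-time inversion reproduces the measured domain sizes", {
  # eta_s is calibrated on the euchromatin theta pair (161 ms, 297 nm)
  expect_equal(rg_from_relaxation(0.161)$R_g, 297, tolerance = 1e-3)
  expect_equal(rg_from_relaxation(0.088)$R_g, 243, tolerance = 0.01)
  expect_equal(rg_from_relaxation(0.191, solvent = "good")$R_g, 359,
               tolerance = 0.01)
  expect_equal(rg_from_relaxation(0.191, "globule")$R_g, 298,
               tolerance = 0.01)
  # round trip: spectrum of the inverted radius returns tau_1
  for (tag in list(c("loop_rosette", "theta"), c("loop_rosette", "good"),
                   c("globule", "theta"), c("blob", "theta"))) {
    g <- rg_from_relaxation(0.1, tag[1], tag[2])
    sp <- mode_spectrum(g$R_g, tag[1], tag[2])
    expect_equal(sp$tau_p[1], 0.1, tolerance = 1e-10)
  }
})

test_that("genomic content reproduces the published intervals", {
  het <- chromatin_calibration(rel_density = 1.56)
  eu <- chromatin_calibration(rel_density = 0.91)
  gc_het <- genomic_content(list(R_g = 245), het)
  expect_equal(gc_het / 1e6, c(0.80, 1.12), tolerance = 0.01)
  gc_eu <- genomic_content(list(R_g = 297), eu)
  expect_equal(gc_eu / 1e6, c(0.83, 1.16), tolerance = 0.01)
  zero <- genomic_content(list(R_g = 245),
                          chromatin_calibration(c_nuc = c(0, 0),
                                                rel_density = 1))
  expect_equal(zero, c(0, 0))
})

test_that("segment MSD is confined diffusion approaching 2*sum(a_p)", {
  sp <- mode_spectrum(297, p_max = 5000)
  msd <- segment_msd(sp, c(0, 10^seq(-4, 2, by = 0.25)))
  expect_equal(msd$msd[1], 0)
  expect_true(all(diff(msd$msd) >= 0))
  expect_true(all(diff(msd$msd[msd$times < 1]) > 0))
  expect_true(all(msd$msd <= msd$plateau + 1e-9))
  # exact series: plateau -> 2 * 0.152 * zeta(2) * R_g^2 = 0.500 R_g^2
  expect_equal(msd$plateau, 2 * 0.152 * pi^2 / 6 * 297^2, tolerance = 1e-3)
})

test_that("parameter surface inverts the gyration-radius branches", {
  calib <- chromatin_calibration()
  # blob: l_p = 3 R_g^2 / L, independent of f
  tb <- parameter_surface(200, 1e6, calib, "blob",
                          density_grid = c(2, 4))
  L <- 1e6 / (2 * 191 / 11)
  expect_equal(tb$l_p[tb$density == 2], 3 * 200^2 / L)
  # theta rosette: l_p strictly increasing in f at fixed density
  tt <- parameter_surface(297, 1e6, calib, "loop_rosette", "theta",
                          f_grid = 1:12, density_grid = 4.5)
  expect_true(all(diff(tt$l_p) > 0))
  # closed-form inversion at the printed density/loop combination
  row9 <- tt[tt$f == 9, ]
  expect_equal(row9$l_p, 197, tolerance = 0.01)
  expect_true(is.logical(tt$plausible))
})

test_that("cross-model geometry is mutually consistent after one calibration", {
  # with eta fixed by (161 ms, 297 nm, theta), all other Table rows follow
  env <- physical_environment()
  pred <- c(rg_from_relaxation(0.088, env = env)$R_g,
            rg_from_relaxation(0.091, env = env)$R_g,
            rg_from_relaxation(0.191, solvent = "good", env = env)$R_g,
            rg_from_relaxation(0.191, "globule", env = env)$R_g)
  expect_equal(pred, c(243, 245, 359, 298), tolerance = 0.01)
})
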