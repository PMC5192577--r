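test_that("domain extraction masks the diagonal band as missing", {
  m <- matrix(0.2, 100, 100); diag(m) <- 1
  map <- contact_map(m, 2500, 0)
  dm <- extract_domain(map, c(0, 250000), diag_mask_halfwidth = 30000)
  d <- abs(row(dm$matrix) - col(dm$matrix))
  expect_true(all(is.na(dm$matrix[d <= 12])))     # 30 kb = 12 bins
  expect_true(all(!is.na(dm$matrix[d > 12])))
  dm0 <- extract_domain(map, c(0, 250000), diag_mask_halfwidth = 0)
  expect_true(all(is.na(diag(dm0$matrix))))
  expect_true(all(!is.na(dm0$matrix[abs(row(dm0$matrix) -
                                          col(dm0$matrix)) == 1])))
  expect_error(extract_domain(map, c(0, 500000)), "outside")
})

test_that("global and local projections average max and mean as specified", {
  m <- matrix(0.2, 60, 60)
  map <- extract_domain(contact_map(m, 2500, 0), diag_mask_halfwidth = 0)
  prof <- global_profile(map)
  expect_equal(length(prof$values), 60L)
  expect_true(all(abs(prof$values - 0.2) < 1e-12))
  # a single bright pixel dominates the max component of both its columns
  m2 <- m; m2[10, 40] <- m2[40, 10] <- 0.9
  p2 <- global_profile(extract_domain(contact_map(m2, 2500, 0),
                                      diag_mask_halfwidth = 0))
  expect_equal(which(p2$values == max(p2$values)), c(10L, 40L))
  expect_equal(max(p2$values), (0.9 + mean(m2[-40, 40])) / 2)
  # local projection: constant map -> constant profile
  lp <- local_projection(map, anchor = 75000)
  expect_true(all(abs(lp$values[!is.na(lp$values)] - 0.2) < 1e-12))
  expect_error(local_projection(map, anchor = 1e9))
  # fully masked band is rejected
  allna <- contact_map(matrix(0.5, 30, 30), 2500, 0)
  allna <- extract_domain(allna, diag_mask_halfwidth = 200000)
  expect_error(local_projection(allna, anchor = 37500), "masked")
})

test_that("parabolic peak detection finds bumps, merges and thresholds", {
  pos <- (0:199) * 2500
  flat <- structure(list(positions = pos, values = rep(1, 200),
                         provenance = list(kind = "global", anchor = NA)),
                    class = "map_profile")
  expect_length(detect_peaks(flat), 0)
  # single Gaussian bump (sigma 10 kb, height 5x mean) at 300 kb
  bump <- 1 + 5 * exp(-(pos - 3e5)^2 / (2 * 1e4^2))
  pb <- structure(list(positions = pos, values = bump,
                       provenance = list(kind = "global", anchor = NA)),
                  class = "map_profile")
  pk <- detect_peaks(pb)
  expect_length(pk, 1)
  expect_lt(abs(pk - 3e5), 5000)
  # two bumps 20 kb apart merge into one call (sub-window separation)
  two <- 1 + 5 * exp(-(pos - 3e5)^2 / (2 * 6e3^2)) +
    4 * exp(-(pos - 3.2e5)^2 / (2 * 6e3^2))
  pt <- structure(list(positions = pos, values = two,
                       provenance = list(kind = "global", anchor = NA)),
                  class = "map_profile")
  expect_length(detect_peaks(pt), 1)
  # raising the threshold never adds peaks
  set.seed(12)
  noisy <- structure(list(positions = pos,
                          values = bump + rnorm(200, sd = 0.3),
                          provenance = list(kind = "global", anchor = NA)),
                     class = "map_profile")
  n_low <- length(detect_peaks(noisy, threshold_frac = 0.5))
  n_high <- length(detect_peaks(noisy, threshold_frac = 1.2))
  expect_lte(n_high, n_low)
  expect_error(detect_peaks(flat, fit_window = 1e9), "window")
})

test_that("loop-base calling recovers planted rosette bases in both directions", {
  map <- simulate_contact_map(planted_rosette_config(),
                              n_conformations = 60, seed = 11)
  truth <- generator_truth(map)$loop_bases
  expect_length(truth, 5)          # 4 loops -> 5 boundary coordinates
  dm <- extract_domain(map, diag_mask_halfwidth = 30000)
  calls <- call_loop_bases(dm)
  expect_true(all(calls$site_i < calls$site_j))
  sites <- unique(c(calls$site_i, calls$site_j))
  hits <- vapply(truth, function(b) any(abs(sites - b) <= 30000),
                 logical(1))
  expect_gte(mean(hits), 0.7)
  expect_true(any(calls$confidence == "high"))
  # determinism: identical map -> identical calls
  expect_identical(calls, call_loop_bases(dm))
})

test_that("globular domains yield no reproducible high-confidence loop calls", {
  # dense-phase configurations decorrelate slowly, so globular ensembles
  # use a deep equilibration/spacing schedule; residual speckle pairs are
  # sampling artifacts and must neither exceed the noise floor nor recur
  # between independent runs
  calls <- lapply(c(13, 14), function(s) {
    map <- simulate_contact_map("lin(75) - dom(300)[glob(300)] - lin(75)",
                                n_conformations = 80, seed = s,
                                equil_sweeps = 1e6, sweeps_between = 5e4)
    dm <- extract_domain(map, c(75000, 375000),
                         diag_mask_halfwidth = 30000)
    subset(call_loop_bases(dm), confidence == "high")
  })
  n_high <- vapply(calls, nrow, integer(1))
  expect_lte(mean(n_high), 1)
  if (all(n_high > 0)) {
    recur <- outer(seq_len(n_high[1]), seq_len(n_high[2]),
                   Vectorize(function(i, j)
                     abs(calls[[1]]$site_i[i] - calls[[2]]$site_i[j]) < 3e4 &&
                     abs(calls[[1]]$site_j[i] - calls[[2]]$site_j[j]) < 3e4))
    expect_false(any(recur))
  }
})

test_that("planted loop-base truth lists the loop boundaries", {
  lb <- loop_base_coords(rosette_1300_config())
  expect_length(lb, 11)            # 10 loops -> 11 boundaries
  expect_equal(lb[1], 0)
  expect_equal(lb[11], 1290 * 1000, tolerance = 0.01)
})
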