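test_that("domain-configuration grammar parses, validates and round-trips", {
  cfg <- parse_domain_config("lin(100)")
  expect_equal(length(cfg$elements), 1L)
  expect_equal(nrow(build_initial_chain(cfg)$coords), 40L)  # 100 kb / 2.5 kb

  full <- parse_domain_config(example_rosette_config())
  doms <- vapply(full$elements, function(e) e$type == "dom", logical(1))
  expect_equal(sum(doms), 4L)
  expect_equal(total_kb(full), 5000, tolerance = 0.005)
  beads <- nrow(build_initial_chain(full)$coords)
  expect_equal(beads, 2000, tolerance = 0.005)

  # declared dom size must match its content
  expect_error(parse_domain_config("dom(1000)[loop(600)]"), "mismatch")
  expect_error(parse_domain_config("lin(abc)"), "parse error")
  expect_error(parse_domain_config("dom(100)[loop(50) - glob(50)]"))

  # canonical serialization round-trips
  txt <- format_domain_config(full)
  expect_equal(format_domain_config(parse_domain_config(txt)), txt)
  expect_equal(n_variants(full), 5L)
})

test_that("initial chains satisfy all lattice invariants", {
  ch <- build_initial_chain("dom(500)[loop(500)]")
  expect_equal(nrow(ch$coords), 200L)
  d <- abs(ch$coords[1, ] - ch$coords[200, ])
  expect_true(max(d) == 1L)           # loop closure: first/last adjacent
  expect_silent(validate_chain(ch))
  # deterministic layout
  ch2 <- build_initial_chain("dom(500)[loop(500)]")
  expect_identical(ch$coords, ch2$coords)
  # occupancy: no collisions anywhere in a mixed config
  mix <- build_initial_chain(
    "lin(50) - dom(250)[loop(100) - loop(150)] - dom(200)[glob(200)] - lin(50)")
  expect_silent(validate_chain(mix))
  expect_true(any(mix$conf_group >= 0))   # glob beads are confined
})

test_that("Monte Carlo preserves invariants and mixes", {
  ch <- build_initial_chain(planted_rosette_config())
  out <- mc_equilibrate(ch, n_sweeps = 2000, seed = 4)
  expect_silent(validate_chain(out))
  st <- attr(out, "mc_stats")
  expect_true(st$acceptance > 0 && st$acceptance < 1)
  expect_false(identical(ch$coords, out$coords))
  # loop closures intact after many sweeps
  for (k in seq_len(nrow(out$loops))) {
    d <- abs(out$coords[out$loops[k, 1], ] - out$coords[out$loops[k, 2], ])
    expect_true(max(d) == 1L)
  }
  # same seed -> bit-identical coordinates
  again <- mc_equilibrate(build_initial_chain(planted_rosette_config()),
                          n_sweeps = 2000, seed = 4)
  expect_identical(out$coords, again$coords)
})

test_that("phantom linear chains reproduce the ideal-chain gyration radius", {
  # <Rg^2> = N b^2 / 6 with b = sqrt(2) a (the exact lattice bond
  # distribution gives <b^2> = 27/13 a^2, 3.8% above 2 a^2)
  ens <- sample_ensemble("lin(1000)", n_conformations = 600,
                         sweeps_between = 150, equil_sweeps = 5000,
                         seed = 7, self_avoiding = FALSE)
  st <- chain_statistics(ens)
  ideal <- 400 * 2 * 30^2 / 6
  expect_equal(mean(st$rg^2), ideal, tolerance = 0.05)
})

test_that("self-avoidance swells the chain", {
  ph <- sample_ensemble("lin(1000)", n_conformations = 150,
                        sweeps_between = 300, equil_sweeps = 4000,
                        seed = 8, self_avoiding = FALSE)
  sa <- sample_ensemble("lin(1000)", n_conformations = 40,
                        sweeps_between = 1000, equil_sweeps = 8000,
                        seed = 8, self_avoiding = TRUE)
  expect_gt(mean(chain_statistics(sa)$rg^2),
            mean(chain_statistics(ph)$rg^2) * 1.2)
})

test_that("rosette size decreases with loop number at fixed total length", {
  rg_f <- vapply(c(2, 8), function(f) {
    loops <- paste(rep(sprintf("loop(%g)", 400 / f), f), collapse = " - ")
    ens <- sample_ensemble(sprintf("dom(400)[%s]", loops),
                           n_conformations = 30, seed = 5)
    chain_statistics(ens)$rg_mean
  }, numeric(1))
  expect_gt(rg_f[1], rg_f[2])
})

test_that("chain statistics use the lattice bond set and exact moments", {
  ens <- sample_ensemble("lin(250)", n_conformations = 10,
                         sweeps_between = 200, equil_sweeps = 1000, seed = 2)
  st <- chain_statistics(ens)
  bonds <- as.numeric(names(st$bond_hist))
  expect_true(all(vapply(bonds, function(b)
    min(abs(b - c(30, sqrt(2) * 30, sqrt(3) * 30))) < 1e-3, logical(1))))
  expect_true(st$bond_mean > 30 && st$bond_mean < sqrt(3) * 30)
  expect_true(all(st$rg > 0))
  # straight line of N beads spacing d: Rg^2 = d^2 (N^2 - 1) / 12
  straight <- build_initial_chain("lin(250)")
  ens1 <- structure(list(chain = straight,
                         conformations = list(straight$coords),
                         seed = 1, self_avoiding = TRUE),
                    class = "chain_ensemble")
  n <- 100
  expect_equal(chain_statistics(ens1)$rg_mean,
               30 * sqrt((n^2 - 1) / 12), tolerance = 1e-10)
  expect_error(chain_statistics(structure(
    list(chain = straight, conformations = list()),
    class = "chain_ensemble")))
})
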