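test_that("derivatives implement the mass-action scheme", {
  wt <- wt_rates()
  # no mass, no flux
  expect_equal(unname(ccrm_derivatives(species_state(), wt)), rep(0, 6))
  # all rates zero: any state is stationary
  zero <- rate_constants(0, 0, 0, 0, 0, 0, 0, 0, locked = character())
  st <- species_state(E = 0.1, S = 1, FS = 0.2, GSI = 0.05, GSp = 0.01,
                      Sp = 0.3)
  expect_equal(unname(ccrm_derivatives(st, zero)), rep(0, 6))
  # hand arithmetic: dS/dt = -k1*E*S + k1r*FS = -100*0.1*1 + 528*0.2
  d <- ccrm_derivatives(st, wt)
  expect_equal(d[["S"]], 95.6)
  # conservation: enzyme- and substrate-containing sums have zero flux
  expect_equal(d[["E"]] + d[["FS"]] + d[["GSI"]] + d[["GSp"]], 0,
               tolerance = 1e-12)
  expect_equal(d[["S"]] + d[["FS"]] + d[["GSI"]] + d[["GSp"]] + d[["Sp"]],
               0, tolerance = 1e-12)
})

test_that("integration preserves totals and matches closed forms", {
  # all rates zero: state constant
  zero <- rate_constants(0, 0, 0, 0, 0, 0, 0, 0, locked = character())
  tr <- simulate_mechanism(zero, species_state(E = 0.5, S = 2.5),
                           seq(0.1, 2, length.out = 20))
  expect_true(all(abs(tr$E - 0.5) < 1e-12) && all(abs(tr$S - 2.5) < 1e-12))

  # two-state relaxation FS <-> GSI: GSI(t) = K2/(1+K2) * (1 - e^-(k2+k2r)t)
  k <- rate_constants(0, 0, 23.2, 6.7, 0, 0, 0, 0, locked = character())
  tt <- seq(0.001, 1, length.out = 200)
  tr <- simulate_mechanism(k, species_state(FS = 1), tt)
  K2 <- 23.2 / 6.7
  closed <- (K2 / (1 + K2)) * (1 - exp(-(23.2 + 6.7) * tt))
  expect_lt(max(abs(tr$GSI - closed)), 1e-6)

  # pseudo-first-order binding with S0 >> E0:
  # FS(t) = E0 * K1S/(1+K1S) * (1 - e^-(k1 S + k1r)t)
  kb <- rate_constants(100, 528, 0, 0, 0, 0, 0, 0, locked = character())
  S0 <- 50; E0 <- 0.01
  trb <- simulate_mechanism(kb, species_state(E = E0, S = S0), tt)
  kobs <- 100 * S0 + 528
  fs_closed <- E0 * (100 * S0 / (100 * S0 + 528)) * (1 - exp(-kobs * tt))
  expect_lt(max(abs(trb$FS - fs_closed)) / E0, 1e-4)

  # irreversible scheme exhausts substrate
  tr2 <- simulate_mechanism(wt_rates(), species_state(E = 0.5, S = 2.5), 200)
  expect_lt(abs(tr2$Sp - 2.5), 1e-3)

  expect_error(simulate_mechanism(wt_rates(), species_state(E = 1),
                                  c(2, 1)), "increasing")
})

test_that("conservation holds to 1e-6 relative on random parameter sets", {
  set.seed(101)
  for (i in 1:100) {
    r <- random_rates()
    tr <- simulate_mechanism(r, species_state(E = 0.5, S = 2.5),
                             seq(0.01, 10, length.out = 40))
    err <- conservation_error(tr)
    expect_lt(err$enzyme, 1e-6)
    expect_lt(err$substrate, 1e-6)
  }
})

test_that("cumulative product is non-decreasing when chemistry is
           irreversible and rebinding negligible", {
  set.seed(202)
  for (i in 1:100) {
    r <- random_rates(k3r = 0, k4r = 1e-6)
    tr <- simulate_mechanism(r, species_state(E = 0.5, S = 2.5),
                             seq(0.01, 10, length.out = 40))
    prod <- tr$GSp + tr$Sp
    expect_gte(min(diff(prod)), -1e-9)
  }
})

test_that("burst amplitude reflects whether product release is rate
           limiting", {
  # no chemistry, no product
  k0 <- rate_constants(100, 100, 50, 1, 0, 0, 0.5, 1e-6,
                       locked = character())
  b0 <- simulate_burst(k0, active_enzyme = 0.1, S0 = 3)
  expect_equal(b0$amplitude, 0, tolerance = 1e-9)
  expect_true(all(b0$product == 0))

  # chemistry much faster than release: burst ~ active sites
  kb <- rate_constants(100, 100, 50, 1, 50, 0, 0.5, 1e-6,
                       locked = character())
  expect_lt(rel_err(simulate_burst(kb, 0.1, 3)$amplitude, 0.1), 0.10)

  # wild type: release faster than chemistry, no burst (<= 10% of sites)
  expect_lte(simulate_burst(wt_rates(), 0.1, 3)$amplitude, 0.01)

  # amplitude increases monotonically with k3/k4
  amps <- vapply(10^seq(-2, 2), function(ratio) {
    r <- rate_constants(100, 100, 50, 1, 1.63 * ratio, 0, 1.63, 1e-6,
                        locked = character())
    simulate_burst(r, 0.1, 3)$amplitude
  }, 0)
  expect_true(all(diff(amps) > 0))
  expect_lt(amps[1], 0.005)
  expect_gt(amps[5], 0.09)

  expect_error(simulate_burst(wt_rates(), 0.5, 0.3), "S0 > active_enzyme")
})

test_that("slowest relaxation rate reflects sub-saturating occupancy", {
  # at 0.25 uM enzyme vs Kd 5.28 uM, the observed single-turnover rate
  # is k3 scaled by the strand-separated occupancy, far below k3
  lam <- slowest_relaxation_rate(wt_rates(), E = 0.25)
  expect_lt(lam, 0.21 / 4)
  # at saturating enzyme the slow eigen-rate approaches
  # k3 * K2/(1+K2) + k4-controlled drain; it must exceed the
  # sub-saturating value and stay below k3
  lam_sat <- slowest_relaxation_rate(wt_rates(), E = 500)
  expect_gt(lam_sat, lam)
  expect_lt(lam_sat, 0.21)
})
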