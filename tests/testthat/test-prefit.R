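# A minimal trace-like object is enough for the exponential pre-fits.
fake_trace <- function(times, signal, kind = "pydc", E = 5, S = 1) {
  d <- experiment_design(kind, E_total = E, S_total = S, times = times)
  new_trace(d, times, signal)
}

test_that("double-exponential fit recovers known parameters exactly on
           noiseless data", {
  tt <- seq(0, 3, length.out = 200)
  a0 <- 1; a1 <- 0.5; b1 <- 10; a2 <- 0.2; b2 <- 1
  y <- a0 + a1 * (1 - exp(-b1 * tt)) + a2 * (1 - exp(-b2 * tt))
  fit <- fit_double_exponential(fake_trace(tt, y))
  expect_lt(rel_err(fit$a0, a0), 1e-4)
  expect_lt(rel_err(fit$phases$rate[1], b1), 1e-4)
  expect_lt(rel_err(fit$phases$rate[2], b2), 1e-4)
  expect_lt(rel_err(fit$phases$amplitude[1], a1), 1e-4)
  expect_lt(rel_err(fit$phases$amplitude[2], a2), 1e-4)
  expect_lt(fit$rms, 1e-8 * max(abs(y)))
  expect_false(fit$ill_conditioned)

  # degenerate case: a single phase present; the split is flagged or the
  # second amplitude is negligible
  y1 <- a0 + a1 * (1 - exp(-b1 * tt))
  fit1 <- fit_double_exponential(fake_trace(tt, y1))
  minor <- min(abs(fit1$phases$amplitude))
  expect_true(fit1$ill_conditioned || minor < 1e-3 * a1)
  # the dominant phase still carries the true rate
  dom <- which.max(abs(fit1$phases$amplitude))
  expect_lt(rel_err(fit1$phases$rate[dom], b1), 1e-3)
})

test_that("double-exponential fit is robust to noise and point order", {
  tt <- seq(0, 3, length.out = 200)
  y <- 1 + 0.5 * (1 - exp(-10 * tt)) + 0.2 * (1 - exp(-1 * tt))
  set.seed(11)
  yn <- y + rnorm(length(y), sd = 0.01)
  fit <- fit_double_exponential(fake_trace(tt, yn))
  expect_lt(rel_err(fit$phases$rate[1], 10), 0.05)
  expect_lt(rel_err(fit$phases$rate[2], 1), 0.05)

  # permutation invariance of the least-squares objective
  set.seed(12)
  ord <- sample(length(tt))
  d <- experiment_design("pydc", 5, 1, tt)
  tr_perm <- list(times = tt[ord], signal = yn[ord], design = d)
  fit_perm <- fit_double_exponential(tr_perm)
  expect_equal(fit_perm$phases$rate, fit$phases$rate, tolerance = 1e-6)

  expect_error(fit_double_exponential(fake_trace(tt[1:5], yn[1:5])),
               "at least 7")
})

test_that("one-phase decay fit matches a known exponential", {
  tt <- seq(0, 30, length.out = 60)
  y <- 1 - exp(-0.2 * tt)
  fit <- fit_one_phase_decay(fake_trace(tt, y, kind = "radio",
                                        E = 0.25, S = 0.1))
  expect_lt(rel_err(fit$rate, 0.2), 1e-6)
  expect_lt(abs(fit$initial), 1e-8)
  expect_lt(rel_err(fit$plateau, 1), 1e-6)
  expect_lt(rel_err(fit$amplitude, 1), 1e-6)
  expect_lt(fit$rms, 1e-8)
})

test_that("one-phase decay rate on a noiseless single-turnover trace
           matches the slow eigen-rate of the linearized scheme", {
  wt <- wt_rates()
  E0 <- 0.25; S0 <- 0.1
  lam <- slowest_relaxation_rate(wt, E = E0)
  tt <- exp(seq(log(0.05), log(5 / lam), length.out = 40))
  tr <- simulate_mechanism(wt, species_state(E = E0, S = S0), tt)
  co <- observable_coefficients()
  d <- experiment_design("radio", E0, S0, tt, dead_time = 0)
  trace <- new_trace(d, tt, signal_from_trajectory(tr, "radio", co))
  fit <- fit_one_phase_decay(trace)

  # independent oracle: smallest-magnitude eigenvalue of the Jacobian of
  # the excess-enzyme linearized system over (S, FS, GSI, GSp), built
  # here by hand rather than via the package helper
  k <- as_rate_vector(wt)
  J <- rbind(
    c(-k["k1"] * E0,  k["k1r"],                         0,                0),
    c( k["k1"] * E0, -(k["k1r"] + k["k2"]),             k["k2r"],         0),
    c( 0,             k["k2"],            -(k["k2r"] + k["k3"]),  k["k3r"]),
    c( 0,             0,                   k["k3"], -(k["k3r"] + k["k4"])))
  lam_hand <- min(abs(Re(eigen(J, only.values = TRUE)$values)))
  expect_lt(rel_err(lam, lam_hand), 1e-10)
  # single-exponential approximation of the multi-exponential truth:
  # rates agree to a few percent
  expect_lt(rel_err(fit$rate, lam), 0.05)
})

test_that("prefit seeds land within an order of magnitude of the truth", {
  wt <- wt_rates()
  co <- observable_coefficients()
  tt <- c(0, exp(seq(log(2e-3), log(2), length.out = 199)))
  dp <- experiment_design("pydc", E_total = 10, S_total = 1, times = tt)
  pydc <- new_trace(dp, tt, model_signal(dp, wt, co))

  lam <- slowest_relaxation_rate(wt, E = 0.25)
  tr_times <- exp(seq(log(0.05), log(5 / lam), length.out = 24))
  dr <- experiment_design("radio", 0.25, 0.1, tr_times, dead_time = 0)
  radio <- new_trace(dr, tr_times, model_signal(dr, wt, co))

  seed <- prefit_initial_rates(pydc, radio)
  sv <- as_rate_vector(seed)
  truth <- as_rate_vector(wt)
  for (nm in c("k1r", "k2", "k2r", "k3")) {
    expect_lt(abs(log10(sv[[nm]] / truth[[nm]])), 1)
  }
  expect_s3_class(seed, "rate_constants")
  expect_true(all(c("k1", "k3r", "k4r") %in% attr(seed, "locked")))
})
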