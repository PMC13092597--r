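# Noiseless dataset with unit weights: the model must reproduce its own
# generator to solver precision, and perturbations must register as SSR.

noiseless_problem <- function(sigma = 1, ...) {
  ds <- quick_dataset(seed = 1, sigma_fluor = 0, sigma_radio = 0)
  fit_problem(ds$traces, ds$truth$rates,
              sigma = rep(sigma, length(ds$traces)), ...)
}

test_that("residuals at the generating truth are solver noise only", {
  prob <- noiseless_problem()
  packed <- ccrmkin:::pack_start(prob)
  r <- fit_residuals(stats::setNames(packed$par, packed$names), prob)
  expect_equal(length(r), sum(vapply(prob$traces,
                                     function(tr) length(tr$times), 0L)))
  expect_lt(sum(r^2), 1e-10)

  # oracle: the packed-parameter residuals equal the hand-composed
  # weighted residuals of each trace
  tr <- prob$traces[[5]]
  m <- model_signal(tr$design, ccrm_fixtures()$WT, observable_coefficients())
  idx <- sum(vapply(prob$traces[1:4], function(t) length(t$times), 0L))
  # the packed representation round-trips rates through log10, so allow
  # one-ulp parameter differences to show up as tiny signal differences
  expect_lt(max(abs(r[(idx + 1):(idx + length(tr$times))] -
                      (m - tr$signal))), 1e-6)
})

test_that("residuals respond correctly to parameter changes", {
  prob <- noiseless_problem()
  packed <- ccrmkin:::pack_start(prob)
  par <- stats::setNames(packed$par, packed$names)

  # doubling k2 produces a real misfit
  par_k2 <- par; par_k2[["k2"]] <- par[["k2"]] + log10(2)
  expect_gt(sum(fit_residuals(par_k2, prob)^2), 1)

  # doubling the PydC output factor doubles the PydC model, so the
  # residual of a truth-generated PydC trace equals the model itself
  par_a1 <- par; par_a1[["pydc.a1"]] <- par[["pydc.a1"]] + log10(2)
  r <- fit_residuals(par_a1, prob)
  tr <- prob$traces[[5]]   # first PydC trace
  idx <- sum(vapply(prob$traces[1:4], function(t) length(t$times), 0L))
  got <- r[(idx + 1):(idx + length(tr$times))]
  expect_equal(got, tr$signal, tolerance = 1e-6)
  # trp traces are untouched by a PydC coefficient
  expect_lt(sum(r[seq_len(idx)]^2), 1e-10)
})

test_that("problem assembly validates locks and sigmas", {
  ds <- quick_dataset(seed = 2, sigma_fluor = 0, sigma_radio = 0)
  all_locked <- do.call(rate_constants, c(
    as.list(as_rate_vector(ds$truth$rates)), list(locked = rate_names)))
  entries <- names(ccrmkin:::coef_entries(observable_coefficients()))
  expect_error(fit_problem(ds$traces, all_locked, coeff_locked = entries),
               "nothing to fit")
  expect_error(fit_problem(ds$traces, ds$truth$rates, sigma = c(1, 1)),
               "one sigma")
  expect_error(fit_problem(ds$traces, ds$truth$rates,
                           sigma = rep(-1, 9)), "positive")

  # coefficients of observables without traces are locked automatically
  prob_fluor <- fit_problem(ds$traces[1:8], ds$truth$rates, sigma = rep(1, 8))
  expect_false(any(startsWith(ccrmkin:::free_param_names(prob_fluor),
                              "radio.")))
})

test_that("a fit started at the truth stays there, honouring locks
           bit-identically", {
  prob <- noiseless_problem(options = list(multistart = 1))
  fit <- fit_global(prob)
  expect_s3_class(fit, "fit_result")
  expect_lt(fit$ssr, 1e-10)
  k <- as_rate_vector(fit$rates)
  truth <- as_rate_vector(ccrm_fixtures()$WT)
  expect_lt(max(rel_err(k[c("k1r", "k2", "k2r", "k3", "k4")],
                        truth[c("k1r", "k2", "k2r", "k3", "k4")])), 1e-6)
  # locked entries come back bit-identical
  expect_identical(k[["k1"]], 100)
  expect_identical(k[["k3r"]], 0)
  expect_identical(k[["k4r"]], 1e-6)
  expect_setequal(attr(fit$rates, "locked"), c("k1", "k3r", "k4r"))
  expect_true(all(fit$scales == 1))
})

test_that("noiseless recovery from a 2x-perturbed start is exact to
           0.1%", {
  ds <- quick_dataset(seed = 3, sigma_fluor = 0, sigma_radio = 0)
  truth <- as_rate_vector(ds$truth$rates)
  start <- truth
  for (nm in c("k1r", "k2", "k2r", "k3")) start[[nm]] <- 2 * start[[nm]]
  start_rates <- do.call(rate_constants, c(
    as.list(start), list(locked = c("k1", "k3r", "k4r", "k4"))))
  sigma <- lapply(ds$traces, function(tr) {
    if (tr$design$kind == "radio") 0.05 * max(tr$signal)
    else 0.01 * diff(range(tr$signal))
  })
  prob <- fit_problem(ds$traces, start_rates, sigma = sigma,
                      options = list(multistart = 1))
  fit <- fit_global(prob)
  k <- as_rate_vector(fit$rates)
  for (nm in c("k1r", "k2", "k2r", "k3")) {
    expect_lt(rel_err(k[[nm]], truth[[nm]]), 1e-3)
  }
  co <- fit$coeffs
  expect_lt(rel_err(co$pydc$a1, 1), 1e-3)
  expect_lt(rel_err(co$trp$a3, 1), 1e-3)
})

test_that("mutant parameter sets are recovered from noisy data with
           prefit-seeded starts", {
  for (variant in c("F125L", "F125W")) {
    ds <- quick_dataset(seed = 7, rates = variant)
    seed_rates <- prefit_initial_rates(ds$traces[[8]], ds$traces[[9]])
    start <- as_rate_vector(seed_rates)
    start_rates <- do.call(rate_constants, c(
      as.list(replace(start, "k4", 1.63)),
      list(locked = c("k1", "k3r", "k4r", "k4"))))
    prob <- dataset_fit_problem(ds, rates = start_rates,
                                options = list(multistart = 2, seed = 5))
    fit <- fit_global(prob)
    truth <- as_rate_vector(ds$truth$rates)
    k <- as_rate_vector(fit$rates)
    for (nm in c("k2", "k2r", "k3")) {
      expect_lt(rel_err(k[[nm]], truth[[nm]]), 0.10)
    }
  }
})
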