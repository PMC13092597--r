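# Shared helpers: small rate sets and reduced-size datasets keep the
# module tests quick; full study-scale runs live in test-acceptance.R.

wt_rates <- function() ccrm_fixtures()$WT

# random rate set, log-uniform in [1e-3, 1e2] unless overridden
random_rates <- function(k3r = NULL, k4r = NULL) {
  r <- 10^stats::runif(8, -3, 2)
  names(r) <- c("k1", "k1r", "k2", "k2r", "k3", "k3r", "k4", "k4r")
  if (!is.null(k3r)) r[["k3r"]] <- k3r
  if (!is.null(k4r)) r[["k4r"]] <- k4r
  do.call(rate_constants, c(as.list(r), list(locked = character())))
}

# reduced-size synthetic dataset for fast fitting tests
quick_dataset <- function(seed = 1, sigma_fluor = 0.01, sigma_radio = 0.05,
                          rates = "WT", n_fluor = 150) {
  generate_full_dataset(synthetic_config(
    rates = rates, sigma_fluor = sigma_fluor, sigma_radio = sigma_radio,
    seed = seed, n_fluor = n_fluor))
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
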