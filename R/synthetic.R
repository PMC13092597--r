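# Seeded synthetic datasets emulating the published experimental
# designs: a tryptophan-fluorescence concentration series (0.5 uM
# enzyme vs 2.5-10 uM DNA), a pyrrolocytosine series (1.0 uM DNA vs
# 2.5-10 uM enzyme over 2 s), and a single-turnover radiochemical
# methylation time course (0.1 uM DNA, 0.25 uM enzyme), each collected
# in triplicate with Gaussian noise and, for the stopped-flow
# experiments, a 2.5 ms dead time.

#' Configuration of the synthetic-data generator
#'
#' @param rates generating truth: a [rate_constants()] object or the
#'   name of a [ccrm_fixtures()] entry (default `"WT"`).
#' @param coeffs generating [observable_coefficients()].  The defaults
#'   (`a1 = 1`, PydC factors 3/2/1.5; `a3 = 1`, Trp factors
#'   0.8/0.6/0.6; `bkg2 = 0`) are package defaults chosen so that the
#'   PydC rise is dominated by the strand-separated intermediate and
#'   the Trp signal quenches on binding; no fluorescence coefficients
#'   were ever published, so these are generator conventions, not
#'   literature values.
#' @param sigma_fluor Gaussian noise SD of the replicate-averaged
#'   fluorescence traces, as a fraction of each trace's amplitude
#'   (default 0.01).
#' @param sigma_radio noise CV of the averaged radiochemical points
#'   (default 0.05; SD proportional to signal).
#' @param replicates replicates generated and averaged (default 3).
#' @param seed integer random seed; identical configurations produce
#'   identical datasets.
#' @param n_fluor points per fluorescence trace (default 500,
#'   log-spaced over 2 s).
#' @param n_radio points in the methylation time course (default 12,
#'   log-spaced over a window of about 5/k3).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(rates = "WT",
                             coeffs = observable_coefficients(),
                             sigma_fluor = 0.01, sigma_radio = 0.05,
                             replicates = 3, seed = 1,
                             n_fluor = 500, n_radio = 12) {
  if (is.character(rates)) {
    fx <- ccrm_fixtures()
    if (!rates %in% names(fx)) {
      stop("unknown fixture '", rates, "'", call. = FALSE)
    }
    rates <- fx[[rates]]
  }
  if (sigma_fluor < 0 || sigma_radio < 0) {
    stop("noise levels must be >= 0", call. = FALSE)
  }
  structure(list(rates = rates, coeffs = coeffs,
                 sigma_fluor = sigma_fluor, sigma_radio = sigma_radio,
                 replicates = replicates, seed = as.integer(seed),
                 n_fluor = n_fluor, n_radio = n_radio),
            class = "synthetic_config")
}

fluor_grid <- function(n, t_max = 2) {
  c(0, exp(seq(log(2e-3), log(t_max), length.out = n - 1)))
}

# Gaussian noise on the replicate average: each replicate carries
# sd*sqrt(replicates) so the averaged trace has per-point SD `sd`.
average_replicates <- function(truth, sd_point, replicates) {
  reps <- replicate(replicates,
                    truth + stats::rnorm(length(truth),
                                         sd = sd_point * sqrt(replicates)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = length(truth))
  list(mean = rowMeans(reps),
       se = apply(reps, 1, stats::sd) / sqrt(replicates))
}

make_fluor_trace <- function(kind, E, S, config, id) {
  design <- experiment_design(kind, E_total = E, S_total = S,
                              times = fluor_grid(config$n_fluor),
                              replicates = config$replicates)
  truth <- model_signal(design, config$rates, config$coeffs)
  amp <- diff(range(truth))
  sd_point <- config$sigma_fluor * amp
  if (sd_point == 0) {
    return(new_trace(design, design$times, truth, id = id))
  }
  avg <- average_replicates(truth, sd_point, config$replicates)
  new_trace(design, design$times, avg$mean, sd = avg$se, id = id)
}

#' Generate the tryptophan-fluorescence concentration series
#'
#' Four traces at 0.5 uM enzyme against 2.5, 5.0, 7.5 and 10.0 uM DNA,
#' observed over 2 s through the Trp observable with the 2.5 ms dead
#' time applied, triplicate Gaussian noise averaged.
#'
#' @param config a [synthetic_config()].
#' @return list of [new_trace()] objects.
#' @export
generate_trp_series <- function(config) {
  set.seed(config$seed + 1L)
  S_levels <- c(2.5, 5.0, 7.5, 10.0)
  lapply(S_levels, function(S) {
    make_fluor_trace("trp", E = 0.5, S = S, config,
                     id = sprintf("trp_S%.1f", S))
  })
}

#' Generate the pyrrolocytosine-fluorescence concentration series
#'
#' Four traces at 1.0 uM labelled DNA against 2.5, 5.0, 7.5 and 10.0 uM
#' enzyme over 2 s (PydC observable, dead time applied, triplicate
#' averaged noise).
#'
#' @param config a [synthetic_config()].
#' @return list of [new_trace()] objects.
#' @export
generate_pydc_series <- function(config) {
  set.seed(config$seed + 2L)
  E_levels <- c(2.5, 5.0, 7.5, 10.0)
  lapply(E_levels, function(E) {
    make_fluor_trace("pydc", E = E, S = 1.0, config,
                     id = sprintf("pydc_E%.1f", E))
  })
}

#' Generate the single-turnover methylation time course
#'
#' Product formation (uM) at 0.1 uM DNA and 0.25 uM enzyme, 12
#' log-spaced points over a window of about 5/k3 of the generating
#' parameter set, triplicate with noise proportional to signal (5% CV
#' by default).
#'
#' @param config a [synthetic_config()].
#' @param t_max time window (s); default auto-scaled to five times the
#'   reciprocal of the slowest relaxation rate of the generating set at
#'   the design enzyme concentration, so the product curve approaches
#'   its plateau inside the window.  (Scaling by 5/k3 alone would
#'   truncate the curve: at 0.25 uM enzyme against a ~5 uM dissociation
#'   constant, binding is sub-saturating and the observed rate is well
#'   below k3.)
#' @return a single [new_trace()] object.
#' @export
generate_methylation_timecourse <- function(config, t_max = NULL) {
  set.seed(config$seed + 3L)
  if (is.null(t_max)) {
    t_max <- 5 / max(slowest_relaxation_rate(config$rates, E = 0.25), 1e-6)
  }
  times <- exp(seq(log(t_max / 50), log(t_max), length.out = config$n_radio))
  design <- experiment_design("radio", E_total = 0.25, S_total = 0.1,
                              times = times, replicates = config$replicates)
  truth <- model_signal(design, config$rates, config$coeffs)
  if (config$sigma_radio == 0) {
    return(new_trace(design, times, truth, id = "radio"))
  }
  sd_point <- config$sigma_radio * abs(truth) * sqrt(config$replicates)
  reps <- replicate(config$replicates,
                    truth + stats::rnorm(length(truth), sd = sd_point))
  new_trace(design, times, rowMeans(reps),
            sd = apply(reps, 1, stats::sd) / sqrt(config$replicates),
            id = "radio")
}

#' Generate a complete three-experiment dataset
#'
#' Composes the Trp series, the PydC series, and the methylation time
#' course into a fit-ready bundle, with the generating truth recorded
#' for recovery scoring.
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory: when given, the traces are written as
#'   delimited text files together with a `manifest.yaml` recording the
#'   generating parameters.
#' @return list of class `synthetic_dataset` with elements `traces`
#'   (4 trp + 4 pydc + 1 radio), `truth` (`rates`, `coeffs`), and
#'   `config`.
#' @export
generate_full_dataset <- function(config, dir = NULL) {
  traces <- c(generate_trp_series(config),
              generate_pydc_series(config),
              list(generate_methylation_timecourse(config)))
  ds <- structure(list(traces = traces,
                       truth = list(rates = config$rates,
                                    coeffs = config$coeffs),
                       config = config),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Build a fit problem from a synthetic dataset
#'
#' @param dataset a `synthetic_dataset` from [generate_full_dataset()].
#' @param rates starting [rate_constants()]; defaults to the dataset
#'   truth (useful for noiseless self-consistency checks; for recovery
#'   studies pass perturbed or prefit-seeded starts).
#' @param coeffs starting [observable_coefficients()].
#' @param ... passed to [fit_problem()].
#' @return a [fit_problem()].
#' @export
dataset_fit_problem <- function(dataset, rates = dataset$truth$rates,
                                coeffs = observable_coefficients(),
                                ...) {
  sigma <- lapply(dataset$traces, function(tr) {
    amp <- diff(range(tr$signal))
    if (tr$design$kind == "radio") {
      if (!is.null(tr$sd) && any(tr$sd > 0)) {
        # proportional noise model: per-point SD scales with signal.
        # Pool the coefficient of variation across points (a per-point
        # 3-replicate SD is itself ~50% noisy) and rescale by signal.
        cv <- mean(tr$sd / pmax(abs(tr$signal), 1e-12))
        pmax(cv * abs(tr$signal), 0.05 * cv * amp)
      } else {
        max(0.05 * amp, 1e-6)
      }
    } else {
      est <- estimate_sigma(tr)
      max(est, 1e-9 * max(amp, 1))
    }
  })
  fit_problem(dataset$traces, rates, coeffs, sigma = sigma, ...)
}
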