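# Global weighted least squares over all experiments.  Positive
# parameters (rate constants, fluorescence coefficients) are optimized
# in log10 space, which enforces positivity and equalizes step sizes
# across constants spanning many orders of magnitude; per-trace scale
# factors, when floated, are linear and bounded near unity.

coef_entries <- function(coeffs) {
  c(as.list(stats::setNames(unlist(coeffs$pydc),
                            paste0("pydc.", names(coeffs$pydc)))),
    as.list(stats::setNames(unlist(coeffs$trp),
                            paste0("trp.", names(coeffs$trp)))),
    as.list(stats::setNames(unlist(coeffs$radio),
                            paste0("radio.", names(coeffs$radio)))))
}

coeffs_from_entries <- function(entries) {
  pick <- function(prefix) {
    nm <- grep(paste0("^", prefix, "\\."), names(entries), value = TRUE)
    out <- entries[nm]
    names(out) <- sub(paste0("^", prefix, "\\."), "", nm)
    out
  }
  observable_coefficients(pydc = pick("pydc"), trp = pick("trp"),
                          radio = pick("radio"))
}

#' Assemble a global fit problem
#'
#' Bundles the traces, the mechanism parameters with their lock flags,
#' the observable coefficients, per-experiment weights, and optimizer
#' options into one object consumed by [fit_global()] and
#' [profile_parameter()].
#'
#' Weights: each trace is weighted by 1/sigma with sigma estimated by
#' [estimate_sigma()] (smoothing-spline detrend for fluorescence,
#' replicate SD for the radiochemical assay) unless supplied.
#'
#' @param traces list of [new_trace()] objects.
#' @param rates [rate_constants()] carrying initial values and locks.
#' @param coeffs [observable_coefficients()] initial values.
#' @param coeff_locked character vector of locked coefficient names in
#'   dotted form (e.g. `"radio.bkg2"`, `"pydc.a1"`).  Coefficients of
#'   observables not present among the traces are locked automatically.
#' @param sigma optional per-trace sigmas: a numeric vector (one scalar
#'   per trace) or a list whose elements are either scalars or per-point
#'   sigma vectors (used for the radiochemical points, whose noise is
#'   proportional to signal).
#' @param scale_floating logical: float a per-trace fluorescence scale
#'   factor, bounded by `scale_bounds`.  Default FALSE (all scales fixed
#'   at 1), appropriate for replicate-averaged traces with no
#'   acquisition drift.
#' @param scale_bounds bounds for floating scale factors.
#' @param options list: `multistart` (number of optimizer starts,
#'   default 8), `perturb` (maximum multiplicative start perturbation,
#'   default 3), `seed`, `maxiter`, `ftol`, `ptol`.
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(traces, rates, coeffs = observable_coefficients(),
                        coeff_locked = "radio.bkg2", sigma = NULL,
                        scale_floating = FALSE, scale_bounds = c(0.8, 1.25),
                        options = list()) {
  stopifnot(length(traces) >= 1)
  kinds <- vapply(traces, function(tr) tr$design$kind, "")
  entries <- coef_entries(coeffs)
  # coefficients of absent observables cannot be determined
  for (k in c("pydc", "trp", "radio")) {
    if (!any(kinds == k)) {
      coeff_locked <- union(coeff_locked,
                            grep(paste0("^", k, "\\."), names(entries),
                                 value = TRUE))
    }
  }
  if (is.null(sigma)) {
    sigma <- vapply(traces, estimate_sigma, 0)
  }
  sigma <- as.list(sigma)
  if (length(sigma) != length(traces)) {
    stop("need one sigma (scalar or per-point vector) per trace",
         call. = FALSE)
  }
  for (i in seq_along(sigma)) {
    n <- length(traces[[i]]$times)
    if (!length(sigma[[i]]) %in% c(1L, n) || any(sigma[[i]] <= 0)) {
      stop("sigma for trace ", i, " must be a positive scalar or length-",
           n, " vector", call. = FALSE)
    }
  }
  opts <- utils::modifyList(
    list(multistart = 8, perturb = 3, seed = 1,
         maxiter = 300, ftol = 1e-10, ptol = 1e-12, epsfcn = 1e-8),
    options)
  prob <- structure(
    list(traces = traces, rates = rates, coeffs = coeffs,
         coeff_locked = coeff_locked, sigma = sigma,
         scale_floating = scale_floating, scale_bounds = scale_bounds,
         options = opts),
    class = "fit_problem")
  if (length(free_param_names(prob)) == 0) {
    stop("nothing to fit: every parameter is locked", call. = FALSE)
  }
  prob
}

free_param_names <- function(problem) {
  rate_free <- setdiff(rate_names, attr(problem$rates, "locked"))
  entries <- coef_entries(problem$coeffs)
  coef_free <- setdiff(names(entries), problem$coeff_locked)
  fluor <- which(vapply(problem$traces,
                        function(tr) tr$design$kind != "radio", NA))
  scales <- if (problem$scale_floating && length(fluor)) {
    paste0("scale.", fluor)
  } else {
    character()
  }
  c(rate_free, coef_free, scales)
}

# log10 bounds for positive parameters
param_bounds <- function(nm) {
  if (nm %in% rate_names) c(1e-6, 1e4) else c(1e-4, 1e4)
}

pack_start <- function(problem) {
  nms <- free_param_names(problem)
  entries <- coef_entries(problem$coeffs)
  k <- as_rate_vector(problem$rates)
  par <- vapply(nms, function(nm) {
    if (startsWith(nm, "scale.")) return(1)
    v <- if (nm %in% rate_names) k[[nm]] else entries[[nm]]
    log10(max(v, param_bounds(nm)[1]))
  }, 0)
  lower <- vapply(nms, function(nm) {
    if (startsWith(nm, "scale.")) problem$scale_bounds[1]
    else log10(param_bounds(nm)[1])
  }, 0)
  upper <- vapply(nms, function(nm) {
    if (startsWith(nm, "scale.")) problem$scale_bounds[2]
    else log10(param_bounds(nm)[2])
  }, 0)
  list(par = par, lower = lower, upper = upper, names = nms)
}

unpack_params <- function(par, problem) {
  nms <- names(par)
  k <- as_rate_vector(problem$rates)
  entries <- coef_entries(problem$coeffs)
  scales <- rep(1, length(problem$traces))
  for (i in seq_along(par)) {
    nm <- nms[i]
    if (nm %in% rate_names) {
      k[[nm]] <- 10^par[i]
    } else if (startsWith(nm, "scale.")) {
      scales[as.integer(sub("scale\\.", "", nm))] <- par[i]
    } else {
      entries[[nm]] <- 10^par[i]
    }
  }
  rates <- do.call(rate_constants,
                   c(as.list(k), list(locked = attr(problem$rates, "locked"))))
  list(rates = rates, coeffs = coeffs_from_entries(entries), scales = scales)
}

#' Weighted residual vector of a fit problem
#'
#' For each trace: integrate the mechanism from the design's post-mix
#' concentrations, evaluate the observable at dead-time-shifted times,
#' apply the trace scale, subtract the data, divide by the trace sigma;
#' residuals of all traces are concatenated.  An integration failure at
#' the proposed parameters yields a large finite penalty residual (with
#' a warning) so the optimizer can back away rather than abort.
#'
#' @param par named parameter vector in the packed (log10/linear)
#'   representation produced by the fitter; see [fit_global()].
#' @param problem a [fit_problem()].
#' @return numeric residual vector.
#' @export
fit_residuals <- function(par, problem) {
  p <- unpack_params(par, problem)
  out <- vector("list", length(problem$traces))
  for (i in seq_along(problem$traces)) {
    tr <- problem$traces[[i]]
    model <- try(model_signal(tr$design, p$rates, p$coeffs,
                              scale = p$scales[i], times = tr$times),
                 silent = TRUE)  # sigma may be scalar or per-point
    if (inherits(model, "try-error")) {
      warning("integration failed during fitting; penalty applied",
              call. = FALSE)
      out[[i]] <- rep(1e6, length(tr$times))
    } else {
      out[[i]] <- (model - tr$signal) / problem$sigma[[i]]
    }
  }
  unlist(out)
}

run_one_start <- function(par, packed, problem) {
  minpack.lm::nls.lm(
    par = par, lower = packed$lower, upper = packed$upper,
    fn = fit_residuals, problem = problem,
    control = minpack.lm::nls.lm.control(
      maxiter = problem$options$maxiter, epsfcn = problem$options$epsfcn,
      ftol = problem$options$ftol, ptol = problem$options$ptol))
}

#' Global fit of all experiments to the mechanism
#'
#' Simultaneous weighted least squares of every trace in the problem
#' against the four-step strand-separation mechanism, honouring locks
#' exactly.  Optimization is trust-region Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) in log10 space for positive parameters, with a
#' seeded multistart: the configured initial values are the first start
#' and the remaining starts are perturbed multiplicatively by random
#' factors up to `options$perturb`; the start reaching the lowest
#' weighted SSR is returned.
#'
#' @param problem a [fit_problem()].
#' @return object of class `fit_result`: `rates` (fitted
#'   [rate_constants], locked entries bit-identical to the input),
#'   `coeffs`, `scales`, `ssr` (weighted), `par` (packed vector),
#'   `par_names`, `residuals` (per trace), `n_obs`, `n_par`,
#'   `starts` (per-start SSR and convergence info).
#' @export
fit_global <- function(problem) {
  packed <- pack_start(problem)
  nstart <- max(1L, problem$options$multistart)
  set.seed(problem$options$seed)
  log_pert <- log10(problem$options$perturb)
  starts <- vector("list", nstart)
  starts[[1]] <- packed$par
  if (nstart > 1) {
    for (j in 2:nstart) {
      p <- packed$par
      free_log <- !startsWith(packed$names, "scale.")
      p[free_log] <- p[free_log] +
        stats::runif(sum(free_log), -log_pert, log_pert)
      starts[[j]] <- pmin(pmax(p, packed$lower), packed$upper)
    }
  }
  results <- vector("list", nstart)
  for (j in seq_len(nstart)) {
    results[[j]] <- try(run_one_start(starts[[j]], packed, problem),
                        silent = TRUE)
  }
  ok <- !vapply(results, inherits, NA, "try-error")
  if (!any(ok)) {
    stop("global fit failed for every start:\n",
         paste(vapply(results, function(r) as.character(r)[1], ""),
               collapse = "\n"), call. = FALSE)
  }
  ssrs <- rep(Inf, nstart)
  ssrs[ok] <- vapply(results[ok], function(r) sum(r$fvec^2), 0)
  best <- results[[which.min(ssrs)]]
  par <- stats::setNames(best$par, packed$names)
  p <- unpack_params(par, problem)
  resid <- fit_residuals(par, problem)
  lens <- vapply(problem$traces, function(tr) length(tr$times), 0L)
  resid_by_trace <- split(resid, rep(seq_along(lens), lens))
  structure(
    list(rates = p$rates, coeffs = p$coeffs, scales = p$scales,
         ssr = sum(resid^2), par = par, par_names = packed$names,
         residuals = resid_by_trace,
         n_obs = sum(lens), n_par = length(par),
         starts = data.frame(start = seq_len(nstart), ssr = ssrs,
                             converged = ok)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global fit: %d traces, %d observations, %d floating parameters\n",
              length(x$residuals), x$n_obs, x$n_par))
  cat(sprintf("Weighted SSR = %.6g\n", x$ssr))
  print(x$rates)
  invisible(x)
}
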