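# Exponential pre-fits used to characterize traces and seed the global
# fit.  Rates are fitted by bounded Levenberg-Marquardt on log10(rate)
# with the amplitudes profiled out by linear least squares (variable
# projection), which makes the multistart cheap and the fit insensitive
# to amplitude starting values.

exp_design_matrix <- function(times, rates) {
  cbind(1, sapply(rates, function(b) 1 - exp(-b * times)))
}

vp_ssr <- function(logb, times, y) {
  b <- 10^logb
  X <- exp_design_matrix(times, b)
  fit <- try(stats::lm.fit(X, y), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(ssr = Inf))
  r <- fit$residuals
  list(ssr = sum(r^2), coef = fit$coefficients, resid = r)
}

#' Fit a rising double-exponential to a trace
#'
#' Least-squares fit of `y = a0 + a1*(1 - exp(-b1*t)) + a2*(1 -
#' exp(-b2*t))`, the function used for initial characterization of the
#' stopped-flow fluorescence traces, where `a0` is the (arbitrary)
#' starting amplitude and the two phases describe the fast
#' binding/isomerization and the slower strand-separation-linked signal
#' change.  Phases are reported ordered fast to slow (`b1 >= b2`).
#'
#' A 5 x 5 grid of log-spaced rate pairs spanning `[0.1/T, 100/T]`
#' (T = trace span) seeds the optimizer, keeping the result independent
#' of starting guesses.
#'
#' @param trace a [new_trace()] object (or any list with `times` and
#'   `signal`), at least 7 points.
#' @return list of class `exp_fit` with elements `a0`, `phases` (data
#'   frame with columns `amplitude`, `rate`, fast phase first), `rms`,
#'   and `ill_conditioned` (TRUE when the fitted rates are within a
#'   factor 1.5, where the phase split is unreliable).
#' @export
fit_double_exponential <- function(trace) {
  tt <- trace$times
  y <- trace$signal
  if (length(tt) < 7) stop("need at least 7 points", call. = FALSE)
  span <- diff(range(tt))
  if (span <= 0) stop("positive time span required", call. = FALSE)
  grid <- log10(exp(seq(log(0.1 / span), log(100 / span), length.out = 5)))
  starts <- as.matrix(expand.grid(b1 = grid, b2 = grid))
  starts <- starts[starts[, 1] >= starts[, 2], , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ],
      lower = rep(log10(1e-4 / span), 2), upper = rep(log10(1e4 / span), 2),
      fn = function(p) {
        v <- vp_ssr(p, tt, y)
        if (!is.finite(v$ssr)) rep(1e6, length(y)) else v$resid
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) stop("double-exponential fit failed to converge",
                          call. = FALSE)
  b <- 10^best$par
  v <- vp_ssr(best$par, tt, y)
  ord <- order(b, decreasing = TRUE)
  phases <- data.frame(amplitude = unname(v$coef[-1][ord]),
                       rate = unname(b[ord]))
  structure(list(a0 = unname(v$coef[1]), phases = phases,
                 rms = sqrt(best$ssr / length(y)),
                 ill_conditioned = phases$rate[1] / phases$rate[2] < 1.5),
            class = "exp_fit")
}

#' Fit a one-phase decay (single-exponential approach to plateau)
#'
#' Least-squares fit of `y = plateau - amplitude * exp(-b*t)`, the model
#' used for background-subtracted single-turnover product formation.
#'
#' @param trace a [new_trace()] object (>= 4 points).
#' @return list of class `exp_fit` with `initial` (value at t = 0),
#'   `plateau`, `amplitude`, `rate`, and `rms`.
#' @export
fit_one_phase_decay <- function(trace) {
  tt <- trace$times
  y <- trace$signal
  if (length(tt) < 4) stop("need at least 4 points", call. = FALSE)
  span <- diff(range(tt))
  if (span <= 0) stop("positive time span required", call. = FALSE)
  starts <- log10(exp(seq(log(0.1 / span), log(100 / span), length.out = 5)))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(b = s),
      lower = log10(1e-4 / span), upper = log10(1e4 / span),
      fn = function(p) {
        v <- vp_ssr(p, tt, y)
        if (!is.finite(v$ssr)) rep(1e6, length(y)) else v$resid
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) stop("one-phase decay fit failed to converge",
                          call. = FALSE)
  b <- 10^best$par
  v <- vp_ssr(best$par, tt, y)
  a0 <- unname(v$coef[1])          # value at t = 0
  amp <- unname(v$coef[2])         # approach amplitude
  structure(list(initial = a0, plateau = a0 + amp, amplitude = amp,
                 rate = unname(b), rms = sqrt(best$ssr / length(y))),
            class = "exp_fit")
}

#' Seed rate constants from exponential pre-fits
#'
#' Maps the exponential characterization of a dataset to starting values
#' for the global fit, following the convention that initial estimates
#' come from per-experiment exponential fits: the fast PydC phase rate
#' approximates the strand-separation relaxation `k2 + k2r` (split
#' assuming K2 = 1 at the start), and the single-turnover decay rate,
#' corrected for the strand-separated occupancy implied by the starting
#' K1 and K2 guesses (the observed rate is roughly k3 times the GSI
#' fraction at sub-saturating enzyme), seeds `k3`.
#'
#' @param pydc_trace a PydC fluorescence trace (the highest-enzyme one
#'   is the most informative).
#' @param radio_trace the single-turnover product trace.
#' @param k1r_guess starting dissociation rate (s^-1); default 300,
#'   i.e. a ~3 uM dissociation constant at the locked k1.
#' @return a [rate_constants] object with default locks, usable as the
#'   starting point of [fit_global()].
#' @export
prefit_initial_rates <- function(pydc_trace, radio_trace, k1r_guess = 300) {
  relax <- fit_double_exponential(pydc_trace)$phases$rate[1]
  obs_rate <- fit_one_phase_decay(radio_trace)$rate
  # GSI occupancy under the starting guesses (K2 = 1), at the radio
  # design's enzyme concentration: observed rate ~ k3 * f_GSI
  K1E <- (100 / k1r_guess) * radio_trace$design$E_total
  f_gsi <- K1E * 1 / (1 + K1E * (1 + 1))
  k3_guess <- obs_rate / max(f_gsi, 0.01)
  rate_constants(k1 = 100, k1r = k1r_guess,
                 k2 = relax / 2, k2r = relax / 2,
                 k3 = k3_guess, k3r = 0, k4 = 1.63, k4r = 1e-6)
}
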