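#' Observable coefficients for the three experimental signals
#'
#' The three experiments each report a different linear combination of
#' species:
#' \itemize{
#'   \item pyrrolocytosine (PydC) fluorescence, which monitors DNA strand
#'     separation: `a1 * (S + FS + cGSI*GSI + cGSp*GSp + cSp*Sp)`;
#'   \item tryptophan fluorescence, which monitors enzyme-DNA binding and
#'     the subsequent conformational change:
#'     `a3 * (E + cFS*FS + cGSI*GSI + cGSp*GSp)`;
#'   \item the radiochemical methylation assay, which counts all product
#'     states: `GSp + Sp + bkg2` (uM product equivalents).
#' }
#' Fluorescence units are arbitrary; the absolute scale is carried by the
#' output factors `a1`/`a3` and, optionally, per-trace scale factors
#' bounded near unity.
#'
#' @param pydc named list with `a1` (> 0) and dimensionless species
#'   factors `cGSI`, `cGSp`, `cSp`.
#' @param trp named list with `a3` (> 0) and factors `cFS`, `cGSI`,
#'   `cGSp`.
#' @param radio named list with background `bkg2` (uM).
#' @return object of class `observable_coefficients`.
#' @export
observable_coefficients <- function(
    pydc = list(a1 = 1, cGSI = 3, cGSp = 2, cSp = 1.5),
    trp = list(a3 = 1, cFS = 0.8, cGSI = 0.6, cGSp = 0.6),
    radio = list(bkg2 = 0)) {
  if (pydc$a1 <= 0 || trp$a3 <= 0) {
    stop("output scale factors a1 and a3 must be positive", call. = FALSE)
  }
  structure(list(pydc = pydc, trp = trp, radio = radio),
            class = "observable_coefficients")
}

#' Experiment design: what was mixed and how it was observed
#'
#' @param kind one of `"trp"`, `"pydc"`, `"radio"`.
#' @param E_total,S_total post-mix enzyme and DNA concentrations (uM).
#' @param times observed time grid (s, instrument clock: 0 is the first
#'   recorded point, `dead_time` after mixing).
#' @param dead_time stopped-flow dead time (s); default 2.5 ms for the
#'   fluorescence experiments, 0 for the manual radiochemical assay.
#' @param replicates number of replicates collected (averaged for
#'   fluorescence).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(kind, E_total, S_total, times,
                              dead_time = if (kind == "radio") 0 else 0.0025,
                              replicates = 3) {
  kind <- match.arg(kind, c("trp", "pydc", "radio"))
  if (E_total <= 0 || S_total <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (dead_time < 0) stop("dead time must be >= 0", call. = FALSE)
  structure(list(kind = kind, E_total = E_total, S_total = S_total,
                 times = times, dead_time = dead_time,
                 replicates = replicates),
            class = "experiment_design")
}

#' A measured or synthetic time-course trace
#'
#' @param design an [experiment_design()].
#' @param times observed times (s), strictly increasing.
#' @param signal signal values (arbitrary fluorescence units, or uM
#'   product for the radiochemical assay).
#' @param sd optional per-point standard deviation.
#' @param id trace identifier string.
#' @return object of class `kin_trace`.
#' @export
new_trace <- function(design, times, signal, sd = NULL, id = "trace") {
  if (length(times) != length(signal)) {
    stop("times and signal must have equal length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(sd) && length(sd) != length(times)) {
    stop("sd must match times in length", call. = FALSE)
  }
  structure(list(design = design, times = times, signal = signal,
                 sd = sd, id = id),
            class = "kin_trace")
}

#' Map a species trajectory to an observed signal
#'
#' @param traj a trajectory from [simulate_mechanism()].
#' @param kind `"trp"`, `"pydc"` or `"radio"`.
#' @param coeffs an [observable_coefficients()] object.
#' @param scale per-trace scale factor (dimensionless, default 1).
#' @return numeric signal series aligned to `traj$time`.
#' @examples
#' tr <- simulate_mechanism(ccrm_fixtures()$WT,
#'                          species_state(E = 2.5, S = 1),
#'                          seq(0.001, 2, length.out = 50))
#' head(signal_from_trajectory(tr, "pydc", observable_coefficients()))
#' @export
signal_from_trajectory <- function(traj, kind,
                                   coeffs = observable_coefficients(),
                                   scale = 1) {
  kind <- match.arg(kind, c("trp", "pydc", "radio"))
  sig <- switch(
    kind,
    pydc = coeffs$pydc$a1 *
      (traj$S + traj$FS + coeffs$pydc$cGSI * traj$GSI +
         coeffs$pydc$cGSp * traj$GSp + coeffs$pydc$cSp * traj$Sp),
    trp = coeffs$trp$a3 *
      (traj$E + coeffs$trp$cFS * traj$FS + coeffs$trp$cGSI * traj$GSI +
         coeffs$trp$cGSp * traj$GSp),
    radio = traj$GSp + traj$Sp + coeffs$radio$bkg2
  )
  scale * sig
}

#' Shift observed times by the stopped-flow dead time
#'
#' A stopped-flow instrument records nothing during the first
#' `dead_time` seconds after mixing, so the first recorded point already
#' corresponds to reaction age `dead_time`.  The model is therefore
#' evaluated at `observed_times + dead_time`.
#'
#' @param observed_times numeric vector of instrument times (s).
#' @param dead_time dead time (s), >= 0; 2.5 ms for the instrument used
#'   here.
#' @return shifted evaluation times.
#' @examples
#' apply_dead_time(c(0, 0.001, 0.002), 0.0025)
#' @export
apply_dead_time <- function(observed_times, dead_time) {
  if (dead_time < 0) stop("dead time must be >= 0", call. = FALSE)
  observed_times + dead_time
}

#' Model signal for one trace design
#'
#' Convenience composition: integrate the mechanism from the design's
#' post-mix concentrations, evaluate at dead-time-shifted times, apply
#' the observable and a scale factor.
#'
#' @param design an [experiment_design()].
#' @param rates,coeffs mechanism parameters.
#' @param scale per-trace scale factor.
#' @param times observed times; defaults to `design$times`.
#' @return numeric model signal at the observed times.
#' @export
model_signal <- function(design, rates, coeffs = observable_coefficients(),
                         scale = 1, times = design$times) {
  eval_times <- apply_dead_time(times, design$dead_time)
  traj <- simulate_mechanism(
    rates, species_state(E = design$E_total, S = design$S_total), eval_times)
  signal_from_trajectory(traj, design$kind, coeffs, scale)
}

#' Estimate the noise level of a trace
#'
#' For fluorescence traces, the residual root-mean-square about a
#' smoothing-spline detrend; for radiochemical traces, the mean of the
#' per-point replicate standard deviations when present, falling back to
#' the spline estimate.
#'
#' @param trace a [new_trace()] object.
#' @return scalar sigma in the trace's signal units.
#' @export
estimate_sigma <- function(trace) {
  if (trace$design$kind == "radio" && !is.null(trace$sd) &&
      any(trace$sd > 0)) {
    return(mean(trace$sd[trace$sd > 0]))
  }
  n <- length(trace$times)
  if (n < 10) {
    return(stats::sd(diff(trace$signal)) / sqrt(2))
  }
  sp <- stats::smooth.spline(trace$times, trace$signal)
  sqrt(mean((trace$signal - stats::predict(sp, trace$times)$y)^2))
}
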