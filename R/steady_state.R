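#' Steady-state kinetic parameters from the microscopic rate constants
#'
#' Closed-form kcat, Km, and kcat/Km of the four-step mechanism
#' `E + S <-> FS <-> GSI <-> GSp <-> E + Sp`, derived by the
#' King-Altman/steady-state treatment with product rebinding neglected
#' (k4r enters no expression; it is held at its minimal locked value):
#' \deqn{kcat = k2 k3 k4 / D, \quad D = k2(k3 + k3r + k4) +
#'   k2r(k3r + k4) + k3 k4}
#' \deqn{Km = [k1r(k2r k3r + k2r k4 + k3 k4) + k2 k3 k4] / (k1 D)}
#' \deqn{kcat/Km = k1 k2 k3 k4 / [k1r(k2r k3r + k2r k4 + k3 k4) +
#'   k2 k3 k4]}
#'
#' Note on the kcat denominator: the term `k2r*(k3r + k4)` involves the
#' forward product-release constant k4, consistent with the Km and
#' kcat/Km expressions (which contain `k2r*k4`); with the reverse
#' constant there instead, the three expressions would be mutually
#' inconsistent and would not reproduce the tabulated steady-state
#' values from the fitted rate constants.  With k3r = 0 the identity
#' `kcat/Km == kcat / Km` holds exactly.
#'
#' @param rates a [rate_constants()] object.
#' @return list of class `steady_state_params`: `kcat` (s^-1), `Km`
#'   (uM), `kcat_over_Km` (uM^-1 s^-1).
#' @examples
#' steady_state_params(ccrm_fixtures()$WT)  # ~0.15 s^-1, ~1.1 uM, ~0.13
#' @export
steady_state_params <- function(rates) {
  k <- as_rate_vector(rates)
  k1 <- k[["k1"]]; k1r <- k[["k1r"]]; k2 <- k[["k2"]]; k2r <- k[["k2r"]]
  k3 <- k[["k3"]]; k3r <- k[["k3r"]]; k4 <- k[["k4"]]
  D <- k2 * (k3 + k3r + k4) + k2r * (k3r + k4) + k3 * k4
  spec_den <- k1r * (k2r * k3r + k2r * k4 + k3 * k4) + k2 * k3 * k4
  if (D <= 0 || k1 <= 0 || spec_den <= 0) {
    stop("undefined steady-state parameters: zero denominator",
         call. = FALSE)
  }
  structure(list(kcat = k2 * k3 * k4 / D,
                 Km = spec_den / (k1 * D),
                 kcat_over_Km = k1 * k2 * k3 * k4 / spec_den),
            class = "steady_state_params")
}

#' @export
print.steady_state_params <- function(x, ...) {
  cat(sprintf("kcat = %.3g s^-1, Km = %.3g uM, kcat/Km = %.3g uM^-1 s^-1\n",
              x$kcat, x$Km, x$kcat_over_Km))
  invisible(x)
}

#' Check the closed-form steady-state parameters against simulation
#'
#' Independent validation route: simulate multiple-turnover initial
#' velocities at each substrate concentration (slope of total product
#' over the linear phase after the pre-steady-state transient), fit the
#' hyperbolic rate law `v = Vmax S / (Km + S)`, and compare with the
#' closed forms.
#'
#' @param rates a [rate_constants()] object.
#' @param S_grid substrate concentrations (uM); default 8 log-spaced
#'   points spanning 0.1-10 x the closed-form Km.
#' @param E0 catalytic enzyme concentration for the simulations (uM);
#'   kept small so substrate depletion over the velocity window stays
#'   below a few percent.
#' @return list with `kcat_sim`, `Km_sim`, the closed-form values, and
#'   `max_rel_dev` (largest relative deviation of kcat and Km).
#' @export
verify_against_simulation <- function(rates, S_grid = NULL, E0 = 0.01) {
  ss <- steady_state_params(rates)
  if (is.null(S_grid)) {
    S_grid <- exp(seq(log(0.1 * ss$Km), log(10 * ss$Km), length.out = 8))
  }
  v <- vapply(S_grid, function(S) {
    v_exp <- ss$kcat * E0 * S / (ss$Km + S)  # only to scale the window
    T_end <- 0.03 * S / v_exp
    tt <- seq(T_end / 3, T_end, length.out = 25)
    traj <- simulate_mechanism(rates, species_state(E = E0, S = S), tt)
    prod <- traj$GSp + traj$Sp
    fit <- stats::lm(prod ~ tt)
    resid_scale <- sqrt(mean(stats::resid(fit)^2)) /
      max(diff(range(prod)), .Machine$double.eps)
    if (resid_scale > 0.02) {
      stop("late product phase is not linear at S = ", signif(S, 3),
           " uM", call. = FALSE)
    }
    unname(stats::coef(fit)[2])
  }, 0)
  hyp <- minpack.lm::nls.lm(
    par = c(lVmax = log(max(v)), lKm = log(stats::median(S_grid))),
    fn = function(p) v - exp(p[1]) * S_grid / (exp(p[2]) + S_grid))
  kcat_sim <- exp(hyp$par[[1]]) / E0
  Km_sim <- exp(hyp$par[[2]])
  list(kcat_sim = kcat_sim, Km_sim = Km_sim,
       kcat_closed = ss$kcat, Km_closed = ss$Km,
       max_rel_dev = max(abs(kcat_sim - ss$kcat) / ss$kcat,
                         abs(Km_sim - ss$Km) / ss$Km))
}

#' Fold changes between two rate-constant sets
#'
#' Ratios reference/variant for k2, k2r, k3 and the derived equilibrium
#' constants K1 and K2 — the comparisons used to express how each
#' mutation destabilizes the strand-separated intermediate.
#'
#' @param reference,variant [rate_constants()] objects (reference is
#'   typically the wild type).
#' @return named numeric vector of ratios; entries where the variant
#'   value is zero are `NA` (undefined).
#' @examples
#' fx <- ccrm_fixtures()
#' fold_changes(fx$WT, fx$F125L)["k2"]  # ~15-fold reduction
#' @export
fold_changes <- function(reference, variant) {
  kr <- as_rate_vector(reference)
  kv <- as_rate_vector(variant)
  er <- equilibrium_constants(reference)
  ev <- equilibrium_constants(variant)
  num <- c(k2 = kr[["k2"]], k2r = kr[["k2r"]], k3 = kr[["k3"]],
           K1 = er$K1, K2 = er$K2)
  den <- c(k2 = kv[["k2"]], k2r = kv[["k2r"]], k3 = kv[["k3"]],
           K1 = ev$K1, K2 = ev$K2)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
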