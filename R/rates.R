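#' Microscopic rate constants of the strand-separation mechanism
#'
#' Container for the eight rate constants of the four-step scheme
#' `E + S <-> FS <-> GSI <-> GSp <-> E + Sp`, together with per-constant
#' lock flags used by the global fit.  Units are micromolar and seconds
#' throughout: `k1` and `k4r` are bimolecular (uM^-1 s^-1), the remaining
#' six are first order (s^-1).  The reverse constants written k-1, k-2,
#' k-3, k-4 in the kinetics literature are spelled `k1r`, `k2r`, `k3r`,
#' `k4r` here.
#'
#' The default lock pattern mirrors the published fitting convention:
#' `k1` locked at 100 uM^-1 s^-1 (rapid-equilibrium binding, with `k1r`
#' floating so that K1 = k1/k1r is determined by the data), the chemical
#' step irreversible (`k3r` locked at 0), and product rebinding locked at
#' the minimal value 1e-6 uM^-1 s^-1.
#'
#' @param k1 association rate constant E + S -> FS (uM^-1 s^-1)
#' @param k1r dissociation of FS (s^-1)
#' @param k2 strand-separation forward rate constant (s^-1)
#' @param k2r re-annealing (reverse) rate constant (s^-1)
#' @param k3 methyl-transfer rate constant (s^-1)
#' @param k3r reverse methylation rate constant (s^-1)
#' @param k4 product release rate constant (s^-1)
#' @param k4r product rebinding rate constant (uM^-1 s^-1)
#' @param locked character vector naming the constants held fixed during
#'   fitting; the remaining constants float.
#' @return An object of class `rate_constants`: a named numeric vector of
#'   the eight constants with a `locked` attribute.
#' @examples
#' wt <- ccrm_fixtures()$WT
#' equilibrium_constants(wt)
#' @export
rate_constants <- function(k1 = 100, k1r = 528, k2 = 23.2, k2r = 6.7,
                           k3 = 0.21, k3r = 0, k4 = 1.63, k4r = 1e-6,
                           locked = c("k1", "k3r", "k4r")) {
  k <- c(k1 = k1, k1r = k1r, k2 = k2, k2r = k2r,
         k3 = k3, k3r = k3r, k4 = k4, k4r = k4r)
  if (any(!is.finite(k))) {
    stop("rate constants must be finite", call. = FALSE)
  }
  if (any(k < 0)) {
    stop("invalid parameter: negative rate constant (",
         paste(names(k)[k < 0], collapse = ", "), ")", call. = FALSE)
  }
  locked <- as.character(locked)
  bad <- setdiff(locked, names(k))
  if (length(bad)) {
    stop("unknown rate constant in `locked`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(k, locked = locked, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  locked <- attr(x, "locked")
  cat("Rate constants of the strand-separation scheme (uM, s):\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-4s = %-10.4g %s\n", nm, unname(x[nm]),
                if (nm %in% locked) "[locked]" else ""))
  }
  invisible(x)
}

#' Names of the eight rate constants, in canonical order
#' @export
rate_names <- c("k1", "k1r", "k2", "k2r", "k3", "k3r", "k4", "k4r")

#' Extract rate constants as a plain named numeric vector
#'
#' @param rates a [rate_constants()] object.
#' @return named numeric vector in [rate_names] order.
#' @export
as_rate_vector <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  unclass(rates)[rate_names]
}

#' Equilibrium constants of binding and strand separation
#'
#' K1 = k1/k1r (uM^-1) is the DNA-binding equilibrium constant; its
#' reciprocal 1/K1 (uM) is the dissociation constant reported in the rate
#' tables.  K2 = k2/k2r (dimensionless) is the equilibrium constant of
#' the strand-separation step and measures the stability of the
#' strand-separated GSI intermediate.
#'
#' @param rates a [rate_constants] object.
#' @return list with elements `K1` (uM^-1), `K2` (dimensionless), and
#'   `Kd` = 1/K1 (uM).
#' @examples
#' equilibrium_constants(ccrm_fixtures()$WT)$K2  # ~3.5 for wild type
#' @export
equilibrium_constants <- function(rates) {
  k <- as_rate_vector(rates)
  if (k[["k1r"]] <= 0 || k[["k2r"]] <= 0) {
    stop("undefined equilibrium: zero reverse rate constant", call. = FALSE)
  }
  K1 <- k[["k1"]] / k[["k1r"]]
  list(K1 = K1, K2 = k[["k2"]] / k[["k2r"]], Kd = 1 / K1)
}

#' Published rate-constant sets for CcrM and its recognition-loop mutants
#'
#' The globally fitted rate constants for wild-type CcrM and the six
#' mutants (F125L, F125A, F125W, R129A, N124A, R44A), entered exactly as
#' tabulated: the binding step as the dissociation constant 1/K1 in uM
#' with k1 locked at 100 uM^-1 s^-1 (so k1r = 100 * (1/K1)), k3r = 0,
#' k4r = 1e-6 uM^-1 s^-1, and k4 = 1.63 s^-1 (fitted for wild type,
#' locked at the wild-type value for the mutants, where product release
#' was not defined by the data).
#'
#' @return Named list of [rate_constants], one per enzyme.
#' @examples
#' names(ccrm_fixtures())
#' steady_state_params(ccrm_fixtures()$WT)
#' @export
ccrm_fixtures <- function() {
  rows <- list(
    #        1/K1   k2     k2r   k3
    WT    = c(5.28, 23.2,  6.7,  0.21),
    F125L = c(2.24, 1.57,  17.3, 0.069),
    F125A = c(6.42, 0.57,  6.6,  0.0025),
    F125W = c(3.00, 17.5,  10.6, 0.018),
    R129A = c(1.45, 0.20,  5.0,  0.0009),
    N124A = c(1.83, 0.39,  3.9,  0.003),
    R44A  = c(2.72, 8.4,   17.5, 0.000153)
  )
  out <- lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    locked <- c("k1", "k3r", "k4r")
    if (nm != "WT") locked <- c(locked, "k4")  # k4 undetermined for mutants
    rate_constants(k1 = 100, k1r = 100 * r[1], k2 = r[2], k2r = r[3],
                   k3 = r[4], k3r = 0, k4 = 1.63, k4r = 1e-6,
                   locked = locked)
  })
  names(out) <- names(rows)
  out
}

#' Read and write rate-constant configurations
#'
#' Parameter sets are stored as a flat YAML mapping with one entry per
#' constant (`k1`, `k1r`, ..., `k4r`), each holding `value`, `locked`,
#' and optionally `lower`/`upper` bounds.
#'
#' @param path file path.
#' @param rates a [rate_constants] object.
#' @param bounds optional named list of `c(lower, upper)` per constant.
#' @return `read_rates_config` returns a [rate_constants] object with a
#'   `bounds` attribute when bounds are present; `write_rates_config`
#'   returns `path` invisibly.
#' @export
write_rates_config <- function(rates, path, bounds = NULL) {
  k <- as_rate_vector(rates)
  locked <- attr(rates, "locked")
  doc <- lapply(rate_names, function(nm) {
    entry <- list(value = unname(k[nm]), locked = nm %in% locked)
    if (!is.null(bounds[[nm]])) {
      entry$lower <- bounds[[nm]][1]
      entry$upper <- bounds[[nm]][2]
    }
    entry
  })
  names(doc) <- rate_names
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_rates_config
#' @export
read_rates_config <- function(path) {
  doc <- yaml::read_yaml(path)
  missing <- setdiff(rate_names, names(doc))
  if (length(missing)) {
    stop("parameter config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(doc[rate_names], function(e) as.numeric(e$value), 0)
  locked <- rate_names[vapply(doc[rate_names],
                              function(e) isTRUE(e$locked), NA)]
  rates <- do.call(rate_constants,
                   c(as.list(vals), list(locked = locked)))
  bnd <- doc[rate_names][vapply(doc[rate_names],
                                function(e) !is.null(e$lower), NA)]
  if (length(bnd)) {
    attr(rates, "bounds") <- lapply(bnd, function(e) c(e$lower, e$upper))
  }
  rates
}
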