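# Profile-likelihood confidence analysis: clamp one parameter on a
# grid, re-optimize everything else, and bound the parameter where the
# re-optimized SSR crosses the F-test threshold
#   SSR_crit = SSR_min * (1 + qf(0.95, 1, N - P) / (N - P))
# with N observations and P floating parameters.

profile_threshold <- function(ssr_min, n_obs, n_par, level = 0.95) {
  df <- n_obs - n_par
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  ssr_min * (1 + stats::qf(level, 1, df) / df)
}

# Locate the threshold crossing between consecutive grid points on one
# side of the optimum and refine it by bisection on ssr_fun.
refine_crossing <- function(ssr_fun, inner, outer, threshold, rel_tol) {
  lo <- inner  # ssr below threshold
  hi <- outer  # ssr above threshold
  while (abs(hi - lo) > rel_tol * abs(lo)) {
    mid <- sqrt(lo * hi)  # bisect in log space (parameters are positive)
    if (ssr_fun(mid) > threshold) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Profile an objective over one parameter
#'
#' Generic profiling core: evaluates a re-optimized SSR function on a
#' grid bracketing the optimum, applies the F-test threshold, and
#' locates the 95% bounds by bisection refinement at the crossings.
#' Used by [profile_parameter()]; also usable directly with any scalar
#' SSR function (e.g. a closed-form regression SSR) for validation.
#'
#' @param ssr_fun function(value) -> re-optimized SSR with the parameter
#'   clamped at `value`.
#' @param best best-fit parameter value (must lie inside `grid`).
#' @param grid increasing vector of positive trial values bracketing
#'   `best`.
#' @param n_obs,n_par observation and floating-parameter counts defining
#'   the threshold degrees of freedom.
#' @param level confidence level (default 0.95).
#' @param rel_tol relative refinement tolerance on the bound (default
#'   0.005, i.e. 0.5% of the parameter value).
#' @param ssr_min optional SSR at the optimum; recomputed from
#'   `ssr_fun(best)` when missing.
#' @return list of class `confidence_profile`: `grid`, `ssr`, `ssr_min`,
#'   `threshold`, `lower`, `upper`, `lower_open`, `upper_open`, `best`.
#' @export
profile_objective <- function(ssr_fun, best, grid, n_obs, n_par,
                              level = 0.95, rel_tol = 0.005,
                              ssr_min = NULL) {
  if (best < min(grid) || best > max(grid)) {
    stop("grid must bracket the best-fit value", call. = FALSE)
  }
  grid <- sort(unique(c(grid, best)))
  ssr <- vapply(grid, ssr_fun, 0)
  if (is.null(ssr_min)) ssr_min <- ssr[which(grid == best)]
  threshold <- profile_threshold(ssr_min, n_obs, n_par, level)
  i_best <- which.min(abs(grid - best))

  side_bound <- function(idx_seq) {
    for (i in idx_seq) {
      if (ssr[i] > threshold) {
        inner_idx <- if (i < i_best) i + 1 else i - 1
        return(list(value = refine_crossing(ssr_fun, grid[inner_idx],
                                            grid[i], threshold, rel_tol),
                    open = FALSE))
      }
    }
    list(value = grid[idx_seq[length(idx_seq)]], open = TRUE)
  }
  lower <- if (i_best > 1) side_bound(seq(i_best - 1, 1)) else
    list(value = grid[1], open = TRUE)
  upper <- if (i_best < length(grid)) side_bound(seq(i_best + 1, length(grid)))
    else list(value = grid[length(grid)], open = TRUE)

  structure(list(grid = grid, ssr = ssr, ssr_min = ssr_min,
                 threshold = threshold, best = best,
                 lower = lower$value, upper = upper$value,
                 lower_open = lower$open, upper_open = upper$open),
            class = "confidence_profile")
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Clamps the named parameter at each grid value, re-optimizes all other
#' floating parameters starting from the best fit (warm-starting
#' outward from the optimum), and reports the 95% bounds where the
#' re-optimized SSR crosses the F-test threshold.  This is the
#' confidence-contour analysis used to attach intervals to each rate
#' constant.
#'
#' @param problem the [fit_problem()] that produced `result`.
#' @param result a [fit_result] from [fit_global()].
#' @param name a floating parameter name (a rate constant such as
#'   `"k2"`, a dotted coefficient name, or `"scale.i"`).
#' @param grid trial values; default 21 log-spaced points per side
#'   spanning a factor 4 below and above the best fit.
#' @param level confidence level.
#' @return a `confidence_profile` (see [profile_objective()]) with the
#'   parameter `name` attached.
#' @export
profile_parameter <- function(problem, result, name, grid = NULL,
                              level = 0.95) {
  if (!(name %in% result$par_names)) {
    stop("cannot profile '", name, "': not a floating parameter",
         call. = FALSE)
  }
  is_scale <- startsWith(name, "scale.")
  best_packed <- result$par[[name]]
  best <- if (is_scale) best_packed else 10^best_packed
  if (is.null(grid)) {
    grid <- exp(seq(log(best / 4), log(best * 4), length.out = 43))
  }
  others <- setdiff(result$par_names, name)
  packed <- pack_start(problem)
  idx <- match(name, packed$names)
  warm <- new.env(parent = emptyenv())
  warm$par <- result$par

  ssr_fun <- function(value) {
    par <- warm$par
    par[idx] <- if (is_scale) value else log10(value)
    if (length(others) == 0) {
      return(sum(fit_residuals(par, problem)^2))
    }
    sub <- minpack.lm::nls.lm(
      par = par[others],
      lower = packed$lower[match(others, packed$names)],
      upper = packed$upper[match(others, packed$names)],
      fn = function(p) {
        full <- par
        full[others] <- p
        fit_residuals(full, problem)
      },
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10,
                                           ptol = 1e-10, epsfcn = 1e-8))
    par[others] <- sub$par
    warm$par <- par
    sum(sub$fvec^2)
  }

  # evaluate outward from the optimum so each clamp warm-starts from its
  # neighbour; profile_objective re-evaluates from the cached states
  grid <- sort(unique(c(grid, best)))
  i_best <- which(grid == best)
  cache <- numeric(length(grid))
  warm0 <- result$par
  for (i in seq(i_best, 1)) cache[i] <- ssr_fun(grid[i])
  warm$par <- warm0
  for (i in seq(i_best, length(grid))) cache[i] <- ssr_fun(grid[i])
  cached_fun <- function(value) {
    hit <- which(abs(grid - value) <= 1e-12 * value)
    if (length(hit)) cache[hit[1]] else ssr_fun(value)
  }
  prof <- profile_objective(cached_fun, best, grid,
                            n_obs = result$n_obs, n_par = result$n_par,
                            level = level, ssr_min = result$ssr)
  prof$name <- name
  prof
}

#' Tabulate best fits with profile confidence intervals
#'
#' Renders the `value (lower-upper)` layout used for globally fitted
#' rate constants.  Open interval sides (the threshold was never crossed
#' inside the profiled grid) are flagged and rendered as `>max` / `<min`.
#'
#' @param profiles list of `confidence_profile` objects (may be empty).
#' @param digits significant digits for rendering (default 3).
#' @return data frame with columns `parameter`, `best`, `lower`,
#'   `upper`, `open`, `formatted`.
#' @examples
#' # ci_table(list(profile_parameter(prob, fit, "k2")))
#' @export
ci_table <- function(profiles, digits = 3) {
  if (length(profiles) == 0) {
    return(data.frame(parameter = character(), best = numeric(),
                      lower = numeric(), upper = numeric(),
                      open = character(), formatted = character(),
                      stringsAsFactors = FALSE))
  }
  fmt <- function(v) format(signif(v, digits), trim = TRUE)
  rows <- lapply(profiles, function(p) {
    lo <- if (p$lower_open) "<min" else fmt(p$lower)
    hi <- if (p$upper_open) ">max" else fmt(p$upper)
    open <- if (p$lower_open && p$upper_open) "both"
      else if (p$lower_open) "lower"
      else if (p$upper_open) "upper" else "none"
    data.frame(parameter = p$name, best = p$best, lower = p$lower,
               upper = p$upper, open = open,
               formatted = sprintf("%s (%s–%s)", fmt(p$best), lo, hi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
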