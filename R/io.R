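# Trace-file dialect: comma-separated values with '.' decimal, columns
# time_s, signal[, sd], preceded by '#'-prefixed header metadata lines:
#   # observable=pydc
#   # E_total_uM=2.5
#   # S_total_uM=1
#   # dead_time_s=0.0025
#   # trace_id=pydc_E2.5

num_fmt <- function(x) sprintf("%.10g", x)

#' Write a trace to a delimited text file
#'
#' @param trace a [new_trace()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_file <- function(trace, path) {
  d <- trace$design
  header <- c(
    sprintf("# observable=%s", d$kind),
    sprintf("# E_total_uM=%s", num_fmt(d$E_total)),
    sprintf("# S_total_uM=%s", num_fmt(d$S_total)),
    sprintf("# dead_time_s=%s", num_fmt(d$dead_time)),
    sprintf("# trace_id=%s", trace$id)
  )
  has_sd <- !is.null(trace$sd)
  cols <- if (has_sd) "time_s,signal,sd" else "time_s,signal"
  rows <- if (has_sd) {
    paste(num_fmt(trace$times), num_fmt(trace$signal), num_fmt(trace$sd),
          sep = ",")
  } else {
    paste(num_fmt(trace$times), num_fmt(trace$signal), sep = ",")
  }
  writeLines(c(header, cols, rows), path)
  invisible(path)
}

#' Read a trace file
#'
#' Inverse of [write_trace_file()] on canonical files (writing then
#' reading reproduces the file byte for byte).
#'
#' @param path path to a trace file in the documented dialect.
#' @return a [new_trace()] object.
#' @export
read_trace_file <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx))) {
    stop("parse error in ", path, ": header lines must precede data",
         call. = FALSE)
  }
  meta <- list()
  for (i in hdr_idx) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) {
      stop("parse error at line ", i, " of ", path,
           ": expected '# key=value'", call. = FALSE)
    }
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  required <- c("observable", "E_total_uM", "S_total_uM", "dead_time_s")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("parse error in ", path, ": missing header(s) ",
         paste0("# ", missing, "=", collapse = ", "), call. = FALSE)
  }
  body <- lines[-hdr_idx]
  if (length(body) < 2) {
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  }
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(cols[1:2], c("time_s", "signal"))) {
    stop("parse error at line ", length(hdr_idx) + 1, " of ", path,
         ": expected columns time_s,signal[,sd]", call. = FALSE)
  }
  dat <- utils::read.csv(text = body, header = TRUE)
  design <- experiment_design(
    kind = meta$observable,
    E_total = as.numeric(meta$E_total_uM),
    S_total = as.numeric(meta$S_total_uM),
    times = dat$time_s,
    dead_time = as.numeric(meta$dead_time_s))
  new_trace(design, dat$time_s, dat$signal,
            sd = if ("sd" %in% names(dat)) dat$sd else NULL,
            id = if (!is.null(meta$trace_id)) meta$trace_id else
              basename(path))
}

#' Write a trajectory as delimited text
#'
#' Columns `time_s,E,S,FS,GSI,GSp,Sp` (uM).
#'
#' @param traj a trajectory from [simulate_mechanism()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- data.frame(time_s = traj$time, traj[species_names])
  utils::write.csv(format(out, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a synthetic dataset directory
#'
#' One trace file per trace plus a `manifest.yaml` recording the
#' generating rate constants, observable coefficients, noise levels and
#' seed, so recovery studies can score fitted values against the truth.
#'
#' @param dataset a `synthetic_dataset` from [generate_full_dataset()].
#' @param dir directory (created if needed).
#' @return `dir` (write) / a list with `traces` and `manifest` (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(dataset$traces, function(tr) {
    f <- file.path(dir, paste0(tr$id, ".csv"))
    write_trace_file(tr, f)
    basename(f)
  }, "")
  truth_rates <- as.list(as_rate_vector(dataset$truth$rates))
  manifest <- list(
    traces = as.list(files),
    truth = list(
      rates = truth_rates,
      locked = as.list(attr(dataset$truth$rates, "locked")),
      coeffs = coef_entries(dataset$truth$coeffs)),
    noise = list(sigma_fluor = dataset$config$sigma_fluor,
                 sigma_radio = dataset$config$sigma_radio,
                 replicates = dataset$config$replicates),
    seed = dataset$config$seed)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  traces <- lapply(manifest$traces,
                   function(f) read_trace_file(file.path(dir, f)))
  list(traces = traces, manifest = manifest)
}

#' Assemble the final report of a global analysis
#'
#' Renders the rate-constant table with profile confidence intervals,
#' the derived steady-state parameters, and residual summaries, together
#' with a JSON-serializable twin of all numbers.
#'
#' @param fit a [fit_result] from [fit_global()].
#' @param profiles optional list of `confidence_profile` objects; rate
#'   constants without a profile get `n.d.` interval columns.
#' @param steady optional [steady_state_params()]; computed from the
#'   fitted rates when `NULL`.
#' @param json_path optional path to write the JSON twin.
#' @return list of class `kin_report` with elements `rate_table`
#'   (data frame), `steady_state`, `residual_rms` (per trace), and
#'   `json` (the serializable twin).
#' @export
report_fit <- function(fit, profiles = NULL, steady = NULL,
                       json_path = NULL) {
  if (is.null(steady)) steady <- steady_state_params(fit$rates)
  k <- as_rate_vector(fit$rates)
  locked <- attr(fit$rates, "locked")
  prof_by <- if (length(profiles)) {
    stats::setNames(profiles, vapply(profiles, function(p) p$name, ""))
  } else {
    list()
  }
  fmt <- function(v) format(signif(v, 3), trim = TRUE)
  rows <- lapply(rate_names, function(nm) {
    p <- prof_by[[nm]]
    if (!is.null(p)) {
      lo <- if (p$lower_open) "<min" else fmt(p$lower)
      hi <- if (p$upper_open) ">max" else fmt(p$upper)
      data.frame(parameter = nm, value = unname(k[nm]),
                 status = "floating",
                 formatted = sprintf("%s (%s–%s)", fmt(k[nm]), lo, hi),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(parameter = nm, value = unname(k[nm]),
                 status = if (nm %in% locked) "locked" else "floating",
                 formatted = if (nm %in% locked) fmt(k[nm]) else
                   sprintf("%s (n.d.)", fmt(k[nm])),
                 stringsAsFactors = FALSE)
    }
  })
  rate_table <- do.call(rbind, rows)
  rms <- vapply(fit$residuals, function(r) sqrt(mean(r^2)), 0)
  eq <- equilibrium_constants(fit$rates)
  json <- list(
    rates = as.list(k), locked = as.list(locked),
    intervals = lapply(prof_by, function(p) {
      list(lower = p$lower, upper = p$upper,
           lower_open = p$lower_open, upper_open = p$upper_open)
    }),
    equilibrium = list(K1 = eq$K1, K2 = eq$K2),
    steady_state = list(kcat = steady$kcat, Km = steady$Km,
                        kcat_over_Km = steady$kcat_over_Km),
    ssr = fit$ssr, residual_rms = as.list(rms),
    scales = as.list(fit$scales))
  if (!is.null(json_path)) {
    jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  structure(list(rate_table = rate_table, steady_state = steady,
                 equilibrium = eq, residual_rms = rms, json = json),
            class = "kin_report")
}

#' @export
print.kin_report <- function(x, ...) {
  cat("Rate constants (value, 95% profile interval where computed):\n")
  for (i in seq_len(nrow(x$rate_table))) {
    cat(sprintf("  %-4s %-22s [%s]\n", x$rate_table$parameter[i],
                x$rate_table$formatted[i], x$rate_table$status[i]))
  }
  cat(sprintf("K1 = %.3g uM^-1 (Kd = %.3g uM), K2 = %.3g\n",
              x$equilibrium$K1, x$equilibrium$Kd, x$equilibrium$K2))
  cat("Steady state: ")
  print(x$steady_state)
  cat(sprintf("Residual RMS (weighted) per trace: %s\n",
              paste(signif(x$residual_rms, 3), collapse = ", ")))
  invisible(x)
}
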