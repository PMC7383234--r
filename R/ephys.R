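#' Boltzmann sigmoid
#'
#' `y = t / (1 + exp((v_half - E)/k))` for an increasing curve (voltage
#' dependence of activation); `decreasing = TRUE` flips the argument sign to
#' describe availability curves that fall with depolarization, keeping the
#' slope factor `k` positive by convention.
#'
#' @param E Applied voltage, mV.
#' @param top Curve maximum `t` (normalized units).
#' @param v_half Half-maximal voltage, mV.
#' @param slope Slope factor `k` in mV (> 0).
#' @param decreasing Availability-style orientation.
#' @return Numeric response.
#' @export
boltzmann <- function(E, top, v_half, slope, decreasing = FALSE) {
  s <- if (decreasing) -1 else 1
  top / (1 + exp(s * (v_half - E) / slope))
}

#' Sum of two Boltzmann components
#'
#' `y = t [ F / (1 + exp((v1 - E)/k1)) + (1 - F) / (1 + exp((v2 - E)/k2)) ]`
#' where `F` is the relative contribution of component 1.
#'
#' @inheritParams boltzmann
#' @param fraction Relative contribution `F` of component 1, in `[0, 1]`.
#' @param v_half_1,slope_1,v_half_2,slope_2 Component midpoints and slopes.
#' @export
double_boltzmann <- function(E, top, fraction, v_half_1, slope_1,
                             v_half_2, slope_2, decreasing = FALSE) {
  top * (fraction * boltzmann(E, 1, v_half_1, slope_1, decreasing) +
         (1 - fraction) * boltzmann(E, 1, v_half_2, slope_2, decreasing))
}

#' Voltage-clamp / current-clamp sweep series
#'
#' Container for a family of sweeps sharing a protocol. Each sweep is a list
#' with `command` (step voltage in mV, or injected current in pA), `time`
#' (ms, uniformly sampled), `value` (current in pA for voltage clamp,
#' membrane voltage in mV for current clamp) and optionally `vcmd`, the
#' per-sample command voltage (needed for leak subtraction across segmented
#' protocols). Currents supplied in nA are converted to pA on construction.
#'
#' @param protocol One of `"activation"`, `"inactivation"`, `"recovery"`,
#'   `"ramp"`, `"step"`.
#' @param sweeps List of sweeps as described above.
#' @param holding Holding potential, mV.
#' @param metadata List of protocol annotations (e.g. `tail_start_ms`,
#'   `test_start_ms`, conditioning duration).
#' @param value_unit `"pA"` or `"nA"` for current traces, `"mV"` for voltage.
#' @return A `sweep_series` object.
#' @export
sweep_series <- function(protocol = c("activation", "inactivation",
                                      "recovery", "ramp", "step"),
                         sweeps, holding = -90, metadata = list(),
                         value_unit = "pA") {
  protocol <- match.arg(protocol)
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    stopifnot(all(c("command", "time", "value") %in% names(sw)),
              length(sw$time) == length(sw$value))
    dt <- diff(sw$time)
    if (length(dt) && diff(range(dt)) > 1e-6 * max(dt)) {
      stop("sweep ", i, ": sampling is not uniform", call. = FALSE)
    }
    if (value_unit == "nA") sweeps[[i]]$value <- sw$value * 1000
  }
  structure(list(protocol = protocol, sweeps = sweeps, holding = holding,
                 metadata = metadata,
                 value_unit = if (value_unit == "nA") "pA" else value_unit),
            class = "sweep_series")
}

#' @export
print.sweep_series <- function(x, ...) {
  cat(sprintf("<sweep_series: %s, %d sweeps, commands %s..%s>\n",
              x$protocol, length(x$sweeps),
              format(min(sweep_commands(x))), format(max(sweep_commands(x)))))
  invisible(x)
}

#' Command levels of a sweep series
#' @param series A [sweep_series()].
#' @return Numeric vector of per-sweep command levels.
#' @export
sweep_commands <- function(series) {
  vapply(series$sweeps, function(s) s$command, numeric(1))
}

#' Offline linear leak subtraction
#'
#' Estimates the linear (ohmic) leak from steady-state currents of sweeps
#' whose command voltage lies in `leak_window` — a voltage range where the
#' channels of interest are closed — by least squares on
#' `I = g (V - V_rev)`, then digitally subtracts the predicted leak from
#' every sample of every sweep (using the per-sample command voltage `vcmd`
#' when present, the sweep command otherwise).
#'
#' @param series A [sweep_series()] of current sweeps.
#' @param leak_window Length-2 voltage range, mV.
#' @param steady_frac Trailing fraction of the command-level samples
#'   averaged as the steady-state current.
#' @return The series with leak removed; the fitted conductance (nS) and
#'   reversal are stored in `metadata$leak_fit`.
#' @export
leak_subtract <- function(series, leak_window, steady_frac = 0.2) {
  stopifnot(inherits(series, "sweep_series"), length(leak_window) == 2)
  cmds <- sweep_commands(series)
  in_win <- cmds >= min(leak_window) & cmds <= max(leak_window)
  if (sum(in_win) < 2) {
    stop("need at least 2 sweeps inside the leak window", call. = FALSE)
  }
  ss <- vapply(series$sweeps[in_win], function(sw) {
    at_cmd <- if (!is.null(sw$vcmd)) which(sw$vcmd == sw$command)
              else seq_along(sw$value)
    tail_idx <- at_cmd[at_cmd >= stats::quantile(at_cmd, 1 - steady_frac)]
    mean(sw$value[tail_idx])
  }, numeric(1))
  fit <- stats::lm(ss ~ cmds[in_win])
  b <- unname(stats::coef(fit)[1]); g <- unname(stats::coef(fit)[2])
  for (i in seq_along(series$sweeps)) {
    sw <- series$sweeps[[i]]
    v <- if (!is.null(sw$vcmd)) sw$vcmd else rep(sw$command, length(sw$value))
    series$sweeps[[i]]$value <- sw$value - (g * v + b)
  }
  series$metadata$leak_fit <- list(g_nS = g, intercept_pA = b,
                                   v_rev = if (abs(g) > 1e-12) -b / g else NA)
  series
}

#' Normalized tail-current activation curve
#'
#' For each sweep of an activation protocol, the tail amplitude is the peak
#' absolute deviation from the late-tail baseline within the first
#' `early_ms` of the tail segment (the segment start must be annotated in
#' `metadata$tail_start_ms`); amplitudes are normalized to the maximum
#' across sweeps and plotted against the step voltage.
#'
#' @param series A [sweep_series()] with `protocol = "activation"`.
#' @param early_ms Window after tail onset searched for the peak.
#' @param baseline_frac Trailing fraction of the tail used as baseline.
#' @return Data frame with `voltage` (mV), `response` (normalized) and
#'   `amplitude` (raw peak tail amplitude, pA).
#' @export
tail_activation_curve <- function(series, early_ms = 10,
                                  baseline_frac = 0.2) {
  stopifnot(inherits(series, "sweep_series"))
  t0 <- series$metadata$tail_start_ms
  if (is.null(t0)) stop("series lacks metadata$tail_start_ms", call. = FALSE)
  amps <- vapply(series$sweeps, function(sw) {
    tl <- sw$time >= t0
    if (!any(tl)) stop("tail segment empty", call. = FALSE)
    v <- sw$value[tl]; tt <- sw$time[tl]
    base <- mean(v[tt >= stats::quantile(tt, 1 - baseline_frac)])
    max(abs(v[tt < t0 + early_ms] - base))
  }, numeric(1))
  data.frame(voltage = sweep_commands(series),
             response = amps / max(amps), amplitude = amps)
}

#' Normalized availability curve from a double-pulse inactivation protocol
#'
#' Peak absolute test-pulse current (first `early_ms` after the test-pulse
#' onset annotated in `metadata$test_start_ms`), normalized to the maximum
#' across conditioning voltages.
#'
#' @inheritParams tail_activation_curve
#' @return Data frame with `voltage` (conditioning, mV) and `response`.
#' @export
availability_curve <- function(series, early_ms = 10) {
  stopifnot(inherits(series, "sweep_series"))
  t0 <- series$metadata$test_start_ms
  if (is.null(t0)) stop("series lacks metadata$test_start_ms", call. = FALSE)
  amps <- vapply(series$sweeps, function(sw) {
    seg <- sw$time >= t0 & sw$time < t0 + early_ms
    if (!any(seg)) stop("test segment empty", call. = FALSE)
    max(abs(sw$value[seg]))
  }, numeric(1))
  data.frame(voltage = sweep_commands(series),
             response = amps / max(amps))
}

#' Toxin-sensitive current by subtraction
#'
#' The stromatoxin-sensitive current is the pre-toxin current minus the
#' post-toxin current, pointwise per sweep. Protocols, command levels and
#' time bases must match.
#'
#' @param pre_series,post_series Matching [sweep_series()] recorded before
#'   and after toxin application.
#' @return A [sweep_series()] of the difference current, with
#'   `metadata$sctx_sensitive = TRUE`.
#' @export
sctx_subtract <- function(pre_series, post_series) {
  stopifnot(inherits(pre_series, "sweep_series"),
            inherits(post_series, "sweep_series"))
  if (!identical(pre_series$protocol, post_series$protocol) ||
      length(pre_series$sweeps) != length(post_series$sweeps)) {
    stop("pre and post series protocols do not match", call. = FALSE)
  }
  for (i in seq_along(pre_series$sweeps)) {
    a <- pre_series$sweeps[[i]]; b <- post_series$sweeps[[i]]
    if (a$command != b$command || !isTRUE(all.equal(a$time, b$time))) {
      stop("sweep ", i, ": command or time base mismatch", call. = FALSE)
    }
    pre_series$sweeps[[i]]$value <- a$value - b$value
  }
  pre_series$metadata$sctx_sensitive <- TRUE
  pre_series
}

default_boltzmann_init <- function(voltage, response) {
  top <- max(response)
  o <- order(voltage)
  v <- voltage[o]; y <- response[o]
  lvl <- function(frac) {
    cross <- which(diff(sign(y - frac * top)) != 0)
    if (!length(cross)) return(v[which.min(abs(y - frac * top))])
    i <- cross[1]
    v[i] + (frac * top - y[i]) * (v[i + 1] - v[i]) / (y[i + 1] - y[i])
  }
  v50 <- lvl(0.5)
  k <- abs(lvl(0.9) - lvl(0.1)) / 4.39
  if (!is.finite(k) || k < 0.5) k <- diff(range(v)) / 8
  list(top = top, v_half = v50, slope = k)
}

#' Fit a single Boltzmann to normalized response points
#'
#' Least-squares fit of `y = t / (1 + exp((v_half - E)/k))` via
#' Levenberg-Marquardt. Default initialization: `t` at the maximum response,
#' `v_half` at the interpolated half-maximum crossing, and
#' `k = (V90 - V10) / 4.39`. The slope is constrained positive; the curve
#' orientation is controlled by `decreasing` (see [boltzmann()]).
#'
#' @param points Data frame with columns `voltage` and `response`, at least
#'   4 points spanning the transition.
#' @param init Optional named list overriding `top`, `v_half`, `slope`.
#' @param fix_top Fix `t` to this value instead of fitting it (e.g. 1 for
#'   pre-normalized data); `NULL` leaves it free.
#' @param decreasing Availability-style orientation.
#' @return A `boltzmann_fit`: `top`, `v_half`, `slope`, `rms`, `converged`,
#'   and `v_half_in_range` (midpoint within the sampled span +/- one span).
#' @export
fit_boltzmann <- function(points, init = NULL, fix_top = NULL,
                          decreasing = FALSE) {
  stopifnot(nrow(points) >= 4,
            all(c("voltage", "response") %in% names(points)))
  y0 <- points$response
  if (decreasing) {
    # a decreasing curve in E is increasing in -E
    ini <- default_boltzmann_init(-points$voltage, y0)
    ini$v_half <- -ini$v_half
  } else {
    ini <- default_boltzmann_init(points$voltage, y0)
  }
  if (!is.null(init)) ini[names(init)] <- init
  d <- data.frame(E = points$voltage, y = y0)
  s <- if (decreasing) -1 else 1
  fit <- if (is.null(fix_top)) {
    try(minpack.lm::nlsLM(
      y ~ top / (1 + exp(s * (v_half - E) / slope)), data = d,
      start = list(top = ini$top, v_half = ini$v_half, slope = ini$slope),
      lower = c(top = 0, v_half = -Inf, slope = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    top <- fix_top
    try(minpack.lm::nlsLM(
      y ~ top / (1 + exp(s * (v_half - E) / slope)), data = d,
      start = list(v_half = ini$v_half, slope = ini$slope),
      lower = c(v_half = -Inf, slope = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    stop("Boltzmann fit failed to converge: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  top <- if (is.null(fix_top)) unname(cf["top"]) else fix_top
  span <- diff(range(points$voltage))
  v_half <- unname(cf["v_half"])
  structure(list(
    top = top, v_half = v_half, slope = unname(cf["slope"]),
    decreasing = decreasing,
    rms = sqrt(mean(stats::resid(fit)^2)),
    converged = TRUE,
    v_half_in_range = v_half >= min(points$voltage) - span &
                      v_half <= max(points$voltage) + span
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: t = %.4g, V50 = %.4g mV, k = %.4g mV (rms %.3g)\n",
              x$top, x$v_half, x$slope, x$rms))
  invisible(x)
}

#' Fit a sum of two Boltzmann components
#'
#' Least-squares fit of
#' `y = t [ F/(1 + exp((v1 - E)/k1)) + (1-F)/(1 + exp((v2 - E)/k2)) ]`
#' with `F` bounded in `[0, 1]` and both slopes positive, using
#' Levenberg-Marquardt with multistart (jittered initializations, seeded) to
#' escape local minima. After fitting, components are ordered so
#' `v_half_1 > v_half_2` (the more depolarized midpoint is component 1);
#' exact midpoint ties are broken by larger `F` first. Fits whose midpoints
#' fall within 2 mV of each other, or whose fraction lands within 0.05 of a
#' boundary, are flagged `degenerate` (the split between components is then
#' unidentifiable and the minor component's parameters are not meaningful).
#'
#' @param points Data frame with `voltage`, `response`; at least 8 points.
#' @param n_starts Number of jittered starts.
#' @param seed Seed for the multistart jitter.
#' @param decreasing Availability-style orientation.
#' @return A `double_boltzmann_fit`: `top`, `fraction`, `v_half_1`,
#'   `slope_1`, `v_half_2`, `slope_2`, `rms`, `degenerate`.
#' @export
fit_double_boltzmann <- function(points, n_starts = 5, seed = 1,
                                 decreasing = FALSE) {
  stopifnot(nrow(points) >= 8,
            all(c("voltage", "response") %in% names(points)))
  d <- data.frame(E = points$voltage, y = points$response)
  s <- if (decreasing) -1 else 1
  span <- diff(range(points$voltage))
  base <- default_boltzmann_init(if (decreasing) -points$voltage
                                 else points$voltage, points$response)
  v0 <- if (decreasing) -base$v_half else base$v_half
  starts <- with_local_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      jit <- if (i == 1) c(0, 0) else stats::rnorm(2, 0, span / 6)
      list(top = base$top, fraction = stats::runif(1, 0.2, 0.8),
           v_half_1 = v0 + span / 5 + jit[1],
           slope_1 = base$slope,
           v_half_2 = v0 - span / 5 + jit[2],
           slope_2 = base$slope)
    })
  })
  resid_fn <- function(par) {
    d$y - double_boltzmann(d$E, par["top"], par["fraction"],
                           par["v_half_1"], par["slope_1"],
                           par["v_half_2"], par["slope_2"],
                           decreasing = decreasing)
  }
  lower <- c(top = 0, fraction = 0, v_half_1 = -Inf, slope_1 = 1e-3,
             v_half_2 = -Inf, slope_2 = 1e-3)
  upper <- c(top = Inf, fraction = 1, v_half_1 = Inf, slope_1 = Inf,
             v_half_2 = Inf, slope_2 = Inf)
  best <- NULL
  for (st in starts) {
    # raw Levenberg-Marquardt: robust when a parameter converges onto a
    # bound (fraction at 0/1 makes the wrapped-nls Jacobian singular)
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = unlist(st)[names(lower)], lower = lower, upper = upper,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300))), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$deviance) ||
        fit$info == 0) next
    # info 5 (maxiter reached) is kept as a candidate: selection is by RSS
    # and flat-surface fits legitimately stall near the optimum
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("double-Boltzmann fit failed to converge from any start",
         call. = FALSE)
  }
  cf <- as.list(best$fit$par)
  comp <- list(list(v = cf$v_half_1, k = cf$slope_1, f = cf$fraction),
               list(v = cf$v_half_2, k = cf$slope_2, f = 1 - cf$fraction))
  ord <- order(-vapply(comp, `[[`, numeric(1), "v"),
               -vapply(comp, `[[`, numeric(1), "f"))
  comp <- comp[ord]
  structure(list(
    top = cf$top, fraction = comp[[1]]$f,
    v_half_1 = comp[[1]]$v, slope_1 = comp[[1]]$k,
    v_half_2 = comp[[2]]$v, slope_2 = comp[[2]]$k,
    decreasing = decreasing,
    rms = sqrt(best$rss / nrow(d)),
    degenerate = abs(comp[[1]]$v - comp[[2]]$v) < 2 ||
                 comp[[1]]$f < 0.05 || comp[[1]]$f > 0.95,
    converged = TRUE
  ), class = "double_boltzmann_fit")
}

#' @export
print.double_boltzmann_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Double Boltzmann fit: t = %.4g, F = %.3g\n",
    "  component 1: V50 = %.4g mV, k = %.4g mV\n",
    "  component 2: V50 = %.4g mV, k = %.4g mV  (rms %.3g%s)\n"),
    x$top, x$fraction, x$v_half_1, x$slope_1, x$v_half_2, x$slope_2,
    x$rms, if (x$degenerate) ", DEGENERATE components" else ""))
  invisible(x)
}

#' Fit recovery from inactivation
#'
#' Single-exponential fit of the fractional recovery time course,
#' `y(dt) = 1 - A exp(-dt / tau)`.
#'
#' @param intervals Recovery intervals, ms (>= 4 values).
#' @param ratios Test/conditioning current ratios, in `[0, 1.2]`.
#' @return A `recovery_fit`: `amplitude` (A), `tau` (ms), `rms`.
#' @export
fit_recovery <- function(intervals, ratios) {
  stopifnot(length(intervals) >= 4, length(intervals) == length(ratios),
            all(ratios >= 0 & ratios <= 1.2))
  d <- data.frame(dt = intervals, y = ratios)
  fit <- try(minpack.lm::nlsLM(
    y ~ 1 - A * exp(-dt / tau), data = d,
    start = list(A = max(1e-3, 1 - min(ratios)),
                 tau = stats::median(intervals)),
    lower = c(A = 0, tau = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("recovery fit failed to converge", call. = FALSE)
  }
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), tau = unname(cf["tau"]),
                 rms = sqrt(mean(stats::resid(fit)^2))),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("Recovery fit: A = %.3g, tau = %.4g ms (rms %.3g)\n",
              x$amplitude, x$tau, x$rms))
  invisible(x)
}

# First sample index at which an action potential is detected: dV/dt above
# `dvdt_crit` (mV/ms) followed by overshoot above `overshoot_mv` within 5 ms.
detect_spike_index <- function(time, voltage, dvdt_crit = 10,
                               overshoot_mv = 0) {
  dvdt <- diff(voltage) / diff(time)
  cand <- which(dvdt >= dvdt_crit)
  for (i in cand) {
    win <- time > time[i] & time <= time[i] + 5
    if (any(voltage[win] > overshoot_mv, na.rm = TRUE)) return(i)
  }
  NA_integer_
}

#' Action-potential threshold from a current ramp
#'
#' Under a monotone current ramp (e.g. 0 to 1 nA over 1 s), returns the
#' injected current at the first action potential, detected as dV/dt
#' exceeding `dvdt_crit` (default 10 mV/ms) followed by overshoot above
#' `overshoot_mv` (default 0 mV). Returns `NA` if no spike occurs.
#'
#' @param trace List with `time` (ms), `voltage` (mV) and `current` (pA,
#'   the injected ramp command).
#' @param dvdt_crit Spike detection slope criterion, mV/ms.
#' @param overshoot_mv Required overshoot, mV.
#' @return Threshold current in pA, or `NA_real_`.
#' @export
ap_threshold_ramp <- function(trace, dvdt_crit = 10, overshoot_mv = 0) {
  stopifnot(all(c("time", "voltage", "current") %in% names(trace)))
  if (any(diff(trace$current) < -1e-9)) {
    stop("ramp command must be non-decreasing", call. = FALSE)
  }
  i <- detect_spike_index(trace$time, trace$voltage, dvdt_crit, overshoot_mv)
  if (is.na(i)) NA_real_ else trace$current[i]
}

#' Action-potential threshold from an incrementing step family
#'
#' Returns the smallest step current eliciting a detected spike across a
#' family of current steps (e.g. +10 pA, 50 ms increments), or `NA` if no
#' step spikes.
#'
#' @param steps List of traces, each with `current` (the step level, pA),
#'   `time` and `voltage`; levels must be strictly increasing from 0.
#' @inheritParams ap_threshold_ramp
#' @return Threshold current in pA, or `NA_real_`.
#' @export
ap_threshold_step <- function(steps, dvdt_crit = 10, overshoot_mv = 0) {
  lev <- vapply(steps, function(s) s$current, numeric(1))
  stopifnot(all(diff(lev) > 0), all(lev > 0))
  for (s in steps) {
    i <- detect_spike_index(s$time, s$voltage, dvdt_crit, overshoot_mv)
    if (!is.na(i)) return(s$current)
  }
  NA_real_
}

#' Capsaicin responder call from a voltage-clamp trace
#'
#' A neuron is a responder if its mean inward (negative) current deflection
#' during the application window exceeds `k_sd` times the pre-application
#' baseline standard deviation, i.e. the response is time-locked to the
#' application.
#'
#' @param trace List with `time` (ms) and `value` (current, pA).
#' @param window Length-2 application window `c(start, end)` in ms.
#' @param k_sd Detection multiple of the baseline SD.
#' @return Logical.
#' @export
capsaicin_responder <- function(trace, window, k_sd = 5) {
  stopifnot(all(c("time", "value") %in% names(trace)), length(window) == 2)
  if (window[1] < min(trace$time) || window[2] > max(trace$time)) {
    stop("application window lies outside the trace", call. = FALSE)
  }
  base <- trace$value[trace$time < window[1]]
  if (length(base) < 10) stop("insufficient pre-application baseline",
                              call. = FALSE)
  inside <- trace$value[trace$time >= window[1] & trace$time <= window[2]]
  deflection <- mean(base) - mean(inside)  # inward = negative current
  deflection > k_sd * stats::sd(base)
}

#' Maximum fractional current reduction across step potentials
#'
#' Compares steady-state currents before and after toxin application sweep
#' by sweep and reports the largest fractional reduction and the step
#' voltage at which it occurs (in the study this peaked at the +20 mV step).
#'
#' @param pre_series,post_series Matching [sweep_series()].
#' @param steady_frac Trailing fraction of each sweep averaged.
#' @return List with `voltage` (mV) and `reduction` (fraction in `[0, 1]`).
#' @export
max_fractional_reduction <- function(pre_series, post_series,
                                     steady_frac = 0.2) {
  cmds <- sweep_commands(pre_series)
  stopifnot(identical(cmds, sweep_commands(post_series)))
  red <- vapply(seq_along(cmds), function(i) {
    a <- pre_series$sweeps[[i]]$value
    b <- post_series$sweeps[[i]]$value
    keep <- seq(floor((1 - steady_frac) * length(a)) + 1, length(a))
    pre <- mean(a[keep]); post <- mean(b[keep])
    if (abs(pre) < 1e-9) return(NA_real_)
    (pre - post) / pre
  }, numeric(1))
  i <- which.max(red)
  list(voltage = cmds[i], reduction = red[i])
}
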