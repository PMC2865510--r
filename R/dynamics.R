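#' Integrate the triad ODE system
#'
#' Adaptive stiff-capable integration (deSolve's `lsoda`) of the
#' dimensionless triad equations under a constant signal or a piecewise
#' signal schedule. Discontinuous schedules are integrated segment by
#' segment so the step-size control never straddles a switch point.
#'
#' @param params A [triad_params][triad_parameters()] object.
#' @param init Initial state `(x_s, x_g, x_f)`.
#' @param signal A [signal_input()], or a list of segments
#'   `list(list(duration =, signal =), ...)` applied in order.
#' @param horizon Total integration time in dimensionless units (ignored
#'   when `signal` is a schedule, whose durations define the horizon).
#' @param n_out Approximate number of output rows.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `triad_trajectory` with columns `time`,
#'   `x_s`, `x_g`, `x_f` (and `hours = time * hours_per_tau`).
#' @export
integrate_triad <- function(params, init, signal = signal_input(),
                            horizon = 100, n_out = 200,
                            rtol = 1e-8, atol = 1e-10) {
  segments <- if (!is.null(signal$n)) {
    list(list(duration = horizon, signal = signal))
  } else signal
  x <- as_state(init)
  if (!is.na(params$clamp_scl)) x[1] <- params$clamp_scl
  total <- sum(purrr::map_dbl(segments, "duration"))
  if (total <= 0) abort("Integration horizon must be > 0.")
  out <- list()
  t0 <- 0
  for (seg in segments) {
    if (seg$duration <= 0) next
    sg <- seg$signal
    deriv <- function(t, y, p) list(unname(triad_rhs(y, sg, params)))
    nt <- max(2L, ceiling(n_out * seg$duration / total))
    times <- seq(0, seg$duration, length.out = nt)
    sol <- deSolve::ode(y = c(x_s = x[1], x_g = x[2], x_f = x[3]),
                        times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      abort(paste0("Integration failed (lsoda istate ",
                   attr(sol, "istate")[1], ") at segment starting t = ",
                   format(t0), "."))
    }
    sol <- as.data.frame(sol)
    x <- pmax(as.numeric(sol[nrow(sol), c("x_s", "x_g", "x_f")]), 0)
    sol$time <- sol$time + t0
    t0 <- t0 + seg$duration
    out <- c(out, list(sol))
  }
  tr <- as_tibble(dplyr::distinct(dplyr::bind_rows(out), .data$time,
                                  .keep_all = TRUE))
  tr$hours <- tr$time * params$hours_per_tau
  class(tr) <- c("triad_trajectory", class(tr))
  tr
}

# final state of a pulse experiment: amplitude on `axis` for `duration`,
# then baseline signal for `relax` time units
pulse_final_state <- function(params, axis, amplitude, duration,
                              from, baseline, relax = 200) {
  sched <- list(
    list(duration = duration, signal = signal_on_axis(axis, amplitude)),
    list(duration = relax, signal = baseline)
  )
  tr <- integrate_triad(params, from, sched, n_out = 60)
  as.numeric(tail(tr, 1)[, c("x_s", "x_g", "x_f")])
}

# nearest stable steady state (log-space) among rows of `stable_states`
nearest_state <- function(x, stable_states) {
  d <- apply(stable_states, 1, function(s) log_dist(x, as.numeric(s)))
  which.min(d)
}

#' Simulate a single signal pulse
#'
#' @param params A [triad_params][triad_parameters()] object.
#' @param axis `"notch"`, `"bmp4"` (OFF to ON) or `"eta"` (ON to OFF; the
#'   amplitude `a` is applied as `eta = 1/(1+a)`).
#' @param amplitude Pulse amplitude (>= 0); for `eta` see above.
#' @param duration Pulse duration in dimensionless time units.
#' @param relax Post-pulse relaxation time before basin classification.
#' @param t_acc_fraction Fraction of the ON-state Scl level whose first
#'   crossing defines the accumulation time `t_acc`.
#' @return A list of class `pulse_result`: `switched`, `final`,
#'   `trajectory`, `t_acc` (NA if never crossed), `duration`, `axis`,
#'   `amplitude`.
#' @export
simulate_pulse <- function(params, axis, amplitude, duration,
                           relax = 200, t_acc_fraction = 0.5) {
  axis <- match.arg(axis, c("notch", "bmp4", "eta"))
  baseline <- signal_input()
  oo <- off_on_states(params, baseline)
  from <- if (axis == "eta") oo$on else oo$off
  target <- if (axis == "eta") oo$off else oo$on
  amp <- if (axis == "eta") 1 / (1 + amplitude) else amplitude
  sched <- list(
    list(duration = duration, signal = signal_on_axis(axis, amp)),
    list(duration = relax, signal = baseline)
  )
  tr <- integrate_triad(params, from, sched, n_out = 400)
  final <- as.numeric(tail(tr, 1)[, c("x_s", "x_g", "x_f")])
  st <- dplyr::filter(oo$all, .data$stable)
  switched <- nearest_state(final, st[, c("x_s", "x_g", "x_f")]) ==
    nearest_state(target, st[, c("x_s", "x_g", "x_f")])
  thr <- t_acc_fraction * oo$on[1]
  crossed <- which(tr$x_s >= thr)
  t_acc <- if (axis != "eta" && length(crossed)) tr$time[crossed[1]] else NA_real_
  structure(list(switched = switched, final = final, trajectory = tr,
                 t_acc = t_acc, duration = duration, axis = axis,
                 amplitude = amplitude),
            class = "pulse_result")
}

#' @export
print.pulse_result <- function(x, ...) {
  cat("<pulse_result>", x$axis, "amplitude", format(x$amplitude),
      "duration", format(x$duration), "->",
      if (x$switched) "switched" else "not switched", "\n")
  invisible(x)
}

#' Minimum pulse duration for switching
#'
#' The shortest signal pulse that flips the triad between its stable
#' states: OFF to ON for Notch/Bmp4, ON to OFF for Gata1 (`eta` axis).
#' Basin membership is decided by integrating 200 time units after pulse
#' release and assigning the endpoint to the nearest stable steady state
#' in log space. Returns `Inf` when even a sustained signal of this
#' amplitude cannot switch the system. Bisection tolerance 0.01 time
#' units.
#'
#' @inheritParams simulate_pulse
#' @param d_max Largest pulse duration tried before declaring `Inf`.
#' @param tol Duration tolerance (dimensionless time).
#' @return A list: `duration` (dimensionless; `Inf` if unswitchable),
#'   `hours`, `axis`, `amplitude`.
#' @export
min_pulse_duration <- function(params, axis, amplitude, d_max = 100,
                               tol = 0.01, relax = 200) {
  axis <- match.arg(axis, c("notch", "bmp4", "eta"))
  baseline <- signal_input()
  oo <- off_on_states(params, baseline)
  from <- if (axis == "eta") oo$on else oo$off
  target <- if (axis == "eta") oo$off else oo$on
  amp <- if (axis == "eta") 1 / (1 + amplitude) else amplitude
  st <- as.matrix(dplyr::filter(oo$all, .data$stable)[, c("x_s", "x_g", "x_f")])
  target_i <- nearest_state(target, st)
  switched <- function(d) {
    xf <- pulse_final_state(params, axis, amp, d, from, baseline, relax)
    nearest_state(xf, st) == target_i
  }
  if (!switched(d_max)) {
    return(list(duration = Inf, hours = Inf, axis = axis,
                amplitude = amplitude))
  }
  lo <- 0; hi <- d_max
  # shrink hi quickly by geometric probing from 1 time unit
  probe <- 1
  while (probe < d_max && !switched(probe)) probe <- probe * 2
  hi <- min(probe, d_max); lo <- if (probe <= 1) 0 else probe / 2
  # resolve to the tighter of the absolute tolerance and 0.5% relative,
  # so that 0.99x/1.01x of the answer always bracket the true threshold
  while (hi - lo > min(tol, 0.005 * hi)) {
    mid <- (lo + hi) / 2
    if (switched(mid)) hi <- mid else lo <- mid
  }
  d <- (lo + hi) / 2
  list(duration = d, hours = d * params$hours_per_tau, axis = axis,
       amplitude = amplitude)
}

#' Minimum-pulse-duration filter curve
#'
#' Maps pulse amplitude to the minimum switching duration, quantifying
#' the low-pass filtering of transient signals: the curve is monotone
#' nonincreasing in amplitude and diverges as the amplitude approaches
#' the static switching threshold from above.
#'
#' @inheritParams min_pulse_duration
#' @param amplitudes Numeric amplitude grid.
#' @return A tibble of class `filter_curve`: `axis`, `amplitude`,
#'   `duration` (dimensionless) and `hours`.
#' @export
filter_curve <- function(params, axis, amplitudes, d_max = 100,
                         tol = 0.01) {
  out <- purrr::map_dfr(amplitudes, function(a) {
    r <- min_pulse_duration(params, axis, a, d_max = d_max, tol = tol)
    tibble(axis = axis, amplitude = a, duration = r$duration,
           hours = r$hours)
  })
  class(out) <- c("filter_curve", class(out))
  out
}

# Static switching threshold on an axis: the saddle-node signal value at
# which the branch the system starts on disappears (activation axes: the
# OFF branch as n/b increases; eta axis: the ON branch as eta decreases).
# The branch is continued by warm-started Newton refinement with an
# adaptive log-scale step: a step fails when Newton does not converge,
# lands on an unstable state (the branch has merged with the saddle), or
# jumps to a distant state; failed steps are halved, so the warm start
# stays glued to the branch right up to the fold.
static_threshold <- function(params, axis, hi = 1e4, rel_tol = 1e-5) {
  neutral <- signal_on_axis(axis, neutral_value(axis))
  ss <- find_steady_states(params, neutral)
  st <- dplyr::filter(ss, .data$stable)
  x <- if (axis == "eta") as.numeric(st[nrow(st), c("x_s", "x_g", "x_f")])
       else as.numeric(st[1, c("x_s", "x_g", "x_f")])
  branch_at <- function(v, x_ref) {
    res <- newton_refine(params, signal_on_axis(axis, v), x_ref)
    if (!res$converged || res$residual > 1e-10) return(NULL)
    if (log_dist(res$x, x_ref) > 0.7) return(NULL) # jumped branches
    sg <- signal_on_axis(axis, v)
    ev <- eigen(rhs_jacobian(params, sg, res$x, free_idx(params)),
                only.values = TRUE)$values
    if (max(Re(ev)) >= 0) return(NULL) # merged with the saddle
    res$x
  }
  # continuation in log10(signal); eta runs downward from 1
  v <- if (axis == "eta") 1 else 1e-3
  if (axis != "eta") {
    x0 <- branch_at(v, x)
    if (is.null(x0)) return(v) # branch already gone at negligible signal
    x <- x0
  }
  dir <- if (axis == "eta") -1 else 1
  h <- 0.25
  lim <- if (axis == "eta") 1e-6 else hi
  repeat {
    v_next <- v * 10^(dir * h)
    if ((axis == "eta" && v_next < lim) || (axis != "eta" && v_next > lim)) {
      return(NA_real_) # branch survives the whole scanned range
    }
    x_new <- branch_at(v_next, x)
    if (!is.null(x_new)) {
      v <- v_next; x <- x_new
      h <- min(h * 1.4, 0.25)
    } else {
      h <- h / 2
      if (h < rel_tol) return(v)
    }
  }
}

#' Match the reduced module's switching threshold to the full triad
#'
#' The reduced module clamps Scl at a constant (its enhancer feedback
#' removed). For a controlled comparison the clamp is chosen so the
#' reduced module's saddle-node threshold on the given axis equals the
#' full triad's, located by bisection on the clamp value. Activation
#' (Notch/Bmp4) and deactivation (`eta`) axes generally need different
#' clamps.
#'
#' @param params Full-triad [triad_params][triad_parameters()].
#' @param axis `"notch"`, `"bmp4"` or `"eta"`.
#' @param interval Search interval for the clamp value.
#' @param tol Relative tolerance on the clamp.
#' @return A list: `clamp`, `threshold_full`, `threshold_reduced`, `axis`.
#' @export
match_reduced_module <- function(params, axis, interval = c(0.01, 10),
                                 tol = 1e-3) {
  thr_full <- static_threshold(params, axis)
  if (!is.finite(thr_full)) {
    abort("Full triad has no switching threshold on this axis.")
  }
  thr_red <- function(cl) {
    red <- make_design(params, paste0("reduced:", cl))
    tryCatch(static_threshold(red, axis), error = function(e) NA_real_)
  }
  # higher clamped Scl -> easier activation (lower threshold); define a
  # signed discrepancy that is monotone in the clamp on each axis
  disc <- function(cl) {
    t <- thr_red(cl)
    if (!is.finite(t)) return(NA_real_)
    log(t) - log(thr_full)
  }
  # bracket by scanning, then uniroot on the log-threshold discrepancy
  cls <- exp(seq(log(interval[1]), log(interval[2]), length.out = 25))
  ds <- purrr::map_dbl(cls, disc)
  okv <- which(is.finite(ds))
  brk <- NULL
  for (i in head(okv, -1)) {
    j <- okv[which(okv > i)][1]
    if (!is.na(j) && ds[i] * ds[j] <= 0) { brk <- c(cls[i], cls[j]); break }
  }
  if (is.null(brk)) {
    abort("No clamp value in the interval matches the full-triad threshold.")
  }
  r <- uniroot(disc, brk, tol = tol * mean(brk))
  list(clamp = r$root, threshold_full = thr_full,
       threshold_reduced = thr_red(r$root), axis = axis)
}
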