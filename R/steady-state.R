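# ---- internal root-finding machinery -------------------------------------

# finite-difference Jacobian of the rhs restricted to the free components
rhs_jacobian <- function(params, signal, x, idx = free_idx(params)) {
  n <- length(idx)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * (1 + abs(x[idx[j]]))
    xp <- x; xp[idx[j]] <- x[idx[j]] + h
    xm <- x; xm[idx[j]] <- max(x[idx[j]] - h, 0)
    hh <- xp[idx[j]] - xm[idx[j]]
    J[, j] <- (triad_rhs(xp, signal, params)[idx] -
               triad_rhs(xm, signal, params)[idx]) / hh
  }
  J
}

# damped Newton iteration projected onto the nonnegative orthant
newton_refine <- function(params, signal, x0, tol = 1e-12, maxit = 60) {
  idx <- free_idx(params)
  x <- pmax(unname(unlist(x0)), 0)
  if (!is.na(params$clamp_scl)) x[1] <- params$clamp_scl
  r <- triad_rhs(x, signal, params)[idx]
  for (it in seq_len(maxit)) {
    nr <- sqrt(sum(r^2))
    if (nr < tol) return(list(x = x, residual = nr, converged = TRUE))
    J <- rhs_jacobian(params, signal, x, idx)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(x = x, residual = nr, converged = FALSE))
    }
    lam <- 1
    repeat {
      xn <- x
      xn[idx] <- pmax(x[idx] + lam * step, 0)
      rn <- triad_rhs(xn, signal, params)[idx]
      if (sqrt(sum(rn^2)) < nr || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && sqrt(sum(rn^2)) >= nr) {
      return(list(x = x, residual = nr, converged = nr < tol))
    }
    x <- xn; r <- rn
  }
  nr <- sqrt(sum(r^2))
  list(x = x, residual = nr, converged = nr < tol)
}

# stability from Jacobian eigenvalue real parts; ambiguous cases resolved
# by short perturbed integration
classify_stability <- function(params, signal, x, margin = 1e-8) {
  idx <- free_idx(params)
  ev <- eigen(rhs_jacobian(params, signal, x, idx), only.values = TRUE)$values
  m <- max(Re(ev))
  if (m < -margin) return(TRUE)
  if (m > margin) return(FALSE)
  # marginal: perturb and integrate
  xp <- x
  xp[idx] <- x[idx] * (1 + 1e-3) + 1e-6
  tr <- integrate_triad(params, xp, signal, horizon = 50)
  xe <- as.numeric(tail(tr, 1)[, c("x_s", "x_g", "x_f")])
  max(abs(xe[idx] - x[idx]) / (1 + abs(x[idx]))) < 1e-3
}

log_dist <- function(a, b, eps = 1e-8) {
  max(abs(log(a + eps) - log(b + eps)))
}

default_starts <- function(params) {
  g <- c(1e-4, 1e-2, 1e-1, 1, 10)
  idx <- free_idx(params)
  if (length(idx) == 3L) {
    as.matrix(expand.grid(g, g, g))
  } else {
    cbind(params$clamp_scl, as.matrix(expand.grid(g, g)))
  }
}

#' Locate and classify all steady states of the triad system
#'
#' Multi-start Newton refinement from a log-spaced grid of initial states
#' (1e-4 to 10 per axis) plus the endpoints of forward integrations from
#' representative corners, deduplicated at a relative merge radius, with
#' stability assigned from the Jacobian eigenvalues (marginal cases
#' resolved by perturbed simulation).
#'
#' @param params A [triad_params][triad_parameters()] object.
#' @param signal A [signal_input()].
#' @param starts Optional matrix of additional starting states (rows).
#' @param tol Residual norm required of a reported steady state.
#' @return A tibble of class `steady_states` with columns `x_s`, `x_g`,
#'   `x_f`, `stable`, `residual`, sorted by `x_g`.
#' @export
find_steady_states <- function(params, signal = signal_input(),
                               starts = NULL, tol = 1e-10) {
  S <- default_starts(params)
  if (!is.null(starts)) S <- rbind(S, as.matrix(starts))
  # forward-integration endpoints catch attractors the grid misses
  idx <- free_idx(params)
  for (x0 in list(rep(1e-4, 3), c(1, 1, 1), rep(10, 3))) {
    x0i <- x0
    if (!is.na(params$clamp_scl)) x0i[1] <- params$clamp_scl
    tr <- integrate_triad(params, x0i, signal, horizon = 400)
    S <- rbind(S, as.numeric(tail(tr, 1)[, c("x_s", "x_g", "x_f")]))
  }
  found <- list()
  for (i in seq_len(nrow(S))) {
    x0 <- as.numeric(S[i, ])
    if (length(x0) == 2L) x0 <- c(params$clamp_scl, x0)
    res <- newton_refine(params, signal, x0)
    if (!res$converged || res$residual >= tol) next
    dup <- purrr::some(found, ~ log_dist(.x$x, res$x) < 1e-4)
    if (!dup) found <- c(found, list(res))
  }
  if (!length(found)) {
    abort("No steady state converged from any start.",
          class = "triadswitch_no_steady_state")
  }
  # a bistable set must hold a saddle between the attractors; if the grid
  # missed it, seed extra starts along log-space chords of state pairs
  stab <- purrr::map_lgl(found, ~ classify_stability(params, signal, .x$x))
  if (sum(stab) >= 2L && !any(!stab)) {
    xs <- purrr::map(found[stab], "x")
    for (i in seq_along(xs)) for (j in seq_len(i - 1L)) {
      for (t in c(0.3, 0.5, 0.7)) {
        x0 <- exp((1 - t) * log(xs[[i]] + 1e-8) + t * log(xs[[j]] + 1e-8))
        res <- newton_refine(params, signal, x0)
        if (res$converged && res$residual < tol &&
            !purrr::some(found, ~ log_dist(.x$x, res$x) < 1e-4)) {
          found <- c(found, list(res))
        }
      }
    }
  }
  out <- purrr::map_dfr(found, function(f) {
    tibble(x_s = f$x[1], x_g = f$x[2], x_f = f$x[3],
           stable = classify_stability(params, signal, f$x),
           residual = f$residual)
  })
  out <- dplyr::arrange(out, .data$x_g)
  class(out) <- c("steady_states", class(out))
  out
}

signal_on_axis <- function(axis, value) {
  switch(axis,
    notch = signal_input(n = value),
    bmp4  = signal_input(b = value),
    eta   = signal_input(eta = value),
    abort("`axis` must be one of 'notch', 'bmp4', 'eta'.")
  )
}

neutral_value <- function(axis) if (axis == "eta") 1 else 0

#' Trace the steady-state response along a signal axis
#'
#' Computes the full steady-state set at every grid value of one signal
#' (the other signals held at their neutral values: Notch and Bmp4 at
#' zero, `eta` at 1) and classifies the response:
#' * `irreversible_bistable` — two stable states coexist at the neutral
#'   signal value (the ON state persists after the signal is gone);
#' * `reversible_bistable` — two stable states coexist somewhere on the
#'   axis but not at the neutral value;
#' * `monostable` — never more than one stable state.
#'
#' Saddle-node thresholds (signal values where the stable-state count
#' changes) are bracketed on the grid and refined by bisection.
#'
#' @param params A [triad_params][triad_parameters()] object.
#' @param axis `"notch"`, `"bmp4"` or `"eta"`.
#' @param grid Signal grid; the neutral value is prepended if absent.
#'   Default: 25 log-spaced Notch/Bmp4 values in `[1e-3, 1e3]`, or 25
#'   descending `eta` values in `[1, 0.01]`.
#' @param refine_tol Relative bisection tolerance for thresholds.
#' @return An object of class `triad_response`: a list with `axis`,
#'   `curve` (tibble: signal value, state, stability), `classification`
#'   and `thresholds`.
#' @export
trace_response <- function(params, axis = c("notch", "bmp4", "eta"),
                           grid = NULL, refine_tol = 1e-3) {
  axis <- match.arg(axis)
  if (is.null(grid)) {
    grid <- if (axis == "eta") {
      exp(seq(log(1), log(0.01), length.out = 25))
    } else {
      c(0, 10^seq(-3, 3, length.out = 24))
    }
  }
  nv <- neutral_value(axis)
  if (!any(abs(grid - nv) < 1e-12)) grid <- c(nv, grid)
  grid <- if (axis == "eta") sort(unique(grid), decreasing = TRUE) else
    sort(unique(grid))
  sets <- purrr::map(grid, function(v) {
    find_steady_states(params, signal_on_axis(axis, v))
  })
  curve <- purrr::map2_dfr(grid, sets, function(v, s) {
    dplyr::mutate(s, signal = v, .before = 1)
  })
  n_stable <- purrr::map_int(sets, ~ sum(.x$stable))
  max_stable <- max(n_stable)
  neutral_i <- which(abs(grid - nv) < 1e-12)[1]
  classification <- if (max_stable >= 2L) {
    if (n_stable[neutral_i] >= 2L) "irreversible_bistable" else
      "reversible_bistable"
  } else "monostable"
  # bracket stable-count changes and refine by bisection
  thresholds <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (n_stable[i] != n_stable[i + 1]) {
      lo <- grid[i]; hi <- grid[i + 1]
      cnt <- function(v) sum(find_steady_states(params,
                                                signal_on_axis(axis, v))$stable)
      target <- n_stable[i]
      for (k in 1:25) {
        mid <- if (axis == "eta" || lo == 0) (lo + hi) / 2 else
          sqrt(lo * hi)
        if (cnt(mid) == target) lo <- mid else hi <- mid
        if (abs(hi - lo) <= refine_tol * (abs(hi) + refine_tol)) break
      }
      thresholds <- c(thresholds, (lo + hi) / 2)
    }
  }
  structure(
    list(axis = axis, curve = curve, classification = classification,
         thresholds = thresholds, n_stable = n_stable, grid = grid),
    class = "triad_response"
  )
}

#' @export
print.triad_response <- function(x, ...) {
  cat("<triad_response> axis:", x$axis, " classification:",
      x$classification, "\n")
  if (length(x$thresholds)) {
    cat("  saddle-node threshold(s):",
        paste(signif(x$thresholds, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a traced response curve
#'
#' @param x A `triad_response` from [trace_response()].
#' @param ... Unused.
#' @return Tibble: `axis`, `signal`, `x_s`, `x_g`, `x_f`, `stable`.
#' @export
tidy.triad_response <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$curve, "signal", "x_s", "x_g", "x_f", "stable"),
    axis = x$axis, .before = 1
  )
}

#' One-row summary of a traced response curve
#' @param x A `triad_response`.
#' @param ... Unused.
#' @return Tibble with `axis`, `classification`, threshold count and the
#'   first threshold (NA if none).
#' @export
glance.triad_response <- function(x, ...) {
  tibble(axis = x$axis, classification = x$classification,
         n_thresholds = length(x$thresholds),
         threshold = if (length(x$thresholds)) x$thresholds[1] else NA_real_)
}

# OFF/ON identification at a given signal: OFF = stable state with the
# lowest x_g, ON = stable state with the highest x_g
off_on_states <- function(params, signal = signal_input()) {
  ss <- find_steady_states(params, signal)
  st <- dplyr::filter(ss, .data$stable)
  if (nrow(st) < 2L) {
    abort("System is not bistable at this signal; no distinct OFF/ON states.",
          class = "triadswitch_not_bistable")
  }
  list(off = as.numeric(st[1, c("x_s", "x_g", "x_f")]),
       on = as.numeric(st[nrow(st), c("x_s", "x_g", "x_f")]),
       all = ss)
}

# does a sustained signal drive the system from `from` into the basin of
# `target` (classified after release at the baseline signal)?
sustained_switches <- function(params, axis, amplitude, from, target,
                               baseline = NULL, drive = 60) {
  baseline <- baseline %||% signal_input(eta = 1)
  tr <- integrate_triad(params, from, signal_on_axis(axis, amplitude),
                        horizon = drive)
  xe <- as.numeric(tail(tr, 1)[, c("x_s", "x_g", "x_f")])
  tr2 <- integrate_triad(params, xe, baseline, horizon = 200)
  xf <- as.numeric(tail(tr2, 1)[, c("x_s", "x_g", "x_f")])
  log_dist(xf, target) < 0.5 * log_dist(from, target)
}

#' Scan chromatin-constant space for switchability
#'
#' At each `(K_g, K_f)` grid point the free energies are refit exactly
#' from the reporter tables, the omegas recalibrated, and the rebuilt
#' triad classified by whether physiological Notch and/or Bmp4
#' (amplitude `signal_max`) can move it from the OFF basin into the ON
#' basin. Grid points whose `K` falls below the feasibility bound are
#' marked infeasible.
#'
#' @param data Reporter table covering all three enhancers.
#' @param K_s Fixed chromatin constant for Scl+19.
#' @param K_g_grid,K_f_grid Numeric grids for the Gata2-3 and Fli1+12
#'   chromatin constants.
#' @param signal_max Largest physiological signal amplitude (default 1e3).
#' @param ... Passed to [triad_parameters()].
#' @return Tibble: `K_g`, `K_f`, `notch_switches`, `bmp4_switches`,
#'   `outcome` in `{both_switch, notch_only, bmp4_only, neither,
#'   infeasible, not_bistable}`.
#' @export
switchability_scan <- function(data, K_s, K_g_grid, K_f_grid,
                               signal_max = 1e3, ...) {
  grid <- tidyr::expand_grid(K_g = K_g_grid, K_f = K_f_grid)
  bounds <- c(
    g = feasibility_bound(prepare_table(data, "gata2m3")),
    f = feasibility_bound(prepare_table(data, "fli1p12"))
  )
  purrr::pmap_dfr(grid, function(K_g, K_f) {
    row <- tibble(K_g = K_g, K_f = K_f, notch_switches = NA,
                  bmp4_switches = NA, outcome = "infeasible")
    if (K_g <= bounds["g"] || K_f <= bounds["f"]) return(row)
    params <- tryCatch(
      build_triad(data, K = c(scl19 = K_s, gata2m3 = K_g, fli1p12 = K_f), ...),
      error = function(e) NULL
    )
    if (is.null(params)) return(row)
    oo <- tryCatch(off_on_states(params), error = function(e) NULL)
    if (is.null(oo)) { row$outcome <- "not_bistable"; return(row) }
    ns <- sustained_switches(params, "notch", signal_max, oo$off, oo$on)
    bs <- sustained_switches(params, "bmp4", signal_max, oo$off, oo$on)
    row$notch_switches <- ns
    row$bmp4_switches <- bs
    row$outcome <- if (ns && bs) "both_switch" else if (ns) "notch_only"
      else if (bs) "bmp4_only" else "neither"
    row
  })
}
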