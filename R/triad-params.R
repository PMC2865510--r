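#' Degradation-rate ratios from protein half-lives
#'
#' Time is normalized by the Scl degradation timescale, so the
#' dimensionless decay rates are the half-life ratios
#' `gamma_i = t_half(Scl) / t_half(i)` with `gamma_s = 1`. With the
#' measured half-lives (Scl 8 h, Gata2 ~10 min, Fli1 2 h) this gives
#' `(1, 48, 4)`: Gata2 is by far the least stable protein and Scl the
#' most stable.
#'
#' @param half_lives Numeric vector of three half-lives in hours, order
#'   (Scl, Gata2, Fli1). Default `c(8, 1/6, 2)`.
#' @return Named vector `c(s = 1, g = ..., f = ...)`.
#' @export
derive_gammas <- function(half_lives = c(8, 1 / 6, 2)) {
  if (length(half_lives) != 3L || any(!is.finite(half_lives)) ||
      any(half_lives <= 0)) {
    abort("`half_lives` must be three positive numbers (hours).")
  }
  setNames(half_lives[1] / half_lives, c("s", "g", "f"))
}

# flatten an enhancer_model into plain vectors/matrices for the ODE
# right-hand side (tibble access is too slow inside integrators)
compile_model <- function(model) {
  cf <- model$configurations
  list(
    w = cf$weight,
    e_s = cf$scl, e_g = cf$gata2, e_f = cf$fli1,
    K = model$K,
    has_n = "notch" %in% model$cofactors,
    has_b = "bmp4" %in% model$cofactors,
    wn = if ("notch" %in% model$cofactors) model$omega[["notch"]] else 1,
    wb = if ("bmp4" %in% model$cofactors) model$omega[["bmp4"]] else 1,
    eta_applies = model$key == "gata2m3"
  )
}

f_compiled <- function(cm, x, n, b, eta) {
  Z <- sum(cm$w * x[1]^cm$e_s * x[2]^cm$e_g * x[3]^cm$e_f)
  nn <- if (cm$has_n) n else 0
  bb <- if (cm$has_b) b else 0
  et <- if (cm$eta_applies) eta else 1
  et * (1 + Z) * (1 + cm$wn * nn + cm$wb * bb) /
    (cm$K - 1 + (1 + Z) * (1 + nn + bb))
}

#' Assemble the dimensionless triad ODE parameter set
#'
#' Combines the three fitted enhancer models into the complete parameter
#' set of the dimensionless ODE system
#' \deqn{dx_i/d\tau = \gamma_i (f_i(x, signal) / f_i^{wt} - x_i)}
#' where `f_i^wt` is each gene's transcription factor at the wild-type
#' state `(1,1,1)` with zero signal, so the wild-type state is always a
#' zero-signal steady state.
#'
#' @param scl19,gata2m3,fli1p12 Fitted [enhancer_model()] objects (with
#'   omegas calibrated, see [calibrate_omegas()]).
#' @param half_lives Protein half-lives in hours (Scl, Gata2, Fli1); see
#'   [derive_gammas()].
#' @param time_unit `"mean_lifetime"` (default; one time unit equals the
#'   Scl mean lifetime, half-life / ln 2 ~ 11.54 h) or `"half_life"` (one
#'   time unit equals the 8 h Scl half-life). Only the hour conversion of
#'   reported durations depends on this choice.
#' @return An object of class `triad_params`.
#' @export
triad_parameters <- function(scl19, gata2m3, fli1p12,
                             half_lives = c(8, 1 / 6, 2),
                             time_unit = c("mean_lifetime", "half_life")) {
  time_unit <- match.arg(time_unit)
  models <- list(scl19 = scl19, gata2m3 = gata2m3, fli1p12 = fli1p12)
  ok <- purrr::map2_lgl(models, names(models),
                        ~ inherits(.x, "enhancer_model") && .x$key == .y)
  if (!all(ok)) {
    abort("Arguments must be enhancer_model objects for Scl+19, Gata2-3, Fli1+12 in order.")
  }
  gamma <- derive_gammas(half_lives)
  zero <- signal_input()
  wt <- purrr::map_dbl(models, ~ transcription_factor(.x, triad_state(), zero))
  if (any(wt <= 0)) abort("Wild-type transcription factors must be > 0.")
  structure(
    list(
      models = models,
      compiled = purrr::map(models, compile_model),
      gamma = gamma,
      wt_rates = setNames(unname(wt), c("s", "g", "f")),
      production_scale = c(s = 1, g = 1, f = 1),
      clamp_scl = NA_real_,
      half_lives = half_lives,
      time_unit = time_unit,
      hours_per_tau = if (time_unit == "mean_lifetime")
        half_lives[1] / log(2) else half_lives[1],
      design = "wildtype"
    ),
    class = "triad_params"
  )
}

#' @export
print.triad_params <- function(x, ...) {
  cat("<triad_params> design:", x$design, "\n")
  cat("  gamma = (", paste(format(x$gamma), collapse = ", "), ")\n")
  cat("  f_wt  = (", paste(format(x$wt_rates, digits = 4), collapse = ", "), ")\n")
  cat("  K     = (", paste(format(purrr::map_dbl(x$models, "K"), digits = 5),
                           collapse = ", "), ")\n")
  if (!is.na(x$clamp_scl)) cat("  Scl clamped at", x$clamp_scl, "\n")
  ps <- x$production_scale
  if (any(ps != 1)) cat("  production scale:",
                        paste(names(ps), ps, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Right-hand side of the dimensionless triad ODE system
#'
#' @param state Length-3 state `(x_s, x_g, x_f)`.
#' @param signal A [signal_input()].
#' @param params A [triad_params][triad_parameters()] object.
#' @return Named rate vector `(dx_s, dx_g, dx_f)` per dimensionless time.
#' @export
triad_rhs <- function(state, signal, params) {
  x <- unname(unlist(state))
  if (length(x) != 3L || any(!is.finite(x)) || any(x < -1e-8)) {
    abort("State must be 3 finite components >= 0.")
  }
  x <- pmax(x, 0) # absorb integrator round-off below zero
  if (!is.na(params$clamp_scl)) x[1] <- params$clamp_scl
  f <- c(
    f_compiled(params$compiled$scl19,   x, signal$n, signal$b, signal$eta),
    f_compiled(params$compiled$gata2m3, x, signal$n, signal$b, signal$eta),
    f_compiled(params$compiled$fli1p12, x, signal$n, signal$b, signal$eta)
  )
  d <- params$gamma * (params$production_scale * f / params$wt_rates - x)
  if (!is.na(params$clamp_scl)) d[1] <- 0
  setNames(d, c("x_s", "x_g", "x_f"))
}

# indices of dynamical (non-clamped) state components
free_idx <- function(params) if (is.na(params$clamp_scl)) 1:3 else 2:3

#' Enumerate the studied enhancer-site-deletion module designs
#'
#' The ten single- and double-site-deletion designs analyzed for the
#' triad: both Scl+19 sites, the three Gata2-3 sites, one representative
#' Scl+19/Gata2-3 double deletion (six designs touching the Scl+19 or
#' Gata2-3 enhancers), and the four Fli1+12 single-site deletions.
#'
#' @return A tibble with columns `design` (string key usable with
#'   [make_design()]), `enhancer`, `sites` (list-column) and `group`
#'   (`"scl19_gata2m3"` or `"fli1p12"`).
#' @export
enumerate_mutant_designs <- function() {
  tibble(
    design = c("scl19:dGATA", "scl19:dETS",
               "gata2m3:dGATA", "gata2m3:dETS", "gata2m3:dEBOX",
               "scl19:dGATA+gata2m3:dGATA",
               "fli1p12:dEBOX", "fli1p12:dsGATA", "fli1p12:dETS",
               "fli1p12:dpGATA"),
    enhancer = c("Scl+19", "Scl+19", "Gata2-3", "Gata2-3", "Gata2-3",
                 "Scl+19 & Gata2-3", "Fli1+12", "Fli1+12", "Fli1+12",
                 "Fli1+12"),
    sites = list("GATA", "ETS", "GATA", "ETS", "EBOX",
                 c("GATA", "GATA"), "EBOX", "sGATA", "ETS", "pGATA"),
    group = c(rep("scl19_gata2m3", 6), rep("fli1p12", 4))
  )
}

parse_design_key <- function(key) {
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  purrr::map(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(bits) != 2L) abort(paste0("Malformed design key: '", p, "'"))
    list(target = bits[1], detail = bits[2])
  })
}

#' Derive a mutant or reduced module from wild-type parameters
#'
#' Supported design keys (combined with `+`):
#' * `"<enhancer>:d<SITE>"` — delete a binding site from `scl19`,
#'   `gata2m3` or `fli1p12` (e.g. `"fli1p12:dEBOX"`); every configuration
#'   requiring the site is removed.
#' * `"ko:<Gene>"` — knockout: zero the gene's production
#'   (`Scl`, `Gata2` or `Fli1`).
#' * `"het:<Gene>"` — heterozygote: halve the gene's production.
#' * `"reduced:<value>"` — reduced module: clamp `x_s` at the value
#'   (Scl put under external control; its ODE is dropped).
#'
#' Wild-type normalization constants `f_i^wt` are retained, so mutants
#' need not have `(1,1,1)` as a steady state; all other parameters keep
#' their full-triad values.
#'
#' @param params A [triad_params][triad_parameters()] object.
#' @param design Design key string (see above), or one row of
#'   [enumerate_mutant_designs()].
#' @return Modified `triad_params`.
#' @export
make_design <- function(params, design) {
  if (is.data.frame(design)) design <- design$design[[1]]
  genes <- c(Scl = "s", Gata2 = "g", Fli1 = "f")
  for (op in parse_design_key(design)) {
    if (op$target %in% c("scl19", "gata2m3", "fli1p12")) {
      site <- sub("^d", "", op$detail)
      params$models[[op$target]] <- delete_sites(params$models[[op$target]], site)
      params$compiled[[op$target]] <- compile_model(params$models[[op$target]])
    } else if (op$target == "ko") {
      if (!op$detail %in% names(genes)) abort(paste0("Unknown gene: ", op$detail))
      params$production_scale[[genes[[op$detail]]]] <- 0
    } else if (op$target == "het") {
      if (!op$detail %in% names(genes)) abort(paste0("Unknown gene: ", op$detail))
      params$production_scale[[genes[[op$detail]]]] <- 0.5
    } else if (op$target == "reduced") {
      v <- suppressWarnings(as.numeric(op$detail))
      if (!is.finite(v) || v < 0) abort("reduced:<value> needs a nonnegative number.")
      params$clamp_scl <- v
    } else {
      abort(paste0("Unknown design target: '", op$target, "'"))
    }
  }
  params$design <- if (identical(params$design, "wildtype")) design else
    paste(params$design, design, sep = "+")
  params
}

#' One-row summary of a triad parameter set
#'
#' @param x A `triad_params` object.
#' @param ... Unused.
#' @return A tibble with the design label, gammas, chromatin constants,
#'   calibrated omegas and wild-type rates.
#' @export
glance.triad_params <- function(x, ...) {
  tibble(
    design = x$design,
    gamma_g = unname(x$gamma["g"]), gamma_f = unname(x$gamma["f"]),
    K_s = x$models$scl19$K, K_g = x$models$gata2m3$K, K_f = x$models$fli1p12$K,
    omega_notch = x$models$gata2m3$omega[["notch"]],
    omega_bmp4_gata2 = x$models$gata2m3$omega[["bmp4"]],
    omega_bmp4_fli1 = x$models$fli1p12$omega[["bmp4"]],
    hours_per_tau = x$hours_per_tau
  )
}
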