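#' Enhancer binding-site inventories and configuration topologies
#'
#' Each triad enhancer admits a small set of transcriptional-regulator (TR)
#' binding configurations that measurably affect reporter expression:
#'
#' * `Scl+19` (sites GATA, ETS): Gata2 bound (`G`), Fli1 dimer bound (`FF`),
#'   both (`G.FF`).
#' * `Gata2-3` (sites GATA, ETS, EBOX): `G`, `FF`, `G.FF`, and the full
#'   Scl-Gata2-Fli1 complex (`S.G.FF`).
#' * `Fli1+12` (sites pGATA, ETS, EBOX, sGATA): `G` (primary GATA), `FF`,
#'   `G.FF`, and the Gata2-Scl-Fli1-Gata2 complex (`G.S.FF.G`).
#'
#' Fli1 always binds as a dimer, so its copy number is even and its
#' concentration enters configuration weights quadratically.
#'
#' @param enhancer `"scl19"`, `"gata2m3"` or `"fli1p12"` (full names
#'   `"Scl+19"` etc. also accepted).
#' @return A tibble with one row per configuration: `id`, copy numbers
#'   `scl`, `gata2`, `fli1`, and `sites` (list-column of required intact
#'   binding sites).
#' @export
enhancer_topology <- function(enhancer) {
  key <- enhancer_key(enhancer)
  switch(key,
    scl19 = tibble(
      id    = c("G", "FF", "G.FF"),
      scl   = c(0L, 0L, 0L),
      gata2 = c(1L, 0L, 1L),
      fli1  = c(0L, 2L, 2L),
      sites = list("GATA", "ETS", c("GATA", "ETS"))
    ),
    gata2m3 = tibble(
      id    = c("G", "FF", "G.FF", "S.G.FF"),
      scl   = c(0L, 0L, 0L, 1L),
      gata2 = c(1L, 0L, 1L, 1L),
      fli1  = c(0L, 2L, 2L, 2L),
      sites = list("GATA", "ETS", c("GATA", "ETS"), c("EBOX", "GATA", "ETS"))
    ),
    fli1p12 = tibble(
      id    = c("G", "FF", "G.FF", "G.S.FF.G"),
      scl   = c(0L, 0L, 0L, 1L),
      gata2 = c(1L, 0L, 1L, 2L),
      fli1  = c(0L, 2L, 2L, 2L),
      sites = list("pGATA", "ETS", c("pGATA", "ETS"),
                   c("pGATA", "EBOX", "ETS", "sGATA"))
    )
  )
}

#' Binding sites present in each enhancer
#' @inheritParams enhancer_topology
#' @return Character vector of site names.
#' @export
enhancer_sites <- function(enhancer) {
  switch(enhancer_key(enhancer),
    scl19   = c("GATA", "ETS"),
    gata2m3 = c("GATA", "ETS", "EBOX"),
    fli1p12 = c("pGATA", "ETS", "EBOX", "sGATA")
  )
}

#' Construct a statistical-thermodynamic enhancer model
#'
#' An enhancer model holds the Boltzmann weights of the TR-binding
#' configurations of one enhancer (at the wild-type reference
#' concentrations, so each weight is `exp(-dG)` with `dG` the
#' concentration-adjusted free energy in units of `1/beta`), the chromatin
#' open/closed equilibrium constant `K` (equal to the maximum possible
#' fold enhancement), and the polymerase-cofactor interaction factors
#' `omega` for any promoter cofactors (Notch and/or Bmp4) acting at the
#' gene's promoter.
#'
#' @param enhancer Enhancer name (see [enhancer_topology()]).
#' @param weights Named numeric vector of nonnegative configuration
#'   weights; names must match the configuration ids of the topology.
#'   Missing configurations get weight 0.
#' @param K Chromatin equilibrium constant, must exceed 1.
#' @param omega Named numeric vector of polymerase-interaction factors for
#'   the enhancer's cofactors, e.g. `c(notch = 3.3, bmp4 = 3.8)`. Defaults
#'   to 1 (neutral) for each cofactor.
#' @return An object of class `enhancer_model`.
#' @export
enhancer_model <- function(enhancer, weights, K, omega = NULL) {
  key <- enhancer_key(enhancer)
  topo <- enhancer_topology(key)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 1) {
    abort("`K` must be a single finite number > 1.")
  }
  w <- setNames(rep(0, nrow(topo)), topo$id)
  if (!is.null(names(weights)) && length(weights)) {
    bad <- setdiff(names(weights), topo$id)
    if (length(bad)) {
      abort(paste0("Unknown configuration id(s) for ", .enhancer_keys[[key]],
                   ": ", paste(bad, collapse = ", ")))
    }
    w[names(weights)] <- unname(weights)
  } else if (length(weights) == nrow(topo)) {
    w[] <- weights
  } else if (length(weights)) {
    abort("`weights` must be named or have one value per configuration.")
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("Configuration weights must be finite and >= 0.")
  }
  cof <- switch(key, scl19 = character(), gata2m3 = c("notch", "bmp4"),
                fli1p12 = "bmp4")
  om <- setNames(rep(1, length(cof)), cof)
  if (!is.null(omega)) {
    keep <- intersect(names(omega), cof)
    om[keep] <- unname(omega[keep])
    if (any(om <= 0)) abort("`omega` factors must be > 0.")
  }
  topo$weight <- unname(w)
  structure(
    list(name = unname(.enhancer_keys[[key]]), key = key,
         configurations = topo, K = K, cofactors = cof, omega = om),
    class = "enhancer_model"
  )
}

#' @export
print.enhancer_model <- function(x, ...) {
  cat("<enhancer_model> ", x$name, "  (K = ", format(x$K), ")\n", sep = "")
  df <- dplyr::mutate(
    dplyr::select(x$configurations, "id", "scl", "gata2", "fli1", "weight"),
    energy = ifelse(.data$weight > 0, -log(.data$weight), Inf)
  )
  print(as.data.frame(df), row.names = FALSE)
  if (length(x$omega)) {
    cat("omega:", paste(names(x$omega), format(x$omega), sep = " = ",
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dimensionless triad state
#'
#' Concentrations of Scl, Gata2 and Fli1 normalized by their wild-type HSC
#' steady-state values, so the wild-type reference state is `(1, 1, 1)`.
#'
#' @param x_s,x_g,x_f Nonnegative dimensionless concentrations.
#' @return Named numeric vector `c(x_s, x_g, x_f)`.
#' @export
triad_state <- function(x_s = 1, x_g = 1, x_f = 1) {
  x <- c(x_s = x_s, x_g = x_g, x_f = x_f)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("State components must be finite and >= 0.")
  }
  x
}

#' Promoter signal input
#'
#' @param n Notch concentration normalized by its promoter dissociation
#'   constant (>= 0).
#' @param b Bmp4 likewise (>= 0).
#' @param eta Gata1 repression factor in (0, 1]; `eta = 1` means no Gata1.
#'   Gata1 lowers RNA-polymerase recruitment at the Gata2 promoter, so
#'   `eta` multiplies the Gata2 transcription factor only.
#' @return Named list with elements `n`, `b`, `eta`.
#' @export
signal_input <- function(n = 0, b = 0, eta = 1) {
  if (!is.finite(n) || n < 0 || !is.finite(b) || b < 0) {
    abort("`n` and `b` must be finite and >= 0.")
  }
  if (!is.finite(eta) || eta <= 0 || eta > 1) {
    abort("`eta` must lie in (0, 1].")
  }
  list(n = n, b = b, eta = eta)
}

as_state <- function(state) {
  x <- unname(unlist(state))
  if (length(x) != 3L) abort("A triad state has exactly 3 components.")
  if (any(!is.finite(x)) || any(x < 0)) abort("State components must be >= 0.")
  x
}

#' Sum of bound-configuration Boltzmann weights
#'
#' The open-chromatin partition function over TR-bound configurations,
#' `Z_b = sum_c w_c * x_s^a_c * x_g^g_c * x_f^d_c`, with the empty open
#' state contributing the reference weight 1 separately.
#'
#' @param model An [enhancer_model()].
#' @param state A [triad_state()] (or any nonnegative length-3 vector,
#'   order `x_s, x_g, x_f`).
#' @return A single nonnegative number.
#' @export
bound_weight_sum <- function(model, state) {
  x <- as_state(state)
  cf <- model$configurations
  # 0^0 == 1 in R, so zero concentrations with zero stoichiometry are safe
  sum(cf$weight * x[1]^cf$scl * x[2]^cf$gata2 * x[3]^cf$fli1)
}

#' Fold enhancement of reporter expression over the enhancerless construct
#'
#' Under the chromatin-ratchet mechanism the enhancer raises expression by
#' shifting the closed/open equilibrium: `F = K (1 + Z_b) / (K + Z_b)`.
#' `F = 1` when no TR binds (`Z_b = 0`) and `F -> K` at saturation, so the
#' chromatin constant `K` is the maximum possible fold enhancement.
#'
#' @inheritParams bound_weight_sum
#' @return Fold enhancement in `[1, K)`.
#' @export
fold_enhancement <- function(model, state) {
  Z <- bound_weight_sum(model, state)
  model$K * (1 + Z) / (model$K + Z)
}

#' Dimensionless transcription factor of a triad gene
#'
#' The cumulative regulatory effect of the enhancer-bound TRs and any
#' promoter cofactors on the probability of RNA-polymerase binding:
#' \deqn{f = \eta_{eff} \frac{(1 + Z_b)(1 + \omega_N n + \omega_B b)}
#'   {K - 1 + (1 + Z_b)(1 + n + b)}}
#' with the Notch/Bmp4 terms present only for the enhancer's cofactors
#' (Gata2-3: both; Fli1+12: Bmp4; Scl+19: none) and `eta` applied only to
#' Gata2-3. At zero signal `f = F / K` with `F` the fold enhancement.
#'
#' @inheritParams bound_weight_sum
#' @param signal A [signal_input()].
#' @return A positive number.
#' @export
transcription_factor <- function(model, state, signal = signal_input()) {
  Z <- bound_weight_sum(model, state)
  has_n <- "notch" %in% model$cofactors
  has_b <- "bmp4" %in% model$cofactors
  n <- if (has_n) signal$n else 0
  b <- if (has_b) signal$b else 0
  wn <- if (has_n) model$omega[["notch"]] else 1
  wb <- if (has_b) model$omega[["bmp4"]] else 1
  eta <- if (model$key == "gata2m3") signal$eta else 1
  eta * (1 + Z) * (1 + wn * n + wb * b) /
    (model$K - 1 + (1 + Z) * (1 + n + b))
}

#' Calibrate promoter cofactor interaction factors
#'
#' Sets `omega` so that a saturating cofactor signal raises the gene's
#' transcription output at the wild-type state by exactly the given fold:
#' since `f(n -> Inf) = omega_N` and `f(0) = (1+Z)/(K+Z)`, the calibration
#' is `omega = fold * (1+Z)/(K+Z)` (and likewise for Bmp4). Wild-type
#' Gata2 output rises 3.5-fold under saturating Notch and 4-fold under
#' saturating Bmp4, the defaults used throughout.
#'
#' @param model An [enhancer_model()] with at least one cofactor.
#' @param wt_state The wild-type reference state, `(1, 1, 1)`.
#' @param fold_notch,fold_bmp4 Target saturating-signal fold increases
#'   (> 1 for activation; used only if the corresponding cofactor acts at
#'   this promoter).
#' @return The model with calibrated `omega`.
#' @export
calibrate_omegas <- function(model, wt_state = triad_state(),
                             fold_notch = 3.5, fold_bmp4 = 4) {
  Z <- bound_weight_sum(model, wt_state)
  ratio <- (1 + Z) / (model$K + Z)
  for (cof in model$cofactors) {
    fold <- switch(cof, notch = fold_notch, bmp4 = fold_bmp4)
    if (!is.finite(fold) || fold <= 0) {
      abort("Calibration folds must be positive.")
    }
    om <- fold * ratio
    if (om <= 0) abort("Infeasible cofactor calibration (omega <= 0).")
    if (om <= 1) {
      warn(paste0("Calibrated omega for ", cof, " at ", model$name,
                  " is <= 1 (repression-like cooperativity)."))
    }
    model$omega[[cof]] <- om
  }
  model
}

#' Delete enhancer binding sites from a model
#'
#' Deleting a site removes every configuration that requires it (cascade
#' removal): e.g. deleting the primary GATA site of Fli1+12 eliminates the
#' `G`, `G.FF` and `G.S.FF.G` configurations, leaving only the Fli1 dimer
#' state and decoupling Fli1 from Gata2 and Scl.
#'
#' @param model An [enhancer_model()].
#' @param sites Character vector of site names to delete.
#' @return The model with the surviving configurations only (deleted
#'   configurations get weight 0; stoichiometry rows are retained so site
#'   bookkeeping stays stable).
#' @export
delete_sites <- function(model, sites) {
  known <- enhancer_sites(model$key)
  bad <- setdiff(sites, known)
  if (length(bad)) {
    abort(paste0("Unknown site(s) for ", model$name, ": ",
                 paste(bad, collapse = ", "),
                 ". Available: ", paste(known, collapse = ", ")))
  }
  hit <- purrr::map_lgl(model$configurations$sites,
                        ~ any(.x %in% sites))
  model$configurations$weight[hit] <- 0
  model$deleted_sites <- union(model$deleted_sites, sites)
  model
}
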