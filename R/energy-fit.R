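#' Invert a single fold enhancement to a Boltzmann weight
#'
#' Solves `F = K (1 + Z) / (K + Z)` for the bound-configuration weight
#' sum: `Z = K (F - 1) / (K - F)`. This is the elementary step of the
#' recursive free-energy estimation; each reporter construct contributes
#' one such equation with exactly one new unknown.
#'
#' @param F Measured fold enhancement, `1 <= F < K`.
#' @param K Chromatin equilibrium constant, > 1.
#' @return The unique nonnegative weight sum.
#' @export
invert_single <- function(F, K) {
  if (!is.finite(F) || F < 1) {
    abort(paste0("Fold enhancement must be >= 1 (got ", format(F),
                 "); values below the enhancerless baseline are not ",
                 "representable."), class = "triadswitch_data_error")
  }
  if (!is.finite(K) || K <= 1) {
    abort("`K` must be a finite number > 1.")
  }
  if (F >= K) {
    abort(paste0("Infeasible fit: measured enhancement ", format(F),
                 " reaches or exceeds K = ", format(K),
                 "; the maximal possible enhancement is K, so K must ",
                 "exceed every measured fold value."),
          class = "triadswitch_infeasible")
  }
  K * (F - 1) / (K - F)
}

#' Strict lower feasibility bound on the chromatin constant
#'
#' The maximum possible fold enhancement equals `K`, so an exact fit
#' requires `K` strictly above the largest measured fold enhancement in
#' the table (820.51 for the wild-type Scl+19 construct).
#'
#' @param table A reporter table (see [read_reporter_csv()]): needs a
#'   `fold_enhancement` column.
#' @return The maximum measured fold enhancement.
#' @export
feasibility_bound <- function(table) {
  if (!nrow(table)) abort("Empty reporter table.")
  max(table$fold_enhancement)
}

# set-equality lookup of a construct row by its intact sites
lookup_fold <- function(table, intact, enhancer) {
  want <- sort(intact)
  hit <- purrr::map_lgl(table$intact_sites, ~ identical(sort(.x), want))
  if (sum(hit) == 0L) {
    abort(paste0("Reporter table for ", enhancer, " is missing the ",
                 "construct with intact sites {",
                 paste(want, collapse = ", "), "} needed by the fit."),
          class = "triadswitch_schema_error")
  }
  if (sum(hit) > 1L) {
    abort(paste0("Reporter table for ", enhancer, " has duplicate rows ",
                 "for intact sites {", paste(want, collapse = ", "), "}."),
          class = "triadswitch_schema_error")
  }
  table$fold_enhancement[hit]
}

# normalize a reporter table: split semicolon-joined intact_sites, filter
# to one enhancer
prepare_table <- function(data, enhancer) {
  key <- enhancer_key(enhancer)
  nm <- .enhancer_keys[[key]]
  need <- c("enhancer", "intact_sites", "fold_enhancement")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Reporter table lacks column(s): ",
                 paste(miss, collapse = ", ")),
          class = "triadswitch_schema_error")
  }
  tb <- dplyr::filter(as_tibble(data),
                      .data$enhancer %in% c(nm, key))
  if (!nrow(tb)) {
    abort(paste0("No rows for enhancer ", nm, " in reporter table."),
          class = "triadswitch_schema_error")
  }
  if (any(!is.finite(tb$fold_enhancement)) || any(tb$fold_enhancement <= 0)) {
    abort("Fold enhancements must be finite and > 0.",
          class = "triadswitch_data_error")
  }
  if (!is.list(tb$intact_sites)) {
    tb$intact_sites <- purrr::map(
      tb$intact_sites,
      ~ if (is.na(.x) || !nzchar(.x)) character() else
        strsplit(.x, ";", fixed = TRUE)[[1]]
    )
  }
  tb
}

# the recursion shared by all three enhancers: each step inverts one fold
# value and subtracts the weights already determined
fit_recursive <- function(tb, K, key, steps) {
  nm <- .enhancer_keys[[key]]
  bound <- feasibility_bound(tb)
  if (K <= bound) {
    abort(paste0("Infeasible K for ", nm, ": K = ", format(K),
                 " but the maximal measured enhancement is ",
                 format(bound), "; the maximal possible enhancement is K."),
          class = "triadswitch_infeasible")
  }
  w <- numeric(0)
  for (s in steps) {
    F_obs <- lookup_fold(tb, s$intact, nm)
    Z <- invert_single(F_obs, K)
    w_new <- Z - sum(w[s$minus])
    if (w_new < 0) {
      abort(paste0("Infeasible fit for ", nm, ": configuration ", s$id,
                   " gets negative weight ", format(w_new),
                   " (measured synergy below the additive expectation ",
                   "contradicts the model)."),
            class = "triadswitch_infeasible")
    }
    w[s$id] <- w_new
  }
  enhancer_model(key, weights = w, K = K)
}

#' Fit enhancer configuration weights from a reporter table
#'
#' Closed-form recursive estimation of the TR-DNA binding free energies of
#' one enhancer from its reporter library. Single-site constructs pin the
#' single-TR weights; each multi-site construct then introduces exactly
#' one new composite weight, obtained by subtracting the already-known
#' weights from the inverted fold value. The fit is exact: re-simulating
#' every used construct reproduces its measured fold to machine precision.
#'
#' Required constructs (by intact sites):
#' * `Scl+19`: \{GATA\}, \{ETS\}, \{GATA, ETS\} (wild type).
#' * `Gata2-3`: \{GATA\}, \{ETS\}, \{GATA, ETS\} (EBOX deleted), wild type.
#' * `Fli1+12`: \{pGATA\}, \{ETS\}, \{pGATA, ETS\}, wild type.
#'
#' @param data Reporter table with columns `enhancer`, `construct`,
#'   `intact_sites` (semicolon-joined or list-column) and
#'   `fold_enhancement`.
#' @param enhancer Which enhancer to fit.
#' @param K Chromatin equilibrium constant; must exceed the table's
#'   [feasibility_bound()].
#' @param method `"exact"` (closed-form recursion, default) or
#'   `"relaxed"` (nonnegative least squares on log fold values, tolerating
#'   inconsistent tables at the price of non-exact reproduction).
#' @return A fitted [enhancer_model()].
#' @export
fit_enhancer <- function(data, enhancer, K,
                         method = c("exact", "relaxed")) {
  method <- match.arg(method)
  key <- enhancer_key(enhancer)
  tb <- prepare_table(data, key)
  steps <- switch(key,
    scl19 = list(
      list(id = "G",    intact = "GATA",            minus = character()),
      list(id = "FF",   intact = "ETS",             minus = character()),
      list(id = "G.FF", intact = c("GATA", "ETS"),  minus = c("G", "FF"))
    ),
    gata2m3 = list(
      list(id = "G",      intact = "GATA",                   minus = character()),
      list(id = "FF",     intact = "ETS",                    minus = character()),
      list(id = "G.FF",   intact = c("GATA", "ETS"),         minus = c("G", "FF")),
      list(id = "S.G.FF", intact = c("GATA", "ETS", "EBOX"), minus = c("G", "FF", "G.FF"))
    ),
    fli1p12 = list(
      list(id = "G",        intact = "pGATA",           minus = character()),
      list(id = "FF",       intact = "ETS",             minus = character()),
      list(id = "G.FF",     intact = c("pGATA", "ETS"), minus = c("G", "FF")),
      list(id = "G.S.FF.G", intact = c("pGATA", "ETS", "EBOX", "sGATA"),
           minus = c("G", "FF", "G.FF"))
    )
  )
  if (method == "exact") {
    return(fit_recursive(tb, K, key, steps))
  }
  fit_relaxed(tb, K, key)
}

# least-squares relaxation: minimize squared log-fold residuals over all
# constructs in the table, weights parameterized on the log scale
fit_relaxed <- function(tb, K, key) {
  bound <- feasibility_bound(tb)
  if (K <= bound) {
    abort(paste0("Infeasible K: bound is ", format(bound)),
          class = "triadswitch_infeasible")
  }
  topo <- enhancer_topology(key)
  predict_folds <- function(logw) {
    m <- enhancer_model(key, setNames(exp(logw), topo$id), K)
    purrr::map_dbl(tb$intact_sites, function(intact) {
      dm <- delete_sites(m, setdiff(enhancer_sites(key), intact))
      fold_enhancement(dm, triad_state())
    })
  }
  obj <- function(logw) sum((log(predict_folds(logw)) -
                             log(tb$fold_enhancement))^2)
  # warm start from the exact recursion when feasible, else flat
  start <- rep(0, nrow(topo))
  fit0 <- tryCatch(fit_enhancer(tb, key, K, method = "exact"),
                   error = function(e) NULL)
  if (!is.null(fit0)) {
    start <- log(pmax(fit0$configurations$weight, 1e-8))
  }
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  enhancer_model(key, setNames(exp(opt$par), topo$id), K)
}

#' Tidy summary of a fitted enhancer model
#'
#' @param x An [enhancer_model()].
#' @param ... Unused.
#' @return A tibble with one row per configuration: `enhancer`, `id`,
#'   stoichiometry, `weight` and `energy = -log(weight)` (in units of
#'   1/beta; `Inf` for absent configurations).
#' @export
tidy.enhancer_model <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$configurations, "id", "scl", "gata2", "fli1", "weight"),
    energy = ifelse(.data$weight > 0, -log(.data$weight), Inf),
    enhancer = x$name, .before = 1
  )
}

#' One-row summary of a fitted enhancer model
#'
#' @param x An [enhancer_model()].
#' @param ... Unused.
#' @return A tibble with `enhancer`, `K`, number of active configurations,
#'   the wild-type fold enhancement at state (1,1,1) and the omegas.
#' @export
glance.enhancer_model <- function(x, ...) {
  tibble(
    enhancer = x$name, K = x$K,
    n_config = sum(x$configurations$weight > 0),
    wt_fold = fold_enhancement(x, triad_state()),
    omega_notch = if ("notch" %in% x$cofactors) x$omega[["notch"]] else NA_real_,
    omega_bmp4 = if ("bmp4" %in% x$cofactors) x$omega[["bmp4"]] else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
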