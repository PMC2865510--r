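#' Choose chromatin constants automatically
#'
#' The exact fit requires each `K` above its enhancer's feasibility
#' bound, and the triad is only Notch/Bmp4-switchable when the wild-type
#' enhancement sits close to saturation, i.e. `K` just above the bound.
#' The automatic choice starts at `bound * 1.05` for every enhancer and
#' verifies that both Notch and Bmp4 can switch the rebuilt triad; if
#' not, a common multiplier is scanned over `[1.01, 2]` and the first
#' switchable value kept.
#'
#' @param data Reporter table for all three enhancers.
#' @param margin Initial multiplier over the feasibility bound.
#' @param verify Check Notch/Bmp4 switchability (slower); if `FALSE` the
#'   margin is applied blindly.
#' @param ... Passed to [triad_parameters()].
#' @return Named numeric `c(scl19 =, gata2m3 =, fli1p12 =)`, with the
#'   chosen multiplier as attribute `"margin"`.
#' @export
auto_K <- function(data, margin = 1.05, verify = TRUE, ...) {
  bounds <- purrr::map_dbl(names(.enhancer_keys),
                           ~ feasibility_bound(prepare_table(data, .x)))
  names(bounds) <- names(.enhancer_keys)
  try_margin <- function(m) {
    K <- bounds * m
    params <- tryCatch(build_triad(data, K = K, ...),
                       error = function(e) NULL)
    if (is.null(params)) return(NULL)
    oo <- tryCatch(off_on_states(params), error = function(e) NULL)
    if (is.null(oo)) return(NULL)
    if (!sustained_switches(params, "notch", 1e3, oo$off, oo$on)) return(NULL)
    if (!sustained_switches(params, "bmp4", 1e3, oo$off, oo$on)) return(NULL)
    K
  }
  if (!verify) {
    K <- bounds * margin
    attr(K, "margin") <- margin
    return(K)
  }
  K <- try_margin(margin)
  if (!is.null(K)) { attr(K, "margin") <- margin; return(K) }
  for (m in seq(1.01, 2, by = 0.01)) {
    K <- try_margin(m)
    if (!is.null(K)) { attr(K, "margin") <- m; return(K) }
  }
  abort("No margin in [1.01, 2] yields a Notch- and Bmp4-switchable triad.",
        class = "triadswitch_infeasible")
}

#' Fit the full triad model from a reporter table
#'
#' Fits all three enhancers by the exact closed-form recursion,
#' calibrates the Notch/Bmp4 polymerase-interaction factors at the
#' wild-type state, and assembles the dimensionless ODE parameter set.
#'
#' @param data Reporter table covering all three enhancers.
#' @param K Named numeric `c(scl19 =, gata2m3 =, fli1p12 =)`, or
#'   `"auto"` (default) for [auto_K()].
#' @param fold_notch,fold_bmp4 Cofactor calibration folds (3.5 and 4).
#' @param half_lives,time_unit Passed to [triad_parameters()].
#' @return A [triad_params][triad_parameters()] object.
#' @export
build_triad <- function(data, K = "auto", fold_notch = 3.5, fold_bmp4 = 4,
                        half_lives = c(8, 1 / 6, 2),
                        time_unit = c("mean_lifetime", "half_life")) {
  time_unit <- match.arg(time_unit)
  if (identical(K, "auto")) {
    K <- auto_K(data, fold_notch = fold_notch, fold_bmp4 = fold_bmp4,
                half_lives = half_lives, time_unit = time_unit)
  }
  models <- purrr::map(names(.enhancer_keys), function(key) {
    m <- fit_enhancer(data, key, K[[key]])
    calibrate_omegas(m, fold_notch = fold_notch, fold_bmp4 = fold_bmp4)
  })
  names(models) <- names(.enhancer_keys)
  triad_parameters(models$scl19, models$gata2m3, models$fli1p12,
                   half_lives = half_lives, time_unit = time_unit)
}
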