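# construct sets emitted for each enhancer: exactly what the fit needs
library_constructs <- function(key) {
  switch(key,
    scl19 = list(
      list(construct = "mut2_gata_only", intact = "GATA"),
      list(construct = "mut1_ets_only",  intact = "ETS"),
      list(construct = "wt",             intact = c("GATA", "ETS"))
    ),
    gata2m3 = list(
      list(construct = "gata_only", intact = "GATA"),
      list(construct = "ets_only",  intact = "ETS"),
      list(construct = "dEbox",     intact = c("GATA", "ETS")),
      list(construct = "wt",        intact = c("GATA", "ETS", "EBOX"))
    ),
    fli1p12 = list(
      list(construct = "pgata_only", intact = "pGATA"),
      list(construct = "ets_only",   intact = "ETS"),
      list(construct = "pgata_ets",  intact = c("pGATA", "ETS")),
      list(construct = "wt",
           intact = c("pGATA", "ETS", "EBOX", "sGATA"))
    )
  )
}

#' Sample a ground-truth parameter set
#'
#' Draws configuration weights log-uniformly in `[0.1, 1e4]` and chromatin
#' constants log-uniformly in `[10, 1e4]` (the range reported for
#' nucleosomal equilibrium constants), redrawing `K` until the wild-type
#' fold enhancement stays below `0.99 K` so the closed-form inversion is
#' well conditioned. Fully determined by the seed.
#'
#' @param seed Integer seed.
#' @return A list of class `ground_truth` with elements `models` (three
#'   [enhancer_model()] objects) and `seed`.
#' @export
generate_truth <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  models <- purrr::map(names(.enhancer_keys), function(key) {
    topo <- enhancer_topology(key)
    w <- setNames(10^runif(nrow(topo), -1, 4), topo$id)
    for (i in 1:100) {
      K <- 10^runif(1, 1, 4)
      m <- enhancer_model(key, w, K)
      if (fold_enhancement(m, triad_state()) <= 0.99 * K) return(m)
    }
    abort("Could not sample a well-conditioned K.")
  })
  structure(list(models = setNames(models, names(.enhancer_keys)),
                 seed = seed),
            class = "ground_truth")
}

#' Generate a synthetic enhancer-reporter library
#'
#' Emits, for each enhancer, the construct set required by the
#' corresponding fit: fold values are computed by [fold_enhancement()]
#' at the wild-type state `(1,1,1)` on the site-deleted model, then
#' multiplied by lognormal measurement noise `exp(sigma * z)` with `z`
#' standard normal. `sigma = 0` gives exact values.
#'
#' @param truth A [generate_truth()] object (or any named list of three
#'   enhancer models `scl19`, `gata2m3`, `fli1p12`).
#' @param sigma Lognormal noise scale (standard deviation of log fold).
#' @param seed Seed for the noise draws (defaults to the truth's seed).
#' @return A reporter-table tibble with columns `enhancer`, `construct`,
#'   `intact_sites` (semicolon-joined), `fold_enhancement`.
#' @export
generate_library <- function(truth, sigma = 0, seed = NULL) {
  models <- truth$models
  seed <- seed %||% truth$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  purrr::map_dfr(names(models), function(key) {
    m <- models[[key]]
    purrr::map_dfr(library_constructs(key), function(cs) {
      dm <- delete_sites(m, setdiff(enhancer_sites(key), cs$intact))
      f <- fold_enhancement(dm, triad_state())
      if (sigma > 0) f <- f * exp(sigma * rnorm(1))
      tibble(enhancer = m$name, construct = cs$construct,
             intact_sites = paste(cs$intact, collapse = ";"),
             fold_enhancement = f)
    })
  })
}

#' Packaged enhancer-reporter fold-change table
#'
#' The reporter library shipped with the package. Main-text anchor values
#' (`source = "measured"`: Scl+19 wild type 820.51; Fli1+12 primary
#' GATA + Fli1 dimer 20 and wild type 60) are combined with synthetic
#' placeholder values for the cells not printed in the main text
#' (`source = "placeholder"`). Quantities that depend on placeholder
#' cells are only anchor-accurate where the anchors pin them.
#'
#' @return A reporter-table tibble with an extra `source` column.
#' @export
hsc_reporter_library <- function() {
  path <- system.file("extdata", "reporter_library.csv",
                      package = "triadswitch", mustWork = TRUE)
  read_reporter_csv(path)
}
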